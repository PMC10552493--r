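test_that("biased sampling of a flat landscape is the bias Gaussian", {
  flat <- ground_truth_fes(function(s) rep(0, length(s)), -2, 8)
  tr <- sample_biased(flat, umbrella_window(3, k = 2), n = 1e5, seed = 3)
  s <- tr$series$cv
  se_mean <- sqrt(0.5 / 1e5)
  expect_lt(abs(mean(s) - 3), 3 * se_mean)
  expect_lt(abs(var(s) - 0.5), 3 * sqrt(2 / 1e5) * 0.5)
})

test_that("empty draws keep valid metadata", {
  tr <- sample_biased(fes_double_well(), umbrella_window(0, 20), n = 0)
  expect_equal(nrow(tr$series), 0)
  expect_s3_class(tr, "cv_series")
  expect_equal(tr$window$center, 0)
  expect_equal(tr$fes_label, "double_well")
})

test_that("samples pass a KS test against the exact biased CDF", {
  fes <- fes_double_well()
  w <- umbrella_window(-0.5, 20)
  tr <- sample_biased(fes, w, n = 1e4, seed = 11)
  dens <- function(s) exp(-(fes$fun(s) + 0.5 * w$k * (s - w$center)^2))
  Z <- integrate(dens, fes$lower, fes$upper, rel.tol = 1e-10)$value
  cdf <- Vectorize(function(q)
    integrate(dens, fes$lower, q, rel.tol = 1e-10)$value / Z)
  ks <- suppressWarnings(ks.test(tr$series$cv, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("2D sampler draws from the separable biased density", {
  fes2 <- fes_double_well_2d()
  w <- umbrella_window(1, 20)
  tr <- sample_biased(fes2, w, n = 2e4, seed = 13)
  # secondary coordinate: Gaussian with mean 4, var 1/(2a) = 0.25
  expect_lt(abs(mean(tr$series$cv2) - 4), 3 * sqrt(0.25 / 2e4))
  expect_lt(abs(var(tr$series$cv2) - 0.25), 4 * sqrt(2 / 2e4) * 0.25)
  # primary coordinate against its exact marginal CDF
  dens <- function(s) exp(-(8 * (s^2 - 1)^2 + 10 * (s - 1)^2))
  Z <- integrate(dens, -2.5, 2.5, rel.tol = 1e-10)$value
  cdf <- Vectorize(function(q)
    integrate(dens, -2.5, q, rel.tol = 1e-10)$value / Z)
  ks <- suppressWarnings(ks.test(tr$series$cv, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("toy chelators carry the right donor counts and topology", {
  dfo <- build_toy_chelator(n_groups = 3, seed = 2)
  expect_equal(sum(dfo$roles == "ligand_oxygen"), 6)
  hms <- build_toy_chelator(n_groups = 4, seed = 2)
  expect_equal(sum(hms$roles == "ligand_oxygen"), 8)
  # determinism
  expect_identical(build_toy_chelator(3, seed = 7)$positions,
                   build_toy_chelator(3, seed = 7)$positions)
  # bonds connect each oxygen to exactly one backbone bead, and backbone
  # beads into a chain
  for (b in dfo$bonds) {
    ri <- dfo$roles[b$i]; rj <- dfo$roles[b$j]
    expect_true((ri == "backbone" && rj %in% c("backbone", "ligand_oxygen")) ||
                  (rj == "backbone" && ri %in% c("backbone", "ligand_oxygen")))
  }
  oxy <- which(dfo$roles == "ligand_oxygen")
  deg <- vapply(oxy, function(o)
    sum(vapply(dfo$bonds, function(b) b$i == o || b$j == o, logical(1))),
    numeric(1))
  expect_true(all(deg == 1))
  # attached CV: ligand oxygens around the ion with r0 = 5
  expect_equal(dfo$cv_specs[[1]]$switching$r0, 5)
  expect_setequal(dfo$cv_specs[[1]]$member_particles, oxy)
})

test_that("quadrature profile matches the analytic Gaussian pushforward", {
  # one tethered free ion, one frozen donor: CN = s(|x|) with x Gaussian
  k <- 2; anchor <- c(2, 0, 0)
  sys <- toy_system(rbind(anchor, c(0, 0, 0)),
                    c("ion", "ligand_oxygen"),
                    masses = c(1, Inf),
                    tether = data.frame(index = 1, k = k, x = anchor[1],
                                        y = anchor[2], z = anchor[3]),
                    cv_specs = list(cv_spec(1, 2, switching_params(2.5))))
  breaks <- seq(0.3, 1, by = 0.1)
  prof <- reference_fes_quadrature(sys, breaks = breaks,
                                   box = rbind(anchor - 4.2, anchor + 4.2),
                                   n_grid = 161)
  expect_lt(prof$max_refinement_change, 0.05)
  # analytic route: radial density of |x| for an isotropic Gaussian about
  # the anchor, pushed through the monotone switch
  a <- sqrt(sum(anchor^2))
  pr <- function(d) d / a * sqrt(k / (2 * pi)) *
    (exp(-k * (d - a)^2 / 2) - exp(-k * (d + a)^2 / 2))
  sw <- function(d) switch_weight(d, switching_params(2.5))
  dmax <- 30
  ref <- vapply(seq_len(length(breaks) - 1), function(b) {
    lo <- uniroot(function(d) sw(d) - breaks[b + 1], c(1e-6, dmax))$root
    hi <- uniroot(function(d) sw(d) - breaks[b], c(1e-6, dmax))$root
    -log(integrate(pr, lo, hi, rel.tol = 1e-10)$value)
  }, numeric(1))
  ref <- ref - min(ref)
  sel <- !is.na(prof$f_values)
  dev <- prof$f_values[sel] - ref[sel]
  expect_lt(max(abs(dev - mean(dev))), 0.05)
})

test_that("flat-potential quadrature equals level-set volume (MC oracle)", {
  sys <- toy_system(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 2, 0)),
                    c("ion", "ligand_oxygen", "ligand_oxygen"),
                    masses = c(1, Inf, Inf),
                    cv_specs = list(cv_spec(1, 2:3, switching_params(2))))
  breaks <- seq(0.1, 1.9, by = 0.2)
  box <- rbind(c(-3, -3, -3), c(5, 5, 3))
  prof <- reference_fes_quadrature(sys, breaks = breaks, box = box,
                                   n_grid = 101)
  # hit-or-miss Monte Carlo volumes of the CN level sets
  set.seed(42)
  n <- 3e5
  pts <- cbind(runif(n, box[1, 1], box[2, 1]),
               runif(n, box[1, 2], box[2, 2]),
               runif(n, box[1, 3], box[2, 3]))
  sw <- switching_params(2)
  cn <- switch_weight(sqrt(rowSums(pts^2)), sw) +
    switch_weight(sqrt(rowSums(sweep(pts, 2, c(0, 2, 0))^2)), sw)
  counts <- tabulate(findInterval(cn, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  ref <- -log(counts / n)
  sel <- !is.na(prof$f_values) & counts > 2000
  dev <- prof$f_values[sel] - (ref[sel] - min(ref[sel]))
  expect_lt(max(abs(dev - mean(dev))), 0.1)
})

test_that("the oracle refuses underdetermined problems", {
  sys <- build_toy_chelator(2)  # many free particles
  expect_error(reference_fes_quadrature(sys, breaks = 0:5,
                                        box = rbind(rep(-1, 3), rep(1, 3))),
               "exactly one free")
})
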