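test_that("unbiased single-window WHAM is -log of the histogram density", {
  set.seed(12)
  s <- rnorm(2e4, mean = 1, sd = 0.7)
  tr <- structure(list(series = data.frame(time = seq_along(s), cv = s),
                       window = umbrella_window(0, k = 0)),
                  class = "cv_series")
  prof <- wham_1d(list(tr), bins = 40)
  counts <- tabulate(findInterval(s, prof$breaks, rightmost.closed = TRUE),
                     nbins = 40)
  ref <- -log(counts / sum(counts))
  ref[counts == 0] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  expect_equal(prof$f_values, ref, tolerance = 1e-9)
  expect_true(all(is.na(prof$f_values[prof$unsampled])))
})

test_that("duplicating every window leaves the profile unchanged", {
  series <- double_well_fixture(n = 4000)
  p1 <- wham_1d(series, bins = 60)
  p2 <- wham_1d(c(series, series), bins = p1$breaks)
  expect_equal(p1$f_values, p2$f_values, tolerance = 1e-10)
})

test_that("window order does not affect the profile or the surface", {
  fes2 <- fes_double_well_2d()
  centers <- seq(-2, 2, 0.5)
  series <- lapply(seq_along(centers), function(i)
    sample_biased(fes2, umbrella_window(centers[i], 20), n = 4000,
                  seed = 40 + i))
  perm <- c(5, 9, 1, 7, 3, 2, 8, 6, 4)
  p1 <- wham_1d(series, bins = 60)
  p2 <- wham_1d(series[perm], bins = p1$breaks)
  expect_equal(p1$f_values, p2$f_values, tolerance = 1e-7)
  s1 <- reweight_2d(series, p1, bins2 = 20)
  s2 <- reweight_2d(series[perm], p2, bins2 = s1$breaks2)
  expect_equal(s1$f_values, s2$f_values, tolerance = 1e-7)
})

test_that("the profile recovers a known double-well landscape", {
  series <- double_well_fixture(n = 1e4)
  prof <- wham_1d(series, bins = 100)
  expect_true(prof$converged)
  expect_equal(prof$n_components, 1)
  f0 <- fes_double_well()$fun(prof$bin_centers)
  sel <- !prof$unsampled & f0 <= 6
  dev <- prof$f_values[sel] - f0[sel]
  expect_lt(max(abs(dev - mean(dev))), 0.2)
  # min-zero convention
  expect_equal(min(prof$f_values, na.rm = TRUE), 0)
})

test_that("offsets are gauge-fixed and consistent with the profile", {
  series <- double_well_fixture(n = 4000)
  prof <- wham_1d(series, bins = 60)
  expect_equal(prof$window_offsets[1], 0)
  # offsets reproduce themselves through the WHAM equation
  cmat <- ionfes:::.bias_matrix(ionfes:::.wham_inputs(series), prof$breaks)
  lp <- -prof$f_values
  lp[prof$unsampled] <- NA
  f_chk <- -log(rowSums(exp(sweep(-cmat, 2, lp, `+`)), na.rm = TRUE))
  f_chk <- f_chk - f_chk[1]
  expect_equal(f_chk, prof$window_offsets, tolerance = 1e-5)
})

test_that("disconnected window histograms are flagged", {
  mk <- function(mu, center) structure(
    list(series = data.frame(time = 1:500, cv = rnorm(500, mu, 0.05)),
         window = umbrella_window(center, 20)), class = "cv_series")
  set.seed(3)
  expect_warning(prof <- wham_1d(list(mk(-2, -2), mk(2, 2)), bins = 50),
                 "disconnected")
  expect_gt(prof$n_components, 1)
})

test_that("bootstrap errors are deterministic, positive, and vanish
           without resampling", {
  series <- double_well_fixture(n = 3000)
  prof <- wham_1d(series, bins = 60)
  p0 <- bootstrap_errors(series, prof, n_boot = 10, seed = 5,
                         resample = FALSE)
  expect_equal(max(p0$f_errors, na.rm = TRUE), 0)
  p1 <- bootstrap_errors(series, prof, n_boot = 10, seed = 5)
  p2 <- bootstrap_errors(series, prof, n_boot = 10, seed = 5)
  expect_identical(p1$f_errors, p2$f_errors)
  expect_true(all(p1$f_errors[!prof$unsampled] >= 0, na.rm = TRUE))
  p3 <- bootstrap_errors(series, prof, n_boot = 10, seed = 6)
  expect_false(identical(p1$f_errors, p3$f_errors))
  expect_error(bootstrap_errors(series, prof, n_boot = 10, seed = 1,
                                block_len = 10000), "exceeds")
})

test_that("more samples shrink the bootstrap error (median over seeds)", {
  med_err <- function(n, seed_base) {
    series <- double_well_fixture(n = n, base_seed = seed_base)
    prof <- wham_1d(series, bins = 60)
    prof <- bootstrap_errors(series, prof, n_boot = 15, seed = 2)
    median(prof$f_errors, na.rm = TRUE)
  }
  deltas <- vapply(c(100, 300, 500, 700, 900), function(b)
    med_err(4000, b) - med_err(2000, b), numeric(1))
  expect_lt(median(deltas), 0)
})

test_that("degenerate secondary CV collapses the surface onto the profile", {
  series <- double_well_fixture(n = 5000)
  for (i in seq_along(series)) series[[i]]$series$cv2 <- 3.3
  prof <- wham_1d(series, bins = 60)
  surf <- reweight_2d(series, prof, bins2 = seq(1, 5, length.out = 11))
  occupied <- which(colSums(!surf$unsampled) > 0)
  expect_length(occupied, 1)
  col <- surf$f_values[, occupied]
  # the single occupied slice reproduces the 1D profile on well-sampled
  # bins, within the marginal-consistency tolerance (the binless frame
  # weights and the binned histogram weight the same samples differently)
  sel <- !is.na(col) & !is.na(prof$f_values) & surf$n_eff[, occupied] >= 100
  dev <- col[sel] - prof$f_values[sel]
  expect_lt(max(abs(dev - mean(dev))), 0.2)
})

test_that("missing secondary CV names the offending window", {
  series <- double_well_fixture(n = 1000)
  prof <- wham_1d(series, bins = 40)
  expect_error(reweight_2d(series, prof), "window 1")
})

test_that("marginalising the 2D surface reproduces the 1D profile", {
  fes2 <- fes_double_well_2d()
  centers <- seq(-2, 2, 0.5)
  series <- lapply(seq_along(centers), function(i)
    sample_biased(fes2, umbrella_window(centers[i], 20), n = 8000,
                  seed = 60 + i))
  prof <- wham_1d(series, bins = 80)
  surf <- reweight_2d(series, prof, bins2 = 30)
  marg <- fes_marginal(surf)
  sel <- !prof$unsampled & prof$f_values <= 6 & !is.na(marg)
  expect_lt(max(abs(marg[sel] - prof$f_values[sel])), 0.2)
})

test_that("2D bootstrap errors are deterministic and well-formed", {
  fes2 <- fes_double_well_2d()
  centers <- seq(-1.5, 1.5, 0.75)
  series <- lapply(seq_along(centers), function(i)
    sample_biased(fes2, umbrella_window(centers[i], 20), n = 2000,
                  seed = 80 + i))
  prof <- wham_1d(series, bins = 40)
  surf <- reweight_2d(series, prof, bins2 = 15)
  s1 <- bootstrap_errors_2d(series, prof, surf, n_boot = 8, seed = 4)
  s2 <- bootstrap_errors_2d(series, prof, surf, n_boot = 8, seed = 4)
  expect_identical(s1$f_errors, s2$f_errors)
  expect_true(all(s1$f_errors >= 0, na.rm = TRUE))
})
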