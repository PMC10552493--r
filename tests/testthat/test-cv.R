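test_that("rational switching function hits its exact landmark values", {
  p <- switching_params(r0 = 5, n_exp = 6, m_exp = 12)
  expect_identical(switch_weight(0, p), 1)
  # removable singularity at d = r0: limit is n/m = 0.5 exactly
  expect_identical(switch_weight(5, p), 0.5)
  expect_equal(switch_weight(5 * (1 + 1e-8), p), 0.5, tolerance = 1e-7)
  expect_equal(switch_weight(5 * (1 - 1e-8), p), 0.5, tolerance = 1e-7)
  # far-field decay ~ (r0/d)^(m-n)
  expect_lt(switch_weight(50, p), 1e-5)
})

test_that("switching weight is in (0,1], strictly decreasing, and agrees
           with the direct rational form", {
  p <- switching_params(r0 = 2.5)
  d <- sort(c(seq(0.01, 25, length.out = 500),
              2.5 * (1 + c(-1, 1) * 1e-3)))
  s <- switch_weight(d, p)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))
  # independent evaluation through the unfactored rational expression,
  # away from its unstable point d = r0
  set.seed(8)
  dr <- runif(1000, 0, 12.5)
  dr <- dr[abs(dr - 2.5) > 1e-4]
  x <- dr / 2.5
  direct <- (1 - x^6) / (1 - x^12)
  expect_equal(switch_weight(dr, p), direct, tolerance = 1e-12)
})

test_that("switch derivative matches finite differences", {
  p <- switching_params(r0 = 5)
  d <- c(0.5, 2, 4.99, 5, 5.01, 8, 20)
  out <- switch_weight(d, p, deriv = TRUE)
  h <- 1e-6
  fd <- (switch_weight(d + h, p) - switch_weight(d - h, p)) / (2 * h)
  expect_equal(out[, "dsdd"], fd, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("coordination number reproduces near/far limits", {
  p <- switching_params(r0 = 5)
  mk <- function(dists) {
    pos <- rbind(c(0, 0, 0),
                 t(vapply(dists, function(d) c(d, 0, 0) +
                            rnorm(3, sd = 1e-12), numeric(3))))
    pos[-1, 1] <- dists  # exact x displacement
    pos
  }
  spec6 <- cv_spec(1, 2:7, p)
  set.seed(1)
  # all members far: CN ~ 0
  far <- coordination_number(mk(rep(50, 6)), spec6)
  expect_lt(far$value, 6e-5)
  # all members close: CN ~ 6, emulating the fully bound six-coordinate pose
  near <- coordination_number(mk(rep(0.5, 6)), spec6)
  expect_gt(near$value, 6 * (1 - 1e-5))
  # half close, half far: sum of the limits
  half <- coordination_number(mk(c(0.5, 0.5, 0.5, 50, 50, 50)), spec6)
  expect_equal(half$value, 3, tolerance = 1e-4)
})

test_that("coordination gradients are analytic and translation-free", {
  set.seed(4)
  pos <- matrix(rnorm(21, sd = 3), 7, 3)
  spec <- cv_spec(1, 2:7, switching_params(r0 = 5))
  cn <- coordination_number(pos, spec)
  expect_lt(max(abs(colSums(cn$gradient))), 1e-12)
  h <- 1e-6
  for (i in 1:7) for (d in 1:3) {
    p1 <- pos; p1[i, d] <- p1[i, d] + h
    p2 <- pos; p2[i, d] <- p2[i, d] - h
    fd <- (coordination_number(p1, spec)$value -
             coordination_number(p2, spec)$value) / (2 * h)
    expect_equal(cn$gradient[i, d], fd, tolerance = 1e-5)
  }
})

test_that("coordination number is invariant under rigid-body transforms", {
  set.seed(5)
  pos <- matrix(rnorm(18, sd = 3), 6, 3)
  spec <- cv_spec(1, 2:6, switching_params(r0 = 5))
  v0 <- coordination_number(pos, spec)$value
  for (rep in 1:20) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shifted <- pos %*% q + matrix(rnorm(3, sd = 10), 6, 3, byrow = TRUE)
    expect_equal(coordination_number(shifted, spec)$value, v0,
                 tolerance = 1e-9)
  }
})

test_that("coincident member and center is a domain error", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  spec <- cv_spec(1, 2:3, switching_params(r0 = 5))
  expect_error(coordination_number(pos, spec), "coincides")
})

test_that("chelate angles use the oxygen-vertex convention", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_equal(chelate_angles(pos, list(c(1, 2, 3))), 180)
  expect_equal(chelate_angles(pos, list(c(1, 2, 4))), 90)
  expect_error(chelate_angles(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
                              list(c(1, 2, 3))), "zero-length")
  # rigid-transform invariance
  set.seed(6)
  tri <- matrix(rnorm(9, sd = 2), 3, 3)
  a0 <- chelate_angles(tri, list(c(1, 2, 3)))
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  a1 <- chelate_angles(tri %*% q + matrix(rnorm(3), 3, 3, byrow = TRUE),
                       list(c(1, 2, 3)))
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("partial coordination curve counts sharply and averages", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  curve <- partial_coordination_curve(pos, 1, 2:4, c(1.5, 2.5, 3.5))
  expect_equal(curve$n, c(1, 2, 3))
  expect_equal(partial_coordination_curve(pos, 1, 2:4, c(0.2, 0.5))$n,
               c(0, 0))
  # two frames: counts {1, 2} and {2, 3} average to {1.5, 2.5}
  posb <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.2, 0, 0), c(0, 0, 1.4))
  two <- partial_coordination_curve(list(pos, posb), 1, 2:4, c(1.3, 2.6))
  expect_equal(two$n, c((1 + 2) / 2, (2 + 3) / 2))
  expect_error(partial_coordination_curve(list(), 1, 2:4, 1), "empty")
  expect_error(partial_coordination_curve(pos, 1, 2:4, c(2, 1)), "sorted")
  # non-decreasing, saturating at the member count
  r <- seq(0, 10, by = 0.5)
  full <- partial_coordination_curve(pos, 1, 2:4, r)
  expect_true(all(diff(full$n) >= 0))
  expect_equal(full$n[length(r)], 3)
})
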