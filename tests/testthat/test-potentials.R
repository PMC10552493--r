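test_that("12-6-4 pair energy matches its closed forms and truncation", {
  p <- pair_params(c12 = 1, c6 = 2)
  # analytic minimum of the 12-6 part: r* = (2 c12/c6)^(1/6) = 1, U = -1
  expect_equal(pair_energy(1, p), -1)
  grid <- seq(0.5, 3, by = 1e-4)
  u <- pair_energy(grid, p)
  expect_equal(min(u), -1, tolerance = 1e-7)
  expect_equal(grid[which.min(u)], 1, tolerance = 1e-3)
  # single-term C4 evaluation
  p4 <- pair_params(c12 = 1e-12, c4 = 1)
  expect_equal(pair_energy(2, p4), 1e-12 / 2^12 - 1 / 16)
  # truncation: exactly zero at and beyond the cutoff
  expect_identical(pair_energy(c(11, 12, 100), p), c(0, 0, 0))
  expect_error(pair_energy(0, p), "positive")
  expect_error(pair_energy(-1, p), "positive")
})

test_that("pair parameter invariants are enforced", {
  expect_error(pair_params(c12 = 0, c6 = 1), "collapse")
  expect_error(pair_params(c12 = 0, c4 = 1), "collapse")
  expect_error(pair_params(c12 = 0, q_product = -1), "collapse")
  expect_error(pair_params(c12 = 1, cutoff = 0))
  expect_silent(pair_params(c12 = 0, q_product = 2))  # pure repulsion is fine
})

test_that("pair energy is monotonically decreasing below the minimum", {
  p <- pair_params(c12 = 100, c6 = 10, c4 = 1, q_product = -2)
  rstar <- optimize(pair_energy, c(0.1, 8), p = p)$minimum
  r <- seq(0.2, rstar, length.out = 200)
  expect_true(all(diff(pair_energy(r, p)) < 0))
})

test_that("pair force is the negative radial derivative of the energy", {
  p <- pair_params(c12 = 100, c6 = 10, c4 = 1, q_product = -2)
  r <- seq(0.8, 5, length.out = 50)
  h <- 1e-7
  fd <- -(pair_energy(r + h, p) - pair_energy(r - h, p)) / (2 * h)
  expect_equal(pair_force(r, p), fd, tolerance = 1e-5)
})

test_that("total energy and forces: trivial two-particle contracts", {
  sys <- toy_system(rbind(c(0, 0, 0), c(12, 0, 0)),
                    c("ion", "ligand_oxygen"),
                    pair_table = list(`ion:ligand_oxygen` =
                                        pair_params(c12 = 1, c6 = 2)))
  ef <- total_energy_forces(sys)
  expect_identical(ef$energy, 0)
  expect_identical(max(abs(ef$forces)), 0)
})

test_that("analytic forces equal finite differences and sum to zero", {
  worst <- 0
  for (seed in 1:100) {
    sys <- random_test_system(n = 5, seed = seed)
    ef <- total_energy_forces(sys)
    expect_lt(max(abs(colSums(ef$forces))), 1e-10)  # Newton's third law
    if (seed <= 20) {  # full FD check on a subset (15 coordinates each)
      worst <- max(worst, max(abs(fd_forces(sys) - ef$forces)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("bonded terms contribute harmonic energy and exclude the pair", {
  sys <- toy_system(rbind(c(0, 0, 0), c(2, 0, 0)),
                    c("ion", "ligand_oxygen"),
                    bonds = list(list(i = 1, j = 2,
                                      params = bond_params(50, 1.5))),
                    pair_table = list(`ion:ligand_oxygen` =
                                        pair_params(c12 = 1, c6 = 2)))
  ef <- total_energy_forces(sys)
  expect_equal(ef$energy, 0.5 * 50 * 0.5^2)  # bonded pair skips the 12-6-4
  expect_equal(ef$forces[1, 1], 50 * 0.5)
})

test_that("overlapping particles raise an explicit error, not infinity", {
  sys <- random_test_system(n = 3, seed = 2)
  sys$positions[2, ] <- sys$positions[1, ] + c(1e-5, 0, 0)
  expect_error(total_energy_forces(sys), "guard")
})

test_that("harmonic bias energy and force follow 1/2 k (s - s0)^2", {
  w <- umbrella_window(center = 3, k = 20)
  dcv <- matrix(rnorm(9), 3, 3)
  at_center <- bias_energy_force(3, dcv, w)
  expect_identical(at_center$energy, 0)
  expect_identical(max(abs(at_center$force)), 0)
  # k = 20 k_BT and a unit CV displacement give 10 k_BT
  expect_equal(bias_energy_force(4, NULL, w)$energy, 10)
  # symmetry about the center
  expect_equal(bias_energy_force(3 + 0.7, NULL, w)$energy,
               bias_energy_force(3 - 0.7, NULL, w)$energy)
  # chain rule
  b <- bias_energy_force(3.5, dcv, w)
  expect_equal(b$force, -20 * 0.5 * dcv)
})

test_that("system validation catches malformed inputs", {
  expect_error(toy_system(matrix(0, 2, 3), c("ion", "ion")), "exactly one")
  expect_error(toy_system(matrix(0, 2, 3), c("ion", "oxygen")), "unknown")
  expect_error(toy_system(matrix(0, 2, 3), c("ion", "backbone"),
                          bonds = list(list(i = 1, j = 1,
                                            params = bond_params(1, 1)))),
               "self-bonds")
  expect_error(toy_system(matrix(0, 2, 3), c("ion", "backbone"),
                          masses = c(1, 0)))
})
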