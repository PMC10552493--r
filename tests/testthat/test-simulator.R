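test_that("identical seeds give bitwise-identical series", {
  sys <- build_ion_ring_system()
  cfg <- sim_config(n_steps = 2000, save_stride = 10, seed = 99)
  t1 <- run_trajectory(sys, cfg, umbrella_window(3, 20), save_frames = FALSE)
  t2 <- run_trajectory(sys, cfg, umbrella_window(3, 20), save_frames = FALSE)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$final_pos, t2$final_pos)
})

test_that("zero-temperature overdamped dynamics quenches the energy", {
  sys <- bound_dimer(r = 1.6)  # stretched from the r* = 1 minimum
  # strong friction: the overdamped-quench limit
  cfg <- sim_config(dt = 0.002, gamma = 50, temperature = 0,
                    n_steps = 20000, save_stride = 100, seed = 1)
  tr <- run_trajectory(sys, cfg, save_frames = FALSE)
  # after the inertial transient the potential descends towards a minimum
  late <- tr$epot[10:length(tr$epot)]
  expect_true(all(diff(late) <= 1e-8))
  expect_lt(tr$epot[length(tr$epot)], tr$epot[1])
})

test_that("Langevin sampling satisfies equipartition in a harmonic well", {
  sys <- harmonic_particle(k = 4)
  cfg <- sim_config(dt = 0.005, gamma = 2, temperature = 1,
                    n_steps = 5e4, save_stride = 5, seed = 21)
  tr <- run_trajectory(sys, cfg, save_frames = TRUE)
  pos <- t(vapply(tr$frames, function(f) f[1, ], numeric(3)))
  v <- mean(apply(pos, 2, var))     # average the three equivalent coords
  expect_equal(v, 1 / 4, tolerance = 0.15)
  # velocities carry k_BT/2 per degree of freedom
  expect_equal(mean(tr$ekin), 1.5, tolerance = 0.15)
})

test_that("velocity-Verlet limit conserves energy at O(dt^2)", {
  sys <- bound_dimer(r = 1.1)
  v0 <- rbind(c(0.3, 0.1, 0), c(-0.3, -0.1, 0))
  drift <- vapply(c(0.002, 0.001), function(dt) {
    cfg <- sim_config(dt = dt, gamma = 0, temperature = 0,
                      n_steps = round(100 / dt), save_stride = 10, seed = 1)
    tr <- run_trajectory(sys, cfg, vel0 = v0, save_frames = FALSE)
    e <- tr$epot + tr$ekin
    max(abs(e - e[1]))
  }, numeric(1))
  expect_lt(drift[1], 1e-4)
  expect_gt(drift[1] / drift[2], 2.5)  # halving dt cuts drift ~4x
})

test_that("energy divergence aborts with a step diagnostic", {
  # a stiff bond integrated far beyond its stability limit blows up
  sys <- toy_system(rbind(c(0, 0, 0), c(2, 0, 0)),
                    c("ion", "ligand_oxygen"),
                    bonds = list(list(i = 1, j = 2,
                                      params = bond_params(100, 1))))
  cfg <- sim_config(dt = 1, gamma = 0, temperature = 0, n_steps = 1000,
                    save_stride = 10, seed = 1)
  expect_error(run_trajectory(sys, cfg, save_frames = FALSE), "step")
})

test_that("umbrella ladders reproduce the production window counts", {
  expect_length(umbrella_ladder(2, 6, 0.5, k = 20), 9)   # DFO-like layout
  expect_length(umbrella_ladder(2, 8, 0.5, k = 20), 13)  # 4HMS-like layout
  expect_equal(vapply(umbrella_ladder(2, 6, 0.5), `[[`, 0, "center"),
               seq(2, 6, 0.5))
  expect_true(all(vapply(umbrella_ladder(2, 6, 0.5), `[[`, 0, "k") == 20))
})

test_that("zero-bias windows reduce to the unbiased trajectory", {
  sys <- build_ion_ring_system()
  cfg <- sim_config(n_steps = 1000, save_stride = 10, seed = 50)
  wins <- list(umbrella_window(2, k = 0), umbrella_window(5, k = 0))
  set <- run_umbrella_set(sys, wins, cfg, equil_frac = 0, ladder = FALSE)
  for (i in 1:2) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    ref <- run_trajectory(sys, cfg_i, wins[[i]], save_frames = FALSE)
    expect_identical(set[[i]]$series, ref$series)
  }
})

test_that("stiff springs confine the CV to the Gaussian limit", {
  sys <- build_ion_ring_system()
  cfg <- sim_config(n_steps = 20000, save_stride = 5, seed = 31)
  tr <- run_umbrella_set(sys, list(umbrella_window(3, k = 1e4)), cfg)[[1]]
  expect_lt(sd(tr$series$cv_ligand), sqrt(1 / 1e4) * 1.5)
})

test_that("windows pull the CV towards their centers and overlap", {
  sys <- build_ion_ring_system()
  cfg <- sim_config(n_steps = 10000, save_stride = 10, seed = 77)
  free <- run_trajectory(sys, cfg, save_frames = FALSE)
  mu0 <- mean(free$series$cv_ligand)
  wins <- umbrella_ladder(1, 5, 0.5, k = 20)
  set <- run_umbrella_set(sys, wins, cfg)
  for (i in seq_along(wins)) {
    mu <- mean(set[[i]]$series$cv_ligand)
    lo <- min(mu0, wins[[i]]$center) - 0.35
    hi <- max(mu0, wins[[i]]$center) + 0.35
    expect_gt(mu, lo)
    expect_lt(mu, hi)
  }
  expect_true(all(window_overlap_coefficients(set) > 0))
})

test_that("equilibration discard removes the leading fraction", {
  sys <- build_ion_ring_system()
  cfg <- sim_config(n_steps = 1000, save_stride = 10, seed = 5)
  set <- run_umbrella_set(sys, list(umbrella_window(3, 20)), cfg,
                          equil_frac = 0.2)
  expect_equal(nrow(set[[1]]$series), 80)
  expect_equal(set[[1]]$series$time[1], 21 * cfg$dt * 10,
               tolerance = 1e-12)
})
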