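# shared fixtures and independent oracles, built in code at test time

# a small random system with 12-6-4 + Coulomb interactions
random_test_system <- function(n = 5, seed = 1, spread = 2.5) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * n, sd = spread), n, 3)
  # keep particles from starting inside the steep core
  for (i in seq_len(n)[-1]) {
    while (min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) -
                               pos[i, ])^2))) < 0.8)
      pos[i, ] <- rnorm(3, sd = spread)
  }
  toy_system(pos, c("ion", rep("ligand_oxygen", n - 1)),
             charges = c(4, rep(-0.5, n - 1)),
             pair_table = list(
               `ion:ligand_oxygen` = pair_params(c12 = 100, c6 = 10, c4 = 1),
               `ligand_oxygen:ligand_oxygen` = pair_params(c12 = 50, c6 = 2)))
}

# single particle in an isotropic harmonic tether (reduced units)
harmonic_particle <- function(k = 4, anchor = c(0, 0, 0)) {
  toy_system(matrix(anchor, 1, 3), "ion",
             tether = data.frame(index = 1, k = k, x = anchor[1],
                                 y = anchor[2], z = anchor[3]))
}

# bound 12-6 dimer for energy-conservation checks
bound_dimer <- function(r = 1.1) {
  toy_system(rbind(c(0, 0, 0), c(r, 0, 0)), c("ion", "ligand_oxygen"),
             pair_table = list(`ion:ligand_oxygen` = pair_params(c12 = 1,
                                                                 c6 = 2)))
}

# central finite-difference gradient of a toy system's energy
fd_forces <- function(sys, h = 1e-6) {
  n <- nrow(sys$positions)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    s1 <- sys; s1$positions[i, d] <- s1$positions[i, d] + h
    s2 <- sys; s2$positions[i, d] <- s2$positions[i, d] - h
    out[i, d] <- -(total_energy_forces(s1)$energy -
                     total_energy_forces(s2)$energy) / (2 * h)
  }
  out
}

# independent WHAM estimate: direct minimisation of the binned-WHAM dual
#   Phi(g) = -sum_i N_i g_i + sum_b M_b log sum_i N_i exp(g_i - c_ib)
# by BFGS, a different algorithmic route from the package's fixed-point
# iteration
wham_ml_reference <- function(series, breaks) {
  B <- length(breaks) - 1
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  counts <- t(sapply(series, function(tr) {
    s <- tr$series[[setdiff(names(tr$series), "time")[1]]]
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE), nbins = B)
  }))
  cmat <- t(sapply(series, function(tr)
    0.5 * tr$window$k * (centers - tr$window$center)^2))
  Ni <- rowSums(counts)
  M <- colSums(counts)
  sampled <- M > 0
  phi <- function(g) {
    f <- c(0, g)
    A <- (log(Ni) + f) - cmat
    Am <- apply(A, 2, max)
    logD <- Am + log(colSums(exp(sweep(A, 2, Am, `-`))))
    -sum(Ni * f) + sum(M[sampled] * logD[sampled])
  }
  gphi <- function(g) {
    f <- c(0, g)
    A <- (log(Ni) + f) - cmat
    Am <- apply(A, 2, max)
    W <- exp(sweep(A, 2, Am, `-`))
    D <- colSums(W)
    grad <- vapply(seq_along(f), function(j)
      -Ni[j] + sum(M[sampled] * W[j, sampled] / D[sampled]), numeric(1))
    grad[-1]
  }
  opt <- stats::optim(rep(0, nrow(counts) - 1), phi, gphi, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  f_ml <- c(0, opt$par)
  A <- (log(Ni) + f_ml) - cmat
  Am <- apply(A, 2, max)
  logD <- Am + log(colSums(exp(sweep(A, 2, Am, `-`))))
  fvals <- ifelse(sampled, -(log(M) - logD), NA)
  fvals - min(fvals, na.rm = TRUE)
}

# basin of attraction of gradient flow dx/dt = -U'(x) by dense ODE
# integration (independent oracle for quench basin assignment)
gradient_flow_basin <- function(x0, grad, t_end = 50) {
  sol <- deSolve::ode(y = c(x = x0), times = c(0, t_end),
                      func = function(t, y, p) list(-grad(y)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(sol[nrow(sol), "x"])
}

# ground-truth bin values of a 1D fes at bin centers
fes_at_centers <- function(fes, profile) fes$fun(profile$bin_centers)

# exact biased samples for a quick WHAM fixture
double_well_fixture <- function(n = 1e4, base_seed = 100, k = 20,
                                centers = seq(-2, 2, 0.5)) {
  fes <- fes_double_well()
  lapply(seq_along(centers), function(i)
    sample_biased(fes, umbrella_window(centers[i], k), n = n,
                  seed = base_seed + i))
}
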