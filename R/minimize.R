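#' Steepest-descent minimisation (generic core)
#'
#' Gradient descent with Armijo backtracking line search. Energy is
#' non-increasing at every accepted step. Convergence is declared on the
#' maximum absolute gradient component (the force threshold of
#' inherent-structure quenches, default \code{1e-4} reduced k_BT/length);
#' the Euclidean gradient norm is reported alongside.
#'
#' @param fn objective function of a numeric vector.
#' @param gr gradient function.
#' @param x0 starting point with finite \code{fn(x0)}.
#' @param force_tol convergence threshold on \code{max(abs(gr(x)))}.
#' @param max_steps iteration cap.
#' @param step0,c_armijo,shrink line-search controls: initial trial step,
#'   Armijo sufficient-decrease constant, and backtracking factor.
#' @return list: \code{x}, \code{value}, \code{grad}, \code{converged},
#'   \code{n_steps}, \code{max_force}, \code{force_norm}.
#' @export
minimize_sd <- function(fn, gr, x0, force_tol = 1e-4, max_steps = 500,
                        step0 = 0.1, c_armijo = 1e-4, shrink = 0.5) {
  x <- as.numeric(x0)
  f <- fn(x)
  if (!is.finite(f)) stop("non-finite starting energy")
  g <- gr(x)
  step <- step0
  it <- 0L
  while (it < max_steps && max(abs(g)) > force_tol) {
    it <- it + 1L
    d <- -g
    t <- step
    gd <- sum(g * d)
    repeat {
      fnew <- fn(x + t * d)
      if (is.finite(fnew) && fnew <= f + c_armijo * t * gd) break
      t <- t * shrink
      if (t < 1e-14) break
    }
    if (t < 1e-14) {  # step-size underflow without progress
      return(list(x = x, value = f, grad = g, converged = FALSE,
                  n_steps = it, max_force = max(abs(g)),
                  force_norm = sqrt(sum(g^2))))
    }
    x <- x + t * d
    f <- fn(x)
    g <- gr(x)
    step <- min(step0, t / shrink)  # grow back cautiously
  }
  list(x = x, value = f, grad = g, converged = max(abs(g)) <= force_tol,
       n_steps = it, max_force = max(abs(g)), force_norm = sqrt(sum(g^2)))
}

#' Conjugate-gradient minimisation (generic core)
#'
#' Polak-Ribiere(+) nonlinear conjugate gradients with automatic restarts
#' and a secant line search on the directional derivative (exact for
#' quadratic objectives, so a d-dimensional quadratic terminates in at
#' most d iterations), safeguarded by Armijo backtracking. On line-search
#' failure the direction is reset to steepest descent; repeated failure is
#' flagged as non-convergence.
#'
#' @inheritParams minimize_sd
#' @return list as in [minimize_sd()].
#' @export
minimize_cg <- function(fn, gr, x0, force_tol = 1e-4, max_steps = 500,
                        c_armijo = 1e-4) {
  x <- as.numeric(x0)
  f <- fn(x)
  if (!is.finite(f)) stop("non-finite starting energy")
  g <- gr(x)
  d <- -g
  it <- 0L
  fails <- 0L
  t_prev_accept <- NA_real_
  while (it < max_steps && max(abs(g)) > force_tol) {
    it <- it + 1L
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }  # restart on non-descent
    # iterative secant on phi'(t) = gr(x + t d).d until the curvature
    # condition |phi'| <= 0.1 |phi'(0)| holds (exact after one secant step
    # on quadratics)
    t <- if (is.finite(t_prev_accept)) t_prev_accept else
      min(1, 1 / max(1, sqrt(sum(d^2))))
    tp <- 0; dp <- gd
    gn <- NULL
    for (ls in 1:10) {
      gt <- gr(x + t * d)
      dphit <- sum(gt * d)
      if (is.finite(dphit) && abs(dphit) <= 0.1 * abs(gd)) { gn <- gt; break }
      tn <- if (is.finite(dphit) && abs(dphit - dp) > 1e-300)
        t - dphit * (t - tp) / (dphit - dp) else NA_real_
      if (!is.finite(tn) || tn <= 0)
        tn <- if (is.finite(dphit) && dphit > 0) t / 2 else t * 2
      tp <- t; dp <- dphit
      t <- min(max(tn, 1e-12), 1e6)
    }
    # Armijo safeguard on the energy itself
    repeat {
      fnew <- fn(x + t * d)
      if (is.finite(fnew) && fnew <= f + c_armijo * t * gd) break
      t <- t / 2
      gn <- NULL
      if (t < 1e-14) break
    }
    if (t < 1e-14) {
      fails <- fails + 1L
      if (fails >= 2L) {
        return(list(x = x, value = f, grad = g, converged = FALSE,
                    n_steps = it, max_force = max(abs(g)),
                    force_norm = sqrt(sum(g^2))))
      }
      d <- -g  # restart from steepest descent
      t_prev_accept <- NA_real_
      next
    }
    fails <- 0L
    t_prev_accept <- t
    xn <- x + t * d
    if (is.null(gn)) gn <- gr(xn)
    beta <- max(0, sum(gn * (gn - g)) / sum(g * g))  # PR+
    d <- -gn + beta * d
    x <- xn; f <- fn(x); g <- gn
  }
  list(x = x, value = f, grad = g, converged = max(abs(g)) <= force_tol,
       n_steps = it, max_force = max(abs(g)), force_norm = sqrt(sum(g^2)))
}

# objective/gradient closures over the free (finite-mass) coordinates
.sys_objective <- function(sys) {
  free <- which(is.finite(sys$masses))
  pairm <- .pair_matrix(sys); bondm <- .bond_matrix(sys)
  tethm <- .tether_matrix(sys)
  pos0 <- sys$positions
  unpack <- function(x) {
    p <- pos0
    p[free, ] <- matrix(x, ncol = 3)
    p
  }
  list(
    free = free,
    unpack = unpack,
    pack = function(sys) as.numeric(sys$positions[free, ]),
    fn = function(x) {
      r <- cpp_energy_forces(unpack(x), pairm, bondm, tethm, .rmin_guard)
      if (!r$ok) return(Inf)
      r$energy
    },
    gr = function(x) {
      r <- cpp_energy_forces(unpack(x), pairm, bondm, tethm, .rmin_guard)
      -as.numeric(r$forces[free, ])
    })
}

#' Steepest-descent quench of a toy system
#'
#' Minimises the (unbiased) potential energy over the free coordinates of
#' the system; frozen particles (infinite mass) stay fixed.
#'
#' @param sys a [toy_system()].
#' @param max_steps iteration cap.
#' @param force_tol threshold on the maximum force component.
#' @return list: \code{system} (updated positions), \code{value},
#'   \code{converged}, \code{n_steps}, \code{max_force}, \code{force_norm}.
#' @export
steepest_descent <- function(sys, max_steps = 500, force_tol = 1e-4) {
  ob <- .sys_objective(sys)
  res <- minimize_sd(ob$fn, ob$gr, ob$pack(sys), force_tol = force_tol,
                     max_steps = max_steps)
  sys$positions <- ob$unpack(res$x)
  c(list(system = sys), res[c("value", "converged", "n_steps", "max_force",
                              "force_norm")])
}

#' Conjugate-gradient quench of a toy system
#'
#' Polishes a configuration (typically the output of [steepest_descent()])
#' to the force threshold used for inherent-structure analysis,
#' \code{1e-4} reduced k_BT/length by default.
#'
#' @param sys a [toy_system()].
#' @param force_tol convergence threshold on the maximum force component.
#' @param max_steps iteration cap.
#' @param source_id identifier copied into the record.
#' @return a quench record: list with \code{system}, \code{source_id},
#'   \code{u_final}, \code{cn_final} (first CV of the system, or NA),
#'   \code{n_cg_steps}, \code{converged}, \code{max_force_final},
#'   \code{force_norm_final}.
#' @export
conjugate_gradient <- function(sys, force_tol = 1e-4, max_steps = 6000,
                               source_id = "") {
  ob <- .sys_objective(sys)
  res <- minimize_cg(ob$fn, ob$gr, ob$pack(sys), force_tol = force_tol,
                     max_steps = max_steps)
  sys$positions <- ob$unpack(res$x)
  cn <- if (length(sys$cv_specs))
    coordination_number(sys$positions, sys$cv_specs[[1]])$value else NA_real_
  list(system = sys, source_id = source_id, u_final = res$value,
       cn_final = cn, n_cg_steps = res$n_steps, converged = res$converged,
       max_force_final = res$max_force, force_norm_final = res$force_norm)
}

#' Inherent-structure scan
#'
#' Quenches a set of finite-temperature configurations to their nearest
#' local minima of the potential energy (steepest descent followed by
#' conjugate gradients) and tabulates final energy against the recomputed
#' coordination number — the potential-energy-landscape counterpart of the
#' free-energy profile. Solvent oxygens can be removed before quenching so
#' the bare complex is optimised.
#'
#' @param sys a [toy_system()] providing topology and parameters.
#' @param frames list of N x 3 position matrices (configurations of
#'   \code{sys}).
#' @param strip_solvent remove solvent oxygens before quenching
#'   (default TRUE).
#' @param sd_steps steepest-descent steps before the CG polish.
#' @param force_tol CG force threshold (default 1e-4 reduced).
#' @param cg_steps CG iteration cap.
#' @return data frame, one row per frame: \code{source_id, u_final,
#'   cn_final, n_sd_steps, n_cg_steps, converged, max_force_final,
#'   force_norm_final}. Individual quench failures are recorded
#'   (\code{converged = FALSE}); the scan continues.
#' @export
inherent_structure_scan <- function(sys, frames, strip_solvent = TRUE,
                                    sd_steps = 200, force_tol = 1e-4,
                                    cg_steps = 6000) {
  stopifnot(inherits(sys, "toy_system"), length(frames) >= 1)
  rows <- lapply(seq_along(frames), function(i) {
    s <- sys
    s$positions <- as.matrix(frames[[i]])
    if (strip_solvent) s <- strip_solvent(s)
    rec <- tryCatch({
      sd <- steepest_descent(s, max_steps = sd_steps, force_tol = force_tol)
      cg <- conjugate_gradient(sd$system, force_tol = force_tol,
                               max_steps = cg_steps,
                               source_id = sprintf("frame_%d", i))
      data.frame(source_id = cg$source_id, u_final = cg$u_final,
                 cn_final = cg$cn_final, n_sd_steps = sd$n_steps,
                 n_cg_steps = cg$n_cg_steps, converged = cg$converged,
                 max_force_final = cg$max_force_final,
                 force_norm_final = cg$force_norm_final)
    }, error = function(e)
      data.frame(source_id = sprintf("frame_%d", i), u_final = NA_real_,
                 cn_final = NA_real_, n_sd_steps = NA_integer_,
                 n_cg_steps = NA_integer_, converged = FALSE,
                 max_force_final = NA_real_, force_norm_final = NA_real_))
    rec
  })
  do.call(rbind, rows)
}
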