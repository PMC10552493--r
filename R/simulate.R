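#' Langevin simulation settings
#'
#' Reduced-unit defaults mirror a typical solvated-complex protocol: a 2 fs
#' time step maps to \code{dt = 0.002}, a thermostat time constant of
#' 2 ps^-1 to \code{gamma = 2}, and temperature is the k_BT energy unit
#' (\code{temperature = 1} is the simulated thermal energy).
#'
#' @param dt integration time step, > 0.
#' @param gamma Langevin friction, >= 0 (0 disables the thermostat, giving
#'   velocity-Verlet dynamics).
#' @param temperature target k_BT, >= 0.
#' @param n_steps number of integration steps, >= 1.
#' @param save_stride record every this many steps.
#' @param seed integer seed; trajectories are bitwise reproducible given
#'   the seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(dt = 0.002, gamma = 2, temperature = 1,
                       n_steps = 10000, save_stride = 10, seed = 1) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0, n_steps >= 1,
            save_stride >= 1)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Umbrella window
#'
#' A harmonic bias \eqn{\frac{1}{2} k (s - s_0)^2} on the system's primary
#' collective variable. The production protocol this package emulates uses
#' \code{k = 20} k_BT for every window and centers laid out in steps of
#' 0.5 along the coordination number.
#'
#' @param center bias center \eqn{s_0}.
#' @param k spring constant in k_BT per CV unit squared, >= 0.
#' @return an object of class \code{umbrella_window}.
#' @seealso [umbrella_ladder()]
#' @export
umbrella_window <- function(center, k = 20) {
  stopifnot(k >= 0)
  structure(list(center = center, k = k), class = "umbrella_window")
}

#' Ladder of umbrella windows
#'
#' Windows at \code{seq(from, to, by = step)}, all sharing spring constant
#' \code{k}. The defaults of the two chelator analogs reproduce the
#' production layouts: centers 2 to 6 (9 windows, DFO-like) and 2 to 8
#' (13 windows, 4HMS-like), step 0.5, k = 20 k_BT.
#'
#' @param from,to,step center range.
#' @param k common spring constant.
#' @return list of [umbrella_window()]s.
#' @export
umbrella_ladder <- function(from = 2, to = 6, step = 0.5, k = 20) {
  lapply(seq(from, to, by = step), umbrella_window, k = k)
}

#' Run one (optionally biased) Langevin trajectory
#'
#' Integrates the toy system with the BAOAB splitting scheme: the exact
#' Ornstein-Uhlenbeck friction/noise update is sandwiched between
#' velocity-Verlet half-steps, which gives accurate configurational
#' sampling at the mapped time step. With \code{gamma = 0} the scheme
#' reduces to velocity Verlet and conserves energy to O(dt^2). All CVs of
#' the system are recorded every \code{save_stride} steps; the harmonic
#' bias, when given, acts on the first CV.
#'
#' @param sys a [toy_system()].
#' @param cfg a [sim_config()].
#' @param window an [umbrella_window()] or NULL for an unbiased run.
#' @param save_frames record positions as well as CVs (default TRUE).
#' @param vel0 optional N x 3 initial velocities (default: Maxwell draw at
#'   the target temperature, or zero when temperature is 0).
#' @return an object of class \code{cv_series}: list with \code{series}
#'   (data frame: time, one column per CV label), \code{epot}, \code{ekin},
#'   \code{frames} (list of N x 3 matrices, if saved), \code{final_pos},
#'   \code{final_vel}, \code{window}, \code{seed}.
#' @export
run_trajectory <- function(sys, cfg, window = NULL, save_frames = TRUE,
                           vel0 = NULL) {
  stopifnot(inherits(sys, "toy_system"), inherits(cfg, "sim_config"))
  if (!is.null(window)) {
    stopifnot(inherits(window, "umbrella_window"))
    if (!length(sys$cv_specs))
      stop("umbrella bias requested but the system has no CV spec")
  }
  n <- nrow(sys$positions)
  set.seed(cfg$seed)
  if (is.null(vel0)) {
    vel0 <- matrix(0, n, 3)
    if (cfg$temperature > 0) {
      free <- is.finite(sys$masses)
      vel0[free, ] <- matrix(rnorm(3 * sum(free)), ncol = 3) *
        sqrt(cfg$temperature / sys$masses[free])
    }
  }
  res <- cpp_run_baoab(sys$positions, vel0, sys$masses, .pair_matrix(sys),
                       .bond_matrix(sys), .tether_matrix(sys), .cv_list(sys),
                       if (is.null(window)) 0 else window$k,
                       if (is.null(window)) 0 else window$center,
                       cfg$dt, cfg$gamma, cfg$temperature, cfg$n_steps,
                       cfg$save_stride, save_frames, .rmin_guard,
                       .energy_guard)
  if (!isTRUE(res$ok))
    stop(sprintf(paste0("energy divergence or particle overlap at step %d ",
                        "(min pair distance %.3g); reduce dt or soften ",
                        "the potential"), res$error_step,
                 res$min_pair_distance))
  labels <- vapply(sys$cv_specs, `[[`, "", "label")
  series <- data.frame(time = res$time)
  for (c in seq_along(labels)) series[[labels[c]]] <- res$cv[, c]
  frames <- NULL
  if (save_frames)
    frames <- lapply(seq_len(dim(res$frames)[3]),
                     function(t) t(res$frames[, , t]))
  structure(list(series = series, epot = res$epot, ekin = res$ekin,
                 frames = frames, final_pos = res$final_pos,
                 final_vel = res$final_vel, window = window,
                 seed = cfg$seed),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series: %d frames, CVs: %s\n", nrow(x$series),
              paste(setdiff(names(x$series), "time"), collapse = ", ")))
  if (!is.null(x$window))
    cat(sprintf("  window: center %.3g, k %.3g\n", x$window$center,
                x$window$k))
  invisible(x)
}

#' Run a full umbrella set
#'
#' One biased trajectory per window. Window i is seeded with
#' \code{cfg$seed + i} (reproducible and independent across windows) and,
#' following common umbrella practice, starts from the final frame of the
#' previous window so the system is dragged along the CV ladder. The first
#' \code{equil_frac} of each window's saved samples is discarded as
#' equilibration.
#'
#' @param sys a [toy_system()].
#' @param windows list of [umbrella_window()]s, non-empty.
#' @param cfg a [sim_config()]; \code{cfg$seed} is the base seed.
#' @param equil_frac fraction of saved samples discarded from the start of
#'   each window (default 0.1).
#' @param save_frames keep positions (default FALSE to save memory).
#' @param ladder start each window from the previous window's final frame
#'   (default TRUE).
#' @return list of [run_trajectory()] results, one per window, each with
#'   its window metadata attached and equilibration removed.
#' @export
run_umbrella_set <- function(sys, windows, cfg, equil_frac = 0.1,
                             save_frames = FALSE, ladder = TRUE) {
  stopifnot(length(windows) >= 1, equil_frac >= 0, equil_frac < 1)
  out <- vector("list", length(windows))
  cur <- sys
  for (i in seq_along(windows)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    tr <- tryCatch(
      run_trajectory(cur, cfg_i, windows[[i]], save_frames = save_frames),
      error = function(e)
        stop(sprintf("window %d (center %.3g): %s", i,
                     windows[[i]]$center, conditionMessage(e)), call. = FALSE))
    drop <- floor(equil_frac * nrow(tr$series))
    if (drop > 0) {
      keep <- seq(drop + 1, nrow(tr$series))
      tr$series <- tr$series[keep, , drop = FALSE]
      tr$epot <- tr$epot[keep]
      tr$ekin <- tr$ekin[keep]
      if (!is.null(tr$frames)) tr$frames <- tr$frames[keep]
    }
    out[[i]] <- tr
    if (ladder) cur$positions <- tr$final_pos
  }
  out
}
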