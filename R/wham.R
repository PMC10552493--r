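# log-sum-exp over a vector / matrix rows, NA-free
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-window sample vectors + bias parameters out of a list of cv_series
# (or plain data frames carrying window attributes)
.wham_inputs <- function(series) {
  lapply(seq_along(series), function(i) {
    tr <- series[[i]]
    if (inherits(tr, "cv_series")) {
      if (is.null(tr$window))
        stop(sprintf("series %d carries no window metadata", i))
      cols <- setdiff(names(tr$series), "time")
      list(s = tr$series[[cols[1]]],
           w = if (length(cols) > 1) tr$series[[cols[2]]] else NULL,
           k = tr$window$k, center = tr$window$center)
    } else {
      stop(sprintf("series %d is not a cv_series", i))
    }
  })
}

# effective bias energies per (window, bin): -log of the bin average of
# exp(-bias), by 5-point Gauss-Legendre quadrature within each bin. Using
# the bin average instead of the bin-center value removes the leading
# histogram-discretisation bias of stiff umbrella springs.
.bias_matrix <- function(inp, breaks) {
  B <- length(breaks) - 1
  gl_x <- c(-0.9061798459386640, -0.5384693101056831, 0,
            0.5384693101056831, 0.9061798459386640)
  gl_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891) / 2
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  half <- diff(breaks) / 2
  nodes <- outer(half, gl_x) + mid   # B x 5
  t(vapply(inp, function(w) {
    if (w$k == 0) return(rep(0, B))
    cb <- 0.5 * w$k * (nodes - w$center)^2
    m <- apply(cb, 1, min)
    m - log((exp(-(cb - m)) %*% gl_w)[, 1])
  }, numeric(B)))
}

# self-consistent binned WHAM solve; returns offsets f (gauge f[1] = 0),
# log-probabilities per bin, iteration count and residual
.wham_solve <- function(counts, cmat, tol, max_iter, f_init = NULL) {
  W <- nrow(counts)
  Ni <- rowSums(counts)
  tot <- colSums(counts)
  sampled <- tot > 0
  logN <- log(Ni)
  log_tot <- ifelse(sampled, log(tot), -Inf)
  f <- if (is.null(f_init)) rep(0, W) else f_init
  iter <- 0L
  resid <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    # log denominator per bin: lse_i [ log Ni + f_i - c_ib ]
    A <- (logN + f) - cmat            # W x B
    Am <- apply(A, 2, max)
    log_den <- Am + log(colSums(exp(sweep(A, 2, Am, `-`))))
    log_p <- log_tot - log_den
    log_p <- log_p - .lse(log_p[sampled])
    # f_i = -lse_b [ log p_b - c_ib ]
    Bm <- sweep(-cmat, 2, log_p, `+`)  # W x B
    Bm[, !sampled] <- -Inf
    rm <- apply(Bm, 1, max)
    f_new <- -(rm + log(rowSums(exp(Bm - rm))))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid <= tol) break
  }
  list(f = f, log_p = log_p, sampled = sampled, n_iterations = iter,
       residual = resid, converged = resid <= tol)
}

# connected components of windows linked by sharing a sampled bin
.window_components <- function(counts) {
  W <- nrow(counts)
  parent <- seq_len(W)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (b in seq_len(ncol(counts))) {
    w <- which(counts[, b] > 0)
    if (length(w) > 1)
      for (j in w[-1]) parent[find(j)] <- find(w[1])
  }
  length(unique(vapply(seq_len(W), find, integer(1))))
}

#' 1D WHAM free-energy profile
#'
#' Reconstructs the unbiased free-energy profile F(s) in k_BT from biased
#' coordination-number histograms by iterating the WHAM self-consistency
#' equations
#' \deqn{p_b \propto \frac{\sum_i n_{ib}}{\sum_i N_i e^{f_i - c_{ib}}},
#'   \qquad e^{-f_i} = \sum_b p_b e^{-c_{ib}},}
#' where \eqn{c_{ib}} is the effective bias energy of window i in bin b
#' (the minus-log bin average of \eqn{e^{-bias}}, by Gauss-Legendre
#' quadrature within the bin, which removes the leading histogram
#' discretisation bias of stiff springs). Iteration stops when the largest
#' change in any window offset falls below \code{tol}. The profile uses
#' the min-zero convention; bins with no counts are reported as unsampled
#' (NA), never interpolated.
#'
#' @param series list of [run_trajectory()] / [sample_biased()] results,
#'   each carrying its umbrella window (k = 0 allowed: unbiased window).
#' @param bins number of bins (default 100) spanning
#'   \code{range(samples) + c(-0.25, 0.25)}, or an explicit vector of
#'   break points.
#' @param tol convergence threshold on the max offset change (k_BT).
#' @param max_iter iteration cap; exceeding it flags non-convergence.
#' @return an object of class \code{fes_profile}: list with
#'   \code{bin_centers}, \code{f_values} (k_BT, NA where unsampled),
#'   \code{f_errors} (NA until [bootstrap_errors()]), \code{unsampled},
#'   \code{window_offsets}, \code{converged}, \code{n_iterations},
#'   \code{residual}, \code{n_components} (>1 flags disconnected window
#'   histograms), \code{breaks}, \code{windows}, \code{counts}.
#' @references Kumar et al., J. Comput. Chem. 13, 1011 (1992) (the WHAM
#'   equations); Grossfield's WHAM implementation conventions.
#' @export
wham_1d <- function(series, bins = 100, tol = 1e-8, max_iter = 1e5) {
  inp <- .wham_inputs(series)
  if (!length(inp)) stop("need at least one window")
  svals <- lapply(inp, `[[`, "s")
  if (any(vapply(svals, length, 0L) == 0))
    stop("every window must contain at least one sample")
  breaks <- if (length(bins) > 1) bins else {
    rng <- range(unlist(svals))
    seq(rng[1] - 0.25, rng[2] + 0.25, length.out = bins + 1)
  }
  B <- length(breaks) - 1
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  counts <- t(vapply(svals, function(s) {
    idx <- findInterval(s, breaks, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= B], nbins = B)
  }, numeric(B)))
  cmat <- .bias_matrix(inp, breaks)
  sol <- .wham_solve(counts, cmat, tol, max_iter)
  if (!sol$converged)
    warning(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                    sol$n_iterations, sol$residual))
  ncomp <- .window_components(counts)
  if (ncomp > 1)
    warning(sprintf("window histograms form %d disconnected components; ",
                    ncomp),
            "relative free energies between components are meaningless")
  f <- -sol$log_p
  f[!sol$sampled] <- NA_real_
  f <- f - min(f, na.rm = TRUE)
  structure(list(bin_centers = centers, f_values = f,
                 f_errors = rep(NA_real_, B), unsampled = !sol$sampled,
                 window_offsets = sol$f, converged = sol$converged,
                 n_iterations = sol$n_iterations, residual = sol$residual,
                 n_components = ncomp, breaks = breaks,
                 windows = lapply(inp, function(w) w[c("k", "center")]),
                 counts = counts, tol = tol, max_iter = max_iter),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf(paste0("fes_profile: %d bins (%d sampled), %d windows, ",
                     "converged: %s (%d iterations)\n"),
              length(x$f_values), sum(!x$unsampled), length(x$windows),
              x$converged, x$n_iterations))
  cat(sprintf("  F range %.3g .. %.3g k_BT (min-zero)\n",
              min(x$f_values, na.rm = TRUE), max(x$f_values, na.rm = TRUE)))
  invisible(x)
}

#' Monte Carlo bootstrap errors for a WHAM profile
#'
#' Re-estimates the profile on \code{n_boot} bootstrap replicates of the
#' input series and reports the per-bin standard deviation. To respect
#' the autocorrelation of the underlying trajectories, each replicate
#' resamples contiguous blocks (moving-block bootstrap, default block
#' length 1/20 of the series) with replacement within each window.
#' Replicate solves are warm-started from the full-data window offsets.
#'
#' @param series the same list passed to [wham_1d()].
#' @param profile the [wham_1d()] result whose binning and settings are
#'   reused.
#' @param n_boot number of replicates, >= 2.
#' @param seed integer seed; errors are deterministic given the seed.
#' @param block_frac block length as a fraction of each series length.
#' @param block_len explicit block length (overrides \code{block_frac});
#'   must not exceed any series length.
#' @param resample set FALSE to disable resampling (all replicates see the
#'   original data; errors are then exactly zero).
#' @return the profile with \code{f_errors} filled in (NA where a bin was
#'   sampled in fewer than 2 replicates) and an \code{n_boot} field.
#' @export
bootstrap_errors <- function(series, profile, n_boot = 50, seed = 1,
                             block_frac = 1 / 20, block_len = NULL,
                             resample = TRUE) {
  stopifnot(inherits(profile, "fes_profile"), n_boot >= 2)
  inp <- .wham_inputs(series)
  breaks <- profile$breaks
  B <- length(breaks) - 1
  centers <- profile$bin_centers
  cmat <- .bias_matrix(inp, breaks)
  lens <- vapply(inp, function(w) length(w$s), 0L)
  if (!is.null(block_len) && any(block_len > lens))
    stop("block length exceeds a series length")
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_boot, B)
  for (r in seq_len(n_boot)) {
    counts <- t(vapply(seq_along(inp), function(i) {
      s <- inp[[i]]$s
      if (resample) {
        L <- lens[i]
        bl <- if (!is.null(block_len)) block_len else max(1L, floor(L * block_frac))
        starts <- sample.int(L - bl + 1L, ceiling(L / bl), replace = TRUE)
        idx <- as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(L)]
        s <- s[idx]
      }
      idx <- findInterval(s, breaks, rightmost.closed = TRUE)
      tabulate(idx[idx >= 1 & idx <= B], nbins = B)
    }, numeric(B)))
    sol <- .wham_solve(counts, cmat, profile$tol, profile$max_iter,
                       f_init = profile$window_offsets)
    f <- -sol$log_p
    f[!sol$sampled] <- NA_real_
    # align the replicate to the reference profile by its mean offset over
    # commonly sampled bins; the min-zero gauge would otherwise inject the
    # noise of whichever single bin happens to be the minimum into every
    # other bin's error
    common <- !is.na(f) & !is.na(profile$f_values)
    reps[r, ] <- f - mean((f - profile$f_values)[common])
  }
  nok <- colSums(!is.na(reps))
  err <- rep(NA_real_, B)
  err[nok >= 2] <- apply(reps[, nok >= 2, drop = FALSE], 2, sd, na.rm = TRUE)
  profile$f_errors <- err
  profile$n_boot <- n_boot
  profile
}

#' Histogram overlap between adjacent umbrella windows
#'
#' Overlap coefficient (sum of bin-wise minima of the two normalised
#' histograms, in [0, 1]) between each pair of adjacent windows — the
#' sampling precondition WHAM relies on. Zero overlap anywhere means the
#' combined profile has disconnected components.
#'
#' @param series list of window series (as for [wham_1d()]), assumed
#'   ordered along the ladder.
#' @param bins bin count or break vector (default 100 bins over the data).
#' @return numeric vector of length \code{length(series) - 1}.
#' @export
window_overlap_coefficients <- function(series, bins = 100) {
  inp <- .wham_inputs(series)
  svals <- lapply(inp, `[[`, "s")
  breaks <- if (length(bins) > 1) bins else {
    rng <- range(unlist(svals))
    seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1)
  }
  B <- length(breaks) - 1
  h <- lapply(svals, function(s) {
    idx <- findInterval(s, breaks, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= B], nbins = B) / length(s)
  })
  vapply(seq_len(length(h) - 1), function(i)
    sum(pmin(h[[i]], h[[i + 1]])), numeric(1))
}

# moving-block bootstrap indices for a series of length L
.block_indices <- function(L, bl) {
  starts <- sample.int(L - bl + 1L, ceiling(L / bl), replace = TRUE)
  as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(L)]
}

#' Monte Carlo bootstrap errors for a 2D surface
#'
#' Block-resamples the input series (jointly in both CV columns), re-runs
#' the 1D WHAM solve and the 2D reweighting per replicate, and reports
#' the per-bin standard deviation of the surface.
#'
#' @inheritParams bootstrap_errors
#' @param surface the [reweight_2d()] result whose grid is reused.
#' @return the surface with an \code{f_errors} matrix added (NA where a
#'   bin was sampled in fewer than 2 replicates).
#' @export
bootstrap_errors_2d <- function(series, profile, surface, n_boot = 50,
                                seed = 1, block_frac = 1 / 20,
                                block_len = NULL, resample = TRUE) {
  stopifnot(inherits(profile, "fes_profile"), inherits(surface, "fes_surface"),
            n_boot >= 2)
  inp <- .wham_inputs(series)
  lens <- vapply(inp, function(w) length(w$s), 0L)
  if (!is.null(block_len) && any(block_len > lens))
    stop("block length exceeds a series length")
  breaks <- profile$breaks
  B <- length(breaks) - 1
  cmat <- .bias_matrix(inp, breaks)
  set.seed(as.integer(seed))
  reps <- array(NA_real_, c(n_boot, nrow(surface$f_values),
                            ncol(surface$f_values)))
  for (r in seq_len(n_boot)) {
    rep_series <- lapply(seq_along(inp), function(i) {
      s <- inp[[i]]$s; w <- inp[[i]]$w
      if (resample) {
        bl <- if (!is.null(block_len)) block_len else
          max(1L, floor(lens[i] * block_frac))
        idx <- .block_indices(lens[i], bl)
        s <- s[idx]; w <- w[idx]
      }
      structure(list(series = data.frame(time = seq_along(s), cv = s,
                                         cv2 = w),
                     window = umbrella_window(inp[[i]]$center, inp[[i]]$k)),
                class = "cv_series")
    })
    counts <- t(vapply(rep_series, function(tr) {
      idx <- findInterval(tr$series$cv, breaks, rightmost.closed = TRUE)
      tabulate(idx[idx >= 1 & idx <= B], nbins = B)
    }, numeric(B)))
    sol <- .wham_solve(counts, cmat, profile$tol, profile$max_iter,
                       f_init = profile$window_offsets)
    rep_prof <- profile
    rep_prof$window_offsets <- sol$f
    rep_prof$converged <- sol$converged
    rs <- reweight_2d(rep_series, rep_prof, bins2 = surface$breaks2)
    # mean-align to the reference surface (same gauge reasoning as in 1D)
    common <- !is.na(rs$f_values) & !is.na(surface$f_values)
    reps[r, , ] <- rs$f_values - mean((rs$f_values - surface$f_values)[common])
  }
  nok <- apply(reps, c(2, 3), function(v) sum(!is.na(v)))
  err <- apply(reps, c(2, 3), sd, na.rm = TRUE)
  err[nok < 2] <- NA_real_
  surface$f_errors <- err
  surface$n_boot <- n_boot
  surface
}

#' Reweight umbrella data onto a 2D free-energy surface
#'
#' Builds a surface over (primary CV, secondary CV) from 1D-biased
#' simulations. Each frame j of window i receives the WHAM frame weight
#' \deqn{w_j \propto \Big[\sum_k N_k\, e^{f_k - c_k(s_j)}\Big]^{-1}}
#' (the converged window offsets \eqn{f_k} come from the 1D profile),
#' which removes the bias consistently across windows; the weighted 2D
#' histogram then gives \eqn{F(s, u) = -\ln \sum_j w_j} per bin, min-zero.
#' Marginalising the surface over the secondary axis reproduces the 1D
#' profile on well-sampled bins.
#'
#' @param series list of series whose frames carry both CV values.
#' @param profile a converged [wham_1d()] result for the same series.
#' @param bins2 number of secondary-axis bins (default 40) spanning the
#'   secondary samples +/- 0.25, or an explicit break vector.
#' @return an object of class \code{fes_surface}: list with
#'   \code{primary_centers}, \code{secondary_centers}, \code{f_values}
#'   (matrix, NA where unsampled), \code{unsampled}, \code{n_eff}
#'   (effective counts per bin), \code{breaks1}, \code{breaks2}.
#' @export
reweight_2d <- function(series, profile, bins2 = 40) {
  stopifnot(inherits(profile, "fes_profile"))
  if (!profile$converged) stop("1D profile must be converged before reweighting")
  inp <- .wham_inputs(series)
  for (i in seq_along(inp))
    if (is.null(inp[[i]]$w))
      stop(sprintf("window %d has no secondary CV column", i))
  breaks1 <- profile$breaks
  wall <- unlist(lapply(inp, `[[`, "w"))
  breaks2 <- if (length(bins2) > 1) bins2 else
    seq(min(wall) - 0.25, max(wall) + 0.25, length.out = bins2 + 1)
  B1 <- length(breaks1) - 1; B2 <- length(breaks2) - 1
  Ni <- vapply(inp, function(w) length(w$s), 0L)
  f <- profile$window_offsets
  # frame weights must share one normalisation across all windows, so the
  # log-weights are assembled globally first
  s_all <- unlist(lapply(inp, `[[`, "s"))
  w_all <- unlist(lapply(inp, `[[`, "w"))
  A <- vapply(seq_along(inp), function(k)
    log(Ni[k]) + f[k] - 0.5 * inp[[k]]$k * (s_all - inp[[k]]$center)^2,
    numeric(length(s_all)))
  A <- matrix(A, nrow = length(s_all))
  m <- apply(A, 1, max)
  logw <- -(m + log(rowSums(exp(A - m))))
  wt <- exp(logw - max(logw))
  i1 <- findInterval(s_all, breaks1, rightmost.closed = TRUE)
  i2 <- findInterval(w_all, breaks2, rightmost.closed = TRUE)
  ok <- i1 >= 1 & i1 <= B1 & i2 >= 1 & i2 <= B2
  Wsum <- matrix(0, B1, B2)
  W2sum <- matrix(0, B1, B2)
  cell <- (i2[ok] - 1L) * B1 + i1[ok]
  agg <- rowsum(cbind(wt[ok], wt[ok]^2), cell)
  cells <- as.integer(rownames(agg))
  Wsum[cells] <- agg[, 1]
  W2sum[cells] <- agg[, 2]
  unsampled <- Wsum == 0
  fmat <- -log(Wsum)
  fmat[unsampled] <- NA_real_
  fmat <- fmat - min(fmat, na.rm = TRUE)
  neff <- ifelse(W2sum > 0, Wsum^2 / W2sum, 0)
  structure(list(primary_centers = (head(breaks1, -1) + tail(breaks1, -1)) / 2,
                 secondary_centers = (head(breaks2, -1) + tail(breaks2, -1)) / 2,
                 f_values = fmat, unsampled = unsampled, n_eff = neff,
                 breaks1 = breaks1, breaks2 = breaks2),
            class = "fes_surface")
}

#' @export
print.fes_surface <- function(x, ...) {
  cat(sprintf("fes_surface: %d x %d bins (%d sampled)\n",
              nrow(x$f_values), ncol(x$f_values), sum(!x$unsampled)))
  invisible(x)
}

#' Marginalise a 2D surface onto its primary axis
#'
#' Computes \eqn{-\ln \sum_u e^{-F(s,u)}} over the secondary axis,
#' min-zero shifted — the consistency check against the 1D profile.
#'
#' @param surface a [reweight_2d()] result.
#' @return numeric vector of marginal free energies (NA where the whole
#'   row is unsampled).
#' @export
fes_marginal <- function(surface) {
  stopifnot(inherits(surface, "fes_surface"))
  m <- apply(surface$f_values, 1, function(row) {
    if (all(is.na(row))) return(NA_real_)
    -.lse(-row[!is.na(row)])
  })
  m - min(m, na.rm = TRUE)
}
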