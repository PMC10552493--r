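#' Ground-truth free-energy landscape
#'
#' Wraps a known free-energy function F0 over one or two CVs, with domain
#' bounds and serialisable parameters, for generating exact biased samples
#' and validating estimators against a controlled truth.
#'
#' @param fun function of one CV value (1D) or of (s, w) (2D),
#'   vectorised; returns free energy in k_BT.
#' @param lower,upper domain bounds (length 1 for 1D, 2 for 2D).
#' @param label short family name.
#' @param params named list of the parameters that generated \code{fun}.
#' @return an object of class \code{ground_truth_fes}.
#' @export
ground_truth_fes <- function(fun, lower, upper, label = "custom",
                             params = list()) {
  stopifnot(is.function(fun), length(lower) == length(upper),
            length(lower) %in% 1:2, all(upper > lower))
  structure(list(fun = fun, lower = lower, upper = upper, label = label,
                 params = params, ndim = length(lower)),
            class = "ground_truth_fes")
}

#' Double-well ground truth
#'
#' The default validation landscape \eqn{F_0(s) = h (s^2 - 1)^2} (h = 8
#' k_BT), mimicking the open-vs-closed two-basin phenomenology of a
#' chelation free-energy profile: two minima separated by a barrier of
#' height h.
#'
#' @param height barrier height h in k_BT.
#' @param lower,upper domain bounds.
#' @return a [ground_truth_fes()].
#' @export
fes_double_well <- function(height = 8, lower = -2.5, upper = 2.5) {
  ground_truth_fes(function(s) height * (s^2 - 1)^2, lower, upper,
                   label = "double_well", params = list(height = height))
}

#' Separable 2D ground truth: double well + harmonic
#'
#' \eqn{F_0(s, w) = h (s^2 - 1)^2 + a (w - w_0)^2}: the double-well
#' primary CV of [fes_double_well()] joined to a harmonic secondary CV
#' (emulating a water-coordination count fluctuating about \eqn{w_0}).
#' Defaults: h = 8, a = 2, w0 = 4.
#'
#' @param height,a,w0 family parameters.
#' @param lower,upper length-2 domain bounds.
#' @return a [ground_truth_fes()].
#' @export
fes_double_well_2d <- function(height = 8, a = 2, w0 = 4,
                               lower = c(-2.5, 1), upper = c(2.5, 7)) {
  ground_truth_fes(function(s, w) height * (s^2 - 1)^2 + a * (w - w0)^2,
                   lower, upper, label = "double_well_2d",
                   params = list(height = height, a = a, w0 = w0))
}

#' Exact i.i.d. samples from a biased ground-truth density
#'
#' Draws from \eqn{p(s) \propto \exp[-(F_0(s) + \frac{1}{2}k(s-s_0)^2)]}
#' by inverse-CDF sampling on a dense grid (1D), or by sampling the
#' gridded marginal of s followed by the conditional of the secondary CV
#' (2D; the bias acts on s only). Deterministic given the seed. This is
#' the reference sampler for estimator validation: its output is exactly
#' distributed (up to grid resolution) as an infinitely long, perfectly
#' decorrelated umbrella simulation.
#'
#' @param fes a [ground_truth_fes()].
#' @param window an [umbrella_window()].
#' @param n number of samples (0 gives an empty series with metadata).
#' @param seed integer seed.
#' @param grid_n grid resolution per axis (default 8192 in 1D,
#'   1024 x 512 in 2D).
#' @return a \code{cv_series} whose \code{series} data frame has columns
#'   \code{time, cv} (1D) or \code{time, cv, cv2} (2D), carrying the
#'   window metadata.
#' @export
sample_biased <- function(fes, window, n, seed = 1, grid_n = NULL) {
  stopifnot(inherits(fes, "ground_truth_fes"),
            inherits(window, "umbrella_window"), n >= 0)
  set.seed(as.integer(seed))
  if (fes$ndim == 1) {
    gn <- if (is.null(grid_n)) 8192L else as.integer(grid_n)
    sg <- seq(fes$lower, fes$upper, length.out = gn)
    logp <- -(fes$fun(sg) + 0.5 * window$k * (sg - window$center)^2)
    logp <- logp - max(logp)
    p <- exp(logp)
    if (!all(is.finite(p)) || sum(p) == 0)
      stop("biased density is not integrable on the domain")
    cdf <- cumsum((p[-1] + p[-gn]) / 2 * diff(sg))
    cdf <- c(0, cdf / cdf[gn - 1])
    s <- if (n > 0) approx(cdf, sg, xout = runif(n), ties = "ordered")$y
         else numeric(0)
    df <- data.frame(time = seq_len(n), cv = s)
  } else {
    gn <- if (is.null(grid_n)) c(1024L, 512L) else as.integer(grid_n)
    sg <- seq(fes$lower[1], fes$upper[1], length.out = gn[1])
    wg <- seq(fes$lower[2], fes$upper[2], length.out = gn[2])
    logp <- -outer(sg, wg, fes$fun)
    logp <- logp - 0.5 * window$k * (sg - window$center)^2
    logp <- logp - max(logp)
    p <- exp(logp)
    if (!all(is.finite(p)) || sum(p) == 0)
      stop("biased density is not integrable on the domain")
    pmarg <- rowSums(p)
    cdf_s <- cumsum((pmarg[-1] + pmarg[-gn[1]]) / 2 * diff(sg))
    cdf_s <- c(0, cdf_s / cdf_s[gn[1] - 1])
    if (n > 0) {
      s <- approx(cdf_s, sg, xout = runif(n), ties = "ordered")$y
      # conditional of w given the nearest s grid row, via precomputed
      # per-row CDFs and manual linear inversion
      irow <- pmin(gn[1], pmax(1L, round((s - fes$lower[1]) /
        (fes$upper[1] - fes$lower[1]) * (gn[1] - 1)) + 1L))
      dw <- diff(wg)
      cdfm <- t(apply(p, 1, function(pr) {
        cw <- cumsum(c(0, (pr[-1] + pr[-gn[2]]) / 2 * dw))
        cw / cw[gn[2]]
      }))
      u <- runif(n)
      w <- vapply(seq_len(n), function(j) {
        cw <- cdfm[irow[j], ]
        i0 <- findInterval(u[j], cw, rightmost.closed = TRUE)
        i0 <- min(max(i0, 1L), gn[2] - 1L)
        frac <- (u[j] - cw[i0]) / max(cw[i0 + 1] - cw[i0], 1e-300)
        wg[i0] + frac * dw[i0]
      }, numeric(1))
    } else s <- w <- numeric(0)
    df <- data.frame(time = seq_len(n), cv = s, cv2 = w)
  }
  structure(list(series = df, window = window, seed = seed,
                 fes_label = fes$label, fes_params = fes$params),
            class = "cv_series")
}

#' Brute-force free-energy profile by grid quadrature
#'
#' The independent oracle for low-dimensional systems: with all particles
#' frozen except one free particle moving in \code{dims} dimensions, the
#' configurational integral is evaluated on a dense grid,
#' \deqn{F(s_b) = -\ln \sum_{x:\, CN(x) \in bin_b} e^{-U(x)},}
#' min-zero shifted. Refuses more than 3 free coordinates. A convergence
#' report (max bin change when the grid is halved) is attached.
#'
#' @param sys a [toy_system()] with exactly one finite-mass particle.
#' @param spec the [cv_spec()] defining the CV (defaults to the system's
#'   first CV).
#' @param breaks CV bin breaks (vector), e.g. a [wham_1d()] profile's.
#' @param box 2 x dims matrix (rows: lower, upper) of the free particle's
#'   integration box.
#' @param n_grid grid points per dimension (default 101).
#' @param dims number of free coordinates, 1..3 (default 3); remaining
#'   coordinates stay at their current values.
#' @param check_convergence also evaluate at half resolution and report
#'   \code{max_refinement_change} (default TRUE).
#' @return an object of class \code{fes_profile} (errors NA, offsets NA)
#'   with an extra \code{max_refinement_change} field.
#' @export
reference_fes_quadrature <- function(sys, spec = NULL, breaks, box,
                                     n_grid = 101, dims = 3,
                                     check_convergence = TRUE) {
  stopifnot(inherits(sys, "toy_system"), dims >= 1, dims <= 3)
  free <- which(is.finite(sys$masses))
  if (length(free) != 1)
    stop("quadrature oracle requires exactly one free (finite-mass) particle")
  if (is.null(spec)) spec <- sys$cv_specs[[1]]
  box <- matrix(box, nrow = 2)
  stopifnot(ncol(box) == dims)

  eval_grid <- function(ng) {
    axes <- lapply(seq_len(dims), function(d)
      seq(box[1, d], box[2, d], length.out = ng))
    g <- as.matrix(expand.grid(axes))
    pos <- sys$positions
    others <- setdiff(seq_len(nrow(pos)), free)
    # energy of the free particle against all frozen ones + its tether
    u <- numeric(nrow(g))
    xyz <- matrix(rep(pos[free, ], each = nrow(g)), ncol = 3)
    xyz[, seq_len(dims)] <- g
    for (j in others) {
      key <- .role_key(sys$roles[free], sys$roles[j])
      p <- sys$pair_table[[key]]
      qq <- sys$coulomb * sys$charges[free] * sys$charges[j]
      if (is.null(p) && qq == 0) next
      r <- sqrt((xyz[, 1] - pos[j, 1])^2 + (xyz[, 2] - pos[j, 2])^2 +
                  (xyz[, 3] - pos[j, 3])^2)
      r <- pmax(r, .rmin_guard)
      if (!is.null(p)) {
        inside <- r < p$cutoff
        u[inside] <- u[inside] + p$c12 / r[inside]^12 - p$c6 / r[inside]^6 -
          p$c4 / r[inside]^4 + qq / r[inside]
      } else u <- u + qq / r
    }
    if (!is.null(sys$tether)) {
      tr <- sys$tether[sys$tether$index == free, , drop = FALSE]
      for (t in seq_len(nrow(tr)))
        u <- u + 0.5 * tr$k[t] * ((xyz[, 1] - tr$x[t])^2 +
                                    (xyz[, 2] - tr$y[t])^2 +
                                    (xyz[, 3] - tr$z[t])^2)
    }
    # CV value over the grid
    cn <- numeric(nrow(g))
    if (free == spec$center_particle) {
      for (j in spec$member_particles) {
        d <- sqrt((xyz[, 1] - pos[j, 1])^2 + (xyz[, 2] - pos[j, 2])^2 +
                    (xyz[, 3] - pos[j, 3])^2)
        cn <- cn + switch_weight(d, spec$switching)
      }
    } else {
      fixed <- 0
      for (j in spec$member_particles) {
        if (j == free) next
        d <- sqrt(sum((pos[spec$center_particle, ] - pos[j, ])^2))
        fixed <- fixed + switch_weight(d, spec$switching)
      }
      if (free %in% spec$member_particles) {
        d <- sqrt((xyz[, 1] - pos[spec$center_particle, 1])^2 +
                    (xyz[, 2] - pos[spec$center_particle, 2])^2 +
                    (xyz[, 3] - pos[spec$center_particle, 3])^2)
        cn <- fixed + switch_weight(d, spec$switching)
      } else cn <- rep(fixed, nrow(g))
    }
    B <- length(breaks) - 1
    idx <- findInterval(cn, breaks, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= B
    w <- exp(-(u - min(u)))
    mass <- rowsum(w[ok], idx[ok])
    fb <- rep(NA_real_, B)
    fb[as.integer(rownames(mass))] <- -log(mass[, 1])
    fb - min(fb, na.rm = TRUE)
  }

  f <- eval_grid(n_grid)
  refine <- NA_real_
  if (check_convergence) {
    ng2 <- max(11, n_grid %/% 2)
    if (ng2 %% 2 == 0) ng2 <- ng2 + 1  # keep symmetry planes on-grid
    f2 <- eval_grid(ng2)
    refine <- max(abs(f - f2), na.rm = TRUE)
  }
  B <- length(breaks) - 1
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  structure(list(bin_centers = centers, f_values = f,
                 f_errors = rep(NA_real_, B), unsampled = is.na(f),
                 window_offsets = NULL, converged = TRUE,
                 n_iterations = 0L, residual = 0,
                 n_components = 1L, breaks = breaks, windows = list(),
                 counts = NULL, tol = NA_real_, max_iter = NA_real_,
                 max_refinement_change = refine),
            class = "fes_profile")
}
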