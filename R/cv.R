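#' Switching-function parameters
#'
#' Parameters of the rational switching function
#' \deqn{s(d) = \frac{1 - (d/r_0)^n}{1 - (d/r_0)^m},}
#' a smooth, strictly decreasing map from distance to a (0, 1] bonding
#' weight. The removable singularity at \eqn{d = r_0} equals \eqn{n/m}
#' exactly (0.5 for the default exponents 6/12); the far tail decays as
#' \eqn{(r_0/d)^{m-n}}.
#'
#' @param r0 cutoff parameter of the switching function, > 0. Defaults used
#'   in this package: 5 (reduced) for ligand-oxygen coordination, 2.5 for
#'   water-oxygen coordination.
#' @param n_exp,m_exp positive integer exponents with \code{m_exp > n_exp}.
#' @return an object of class \code{switching_params}.
#' @export
switching_params <- function(r0, n_exp = 6L, m_exp = 12L) {
  n_exp <- as.integer(n_exp); m_exp <- as.integer(m_exp)
  stopifnot(r0 > 0, n_exp >= 1, m_exp > n_exp)
  structure(list(r0 = r0, n_exp = n_exp, m_exp = m_exp),
            class = "switching_params")
}

#' Coordination-number CV specification
#'
#' Defines a coordination number \eqn{CN = \sum_i s(d_i)} of switching
#' weights over the distances from one center particle (the ion) to a set
#' of member particles (ligand oxygens, or solvent oxygens for the water
#' coordination number).
#'
#' @param center_particle index of the center (the ion).
#' @param member_particles indices of candidate coordinating particles;
#'   non-empty and not containing the center.
#' @param switching a [switching_params()].
#' @param label column label used in COLVAR output (e.g. "cv_ligand").
#' @return an object of class \code{cv_spec}.
#' @export
cv_spec <- function(center_particle, member_particles, switching,
                    label = "cv") {
  stopifnot(inherits(switching, "switching_params"),
            length(member_particles) >= 1,
            !(center_particle %in% member_particles))
  structure(list(center_particle = as.integer(center_particle),
                 member_particles = as.integer(member_particles),
                 switching = switching, label = label),
            class = "cv_spec")
}

#' Rational switching function
#'
#' Evaluates the switching weight \code{s(d)} (and optionally its
#' derivative) for distances \code{d >= 0}. The implementation uses the
#' geometric-sum factorisation of the rational form, which is exact and
#' finite for all d including \code{d = r0}.
#'
#' @param d distances, >= 0; vectorised.
#' @param p a [switching_params()].
#' @param deriv if TRUE also return ds/dd.
#' @return weights in (0, 1], or a two-column matrix \code{(s, dsdd)}.
#' @export
switch_weight <- function(d, p, deriv = FALSE) {
  stopifnot(inherits(p, "switching_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  out <- cpp_switch(as.numeric(d), p$r0, p$n_exp, p$m_exp)
  if (deriv) {
    colnames(out) <- c("s", "dsdd")
    out
  } else out[, 1]
}

#' Coordination number with analytic gradients
#'
#' Computes \eqn{CN = \sum_i s(d_i)} over the CV's member particles and the
#' full per-particle gradient matrix. Gradients sum to zero over particles
#' (translational invariance) and the value is invariant under rigid-body
#' transforms.
#'
#' @param frame N x 3 position matrix (or a [toy_system()], whose positions
#'   are used).
#' @param spec a [cv_spec()].
#' @return list with \code{value} and \code{gradient} (N x 3).
#' @export
coordination_number <- function(frame, spec) {
  stopifnot(inherits(spec, "cv_spec"))
  pos <- if (inherits(frame, "toy_system")) frame$positions else as.matrix(frame)
  stopifnot(max(spec$center_particle, spec$member_particles) <= nrow(pos))
  d2 <- colSums((t(pos[spec$member_particles, , drop = FALSE]) -
                   pos[spec$center_particle, ])^2)
  if (any(d2 < .rmin_guard^2))
    stop("a member particle coincides with the CV center (gradient singularity)")
  res <- cpp_coordination(pos, spec$center_particle,
                          as.integer(spec$member_particles),
                          spec$switching$r0, spec$switching$n_exp,
                          spec$switching$m_exp)
  list(value = res$value, gradient = res$gradient)
}

#' Chelate-ring angles at the donor oxygen
#'
#' For each (ion, O, X) index triple, returns the angle at the oxygen
#' vertex between the O->ion and O->X vectors, in degrees. This is the
#' convention of ion-oxygen-nitrogen / ion-oxygen-carbon chelate angles.
#'
#' @param frame N x 3 position matrix or [toy_system()].
#' @param triplets list of length-3 index vectors \code{c(ion, O, X)}.
#' @return numeric vector of angles in [0, 180] degrees.
#' @export
chelate_angles <- function(frame, triplets) {
  pos <- if (inherits(frame, "toy_system")) frame$positions else as.matrix(frame)
  vapply(triplets, function(tr) {
    stopifnot(length(tr) == 3, length(unique(tr)) == 3)
    v1 <- pos[tr[1], ] - pos[tr[2], ]
    v2 <- pos[tr[3], ] - pos[tr[2], ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < .rmin_guard || n2 < .rmin_guard)
      stop("zero-length vector at the oxygen vertex")
    acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }, numeric(1))
}

#' Partial coordination number n(r)
#'
#' Sharp (step-function) cumulative coordination count: the mean over
#' trajectory frames of the number of member particles within distance r
#' of the center, evaluated on a grid of radii. Distinct from the smooth
#' switching-weighted [coordination_number()].
#'
#' @param traj list of N x 3 position matrices (or a single matrix).
#' @param center center particle index.
#' @param members member particle indices.
#' @param r_grid radii, sorted ascending.
#' @return data frame with columns \code{r} and \code{n} (mean counts).
#' @export
partial_coordination_curve <- function(traj, center, members, r_grid) {
  if (is.matrix(traj)) traj <- list(traj)
  if (!length(traj)) stop("empty trajectory")
  if (is.unsorted(r_grid)) stop("r_grid must be sorted ascending")
  counts <- vapply(traj, function(pos) {
    d <- sqrt(colSums((t(pos[members, , drop = FALSE]) - pos[center, ])^2))
    vapply(r_grid, function(r) sum(d <= r), numeric(1))
  }, numeric(length(r_grid)))
  data.frame(r = r_grid, n = rowMeans(matrix(counts, nrow = length(r_grid))))
}
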