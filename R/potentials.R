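#' Nonbonded 12-6-4 pair parameters
#'
#' Parameters of the 12-6-4 nonbonded pair potential
#' \deqn{U(r) = c_{12}/r^{12} - c_6/r^6 - c_4/r^4 + q/r,}
#' a Lennard-Jones interaction corrected by an extra attractive
#' \eqn{C_4/r^4} term that mimics the charge-induced-dipole interactions of
#' highly charged ions such as Zr(4+). The potential is truncated (set to
#' zero, not shifted) at \code{cutoff}.
#'
#' @param c12 repulsive coefficient (energy * length^12), >= 0.
#' @param c6 dispersion coefficient (energy * length^6), >= 0.
#' @param c4 charge-induced-dipole coefficient (energy * length^4), >= 0.
#' @param q_product charge product already multiplied by the Coulomb
#'   constant (reduced units), so the Coulomb term is \code{q_product / r}.
#'   When parameters are attached to a [toy_system()] pair table this field
#'   is ignored: system electrostatics are built from per-particle charges.
#' @param cutoff truncation distance, > 0 (default 11, mirroring an 11 A
#'   nonbonded cutoff mapped to reduced units).
#' @param exp_rep,exp_disp,exp_ind exponents of the three power-law terms;
#'   defaults give the standard 12-6-4 form but variants are representable.
#' @return an object of class \code{pair_params}.
#' @examples
#' p <- pair_params(c12 = 1, c6 = 2)
#' pair_energy(1, p)  # the minimum of the 12-6 pair at r* = (2 c12/c6)^(1/6)
#' @export
pair_params <- function(c12 = 0, c6 = 0, c4 = 0, q_product = 0, cutoff = 11,
                        exp_rep = 12L, exp_disp = 6L, exp_ind = 4L) {
  stopifnot(cutoff > 0, c12 >= 0, c6 >= 0, c4 >= 0)
  if ((c6 > 0 || c4 > 0 || q_product < 0) && c12 <= 0)
    stop("attractive terms require c12 > 0 to prevent collapse")
  structure(list(c12 = c12, c6 = c6, c4 = c4, q_product = q_product,
                 cutoff = cutoff, exp_rep = as.integer(exp_rep),
                 exp_disp = as.integer(exp_disp), exp_ind = as.integer(exp_ind)),
            class = "pair_params")
}

#' Harmonic bond parameters
#'
#' @param k_bond spring constant (energy / length^2), > 0.
#' @param r_eq equilibrium length, > 0.
#' @return an object of class \code{bond_params}.
#' @export
bond_params <- function(k_bond, r_eq) {
  stopifnot(k_bond > 0, r_eq > 0)
  structure(list(k_bond = k_bond, r_eq = r_eq), class = "bond_params")
}

#' 12-6-4 pair energy
#'
#' Evaluates the truncated 12-6-4 pair potential at separation \code{r}.
#' Returns exactly 0 for \code{r >= cutoff}.
#'
#' @param r separation(s), all > 0.
#' @param p a [pair_params()] object.
#' @return energy in k_BT, vectorised over \code{r}.
#' @export
pair_energy <- function(r, p) {
  stopifnot(inherits(p, "pair_params"))
  if (any(r <= 0)) stop("pair separation must be positive")
  u <- p$c12 / r^p$exp_rep - p$c6 / r^p$exp_disp - p$c4 / r^p$exp_ind +
    p$q_product / r
  u[r >= p$cutoff] <- 0
  u
}

#' 12-6-4 pair force magnitude
#'
#' Radial derivative \eqn{-dU/dr} of the truncated pair potential; positive
#' values push the pair apart.
#'
#' @inheritParams pair_energy
#' @return force in k_BT / length, vectorised over \code{r}.
#' @export
pair_force <- function(r, p) {
  stopifnot(inherits(p, "pair_params"))
  if (any(r <= 0)) stop("pair separation must be positive")
  f <- p$exp_rep * p$c12 / r^(p$exp_rep + 1) -
    p$exp_disp * p$c6 / r^(p$exp_disp + 1) -
    p$exp_ind * p$c4 / r^(p$exp_ind + 1) + p$q_product / r^2
  f[r >= p$cutoff] <- 0
  f
}

#' Harmonic umbrella bias energy and force
#'
#' Bias \eqn{U_b = \frac{1}{2} k (s - s_0)^2} on a collective variable
#' \eqn{s}, with the chain-rule force contribution
#' \eqn{F = -k (s - s_0)\, \partial s/\partial x}.
#'
#' @param cv_value current CV value \eqn{s}.
#' @param dcv_dx per-particle CV gradients (N x 3 matrix), or \code{NULL}
#'   to return only the energy.
#' @param window an [umbrella_window()].
#' @return list with \code{energy} (k_BT) and \code{force} (N x 3 or NULL).
#' @export
bias_energy_force <- function(cv_value, dcv_dx, window) {
  stopifnot(inherits(window, "umbrella_window"))
  dev <- cv_value - window$center
  force <- if (is.null(dcv_dx)) NULL else -window$k * dev * dcv_dx
  list(energy = 0.5 * window$k * dev^2, force = force)
}

#' Total potential energy and analytic forces of a toy system
#'
#' Sums truncated 12-6-4 nonbonded pairs (bonded pairs excluded), harmonic
#' bonds, and harmonic tethers. Forces are exact analytic gradients; by
#' Newton's third law they sum to the zero vector for tether-free systems.
#'
#' @param sys a [toy_system()].
#' @return list with \code{energy} (k_BT), \code{forces} (N x 3), and
#'   \code{min_pair_distance}.
#' @seealso [pair_energy()], [toy_system()]
#' @export
total_energy_forces <- function(sys) {
  stopifnot(inherits(sys, "toy_system"))
  res <- cpp_energy_forces(sys$positions, .pair_matrix(sys),
                           .bond_matrix(sys), .tether_matrix(sys),
                           .rmin_guard)
  if (!res$ok)
    stop(sprintf(paste0("overlapping particles: minimum nonbonded distance ",
                        "%.3g is below the guard %.3g"),
                 res$min_pair_distance, .rmin_guard))
  res[c("energy", "forces", "min_pair_distance")]
}
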