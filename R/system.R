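#' Construct a toy ion-chelator system
#'
#' A desk-scale stand-in for a solvated metal-chelator complex: one ion,
#' donor ("ligand") oxygens on a flexible bonded backbone, and optional
#' tethered solvent oxygens. Nonbonded interactions are assigned per
#' role pair from \code{pair_table}; electrostatics are built from
#' per-particle \code{charges} times \code{coulomb} (so the
#' \code{q_product} field of table entries is ignored here). Directly
#' bonded pairs are excluded from the nonbonded sum. No periodic
#' boundaries are used; harmonic tethers replace the box.
#'
#' @param positions N x 3 matrix of coordinates (reduced lengths).
#' @param roles character vector, one of \code{"ion"},
#'   \code{"ligand_oxygen"}, \code{"backbone"}, \code{"solvent_oxygen"};
#'   exactly one particle must be the ion.
#' @param charges per-particle charges (default 0).
#' @param masses per-particle masses, all > 0 (default 1).
#' @param bonds list of \code{list(i =, j =, params = bond_params)}.
#' @param pair_table named list of [pair_params()]; names are
#'   \code{"roleA:roleB"} pairs (order-insensitive). Missing role pairs do
#'   not interact.
#' @param tether data frame with columns \code{index, k, x, y, z}
#'   (harmonic anchors), or NULL.
#' @param cv_specs list of [cv_spec()]; the first is the biased CV during
#'   umbrella sampling.
#' @param coulomb Coulomb constant in reduced units (default 1).
#' @return an object of class \code{toy_system}.
#' @export
toy_system <- function(positions, roles, charges = NULL, masses = NULL,
                       bonds = list(), pair_table = list(), tether = NULL,
                       cv_specs = list(), coulomb = 1) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  roles <- as.character(roles)
  stopifnot(length(roles) == n)
  bad <- setdiff(roles, c("ion", "ligand_oxygen", "backbone", "solvent_oxygen"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  if (sum(roles == "ion") != 1) stop("exactly one particle must have role 'ion'")
  if (is.null(charges)) charges <- rep(0, n)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(charges) == n, length(masses) == n, all(masses > 0))
  for (b in bonds) {
    if (b$i == b$j) stop("self-bonds are not allowed")
    stopifnot(b$i >= 1, b$j >= 1, b$i <= n, b$j <= n,
              inherits(b$params, "bond_params"))
  }
  if (!is.null(tether)) {
    tether <- as.data.frame(tether)
    stopifnot(all(c("index", "k", "x", "y", "z") %in% names(tether)),
              all(tether$index >= 1 & tether$index <= n), all(tether$k >= 0))
  }
  for (cv in cv_specs) stopifnot(inherits(cv, "cv_spec"))
  structure(list(positions = positions, roles = roles, charges = charges,
                 masses = masses, bonds = bonds, pair_table = pair_table,
                 tether = tether, cv_specs = cv_specs, coulomb = coulomb),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d particles (%s)\n", nrow(x$positions),
              paste(sprintf("%d %s", table(x$roles), names(table(x$roles))),
                    collapse = ", ")))
  cat(sprintf("  %d bonds, %d tethers, %d CV specs\n", length(x$bonds),
              if (is.null(x$tether)) 0L else nrow(x$tether),
              length(x$cv_specs)))
  invisible(x)
}

.role_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

# flatten nonbonded interactions into the (i, j, c12, c6, c4, qq, cutoff)
# matrix the compiled kernels consume; excludes 1-2 bonded pairs.
.pair_matrix <- function(sys) {
  n <- nrow(sys$positions)
  bonded <- character(0)
  for (b in sys$bonds)
    bonded <- c(bonded, paste(min(b$i, b$j), max(b$i, b$j)))
  keys <- lapply(sys$pair_table, function(p) {
    stopifnot(inherits(p, "pair_params"))
    if (p$exp_rep != 12L || p$exp_disp != 6L || p$exp_ind != 4L)
      stop("system assembly supports the 12-6-4 form only")
    p
  })
  out <- vector("list", 64)
  m <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (paste(i, j) %in% bonded) next
      p <- sys$pair_table[[.role_key(sys$roles[i], sys$roles[j])]]
      qq <- sys$coulomb * sys$charges[i] * sys$charges[j]
      if (is.null(p)) {
        if (qq == 0) next
        p <- list(c12 = 0, c6 = 0, c4 = 0, cutoff = 11)
      }
      m <- m + 1L
      out[[m]] <- c(i, j, p$c12, p$c6, p$c4, qq, p$cutoff)
    }
  }
  if (m == 0L) return(matrix(0, 0, 7))
  do.call(rbind, out[seq_len(m)])
}

.bond_matrix <- function(sys) {
  if (!length(sys$bonds)) return(matrix(0, 0, 4))
  do.call(rbind, lapply(sys$bonds, function(b)
    c(b$i, b$j, b$params$k_bond, b$params$r_eq)))
}

.tether_matrix <- function(sys) {
  if (is.null(sys$tether) || !nrow(sys$tether)) return(matrix(0, 0, 5))
  as.matrix(sys$tether[, c("index", "k", "x", "y", "z")])
}

.cv_list <- function(sys) {
  lapply(sys$cv_specs, function(cv)
    list(center = cv$center_particle, members = as.integer(cv$member_particles),
         r0 = cv$switching$r0, nexp = cv$switching$n_exp,
         mexp = cv$switching$m_exp))
}

# default toy force field: ion-oxygen 12-6-4 well near r = 2.2 (the DFT
# Zr-O contact range), soft oxygen-oxygen and backbone repulsion
.default_pair_table <- function() {
  list(
    `ion:ligand_oxygen` = pair_params(c12 = 102900, c6 = 1815, c4 = 50),
    `ion:solvent_oxygen` = pair_params(c12 = 102900, c6 = 1400, c4 = 50),
    `ligand_oxygen:ligand_oxygen` = pair_params(c12 = 2000, c6 = 10),
    `ligand_oxygen:solvent_oxygen` = pair_params(c12 = 2000, c6 = 10),
    `solvent_oxygen:solvent_oxygen` = pair_params(c12 = 2000, c6 = 10),
    `backbone:backbone` = pair_params(c12 = 2000),
    `backbone:ligand_oxygen` = pair_params(c12 = 500),
    `backbone:solvent_oxygen` = pair_params(c12 = 2000),
    `backbone:ion` = pair_params(c12 = 2000)
  )
}

#' Build a toy multidentate chelator around a metal ion
#'
#' Constructs a reduced analog of a hydroxamate chelator: \code{n_groups}
#' binding groups, each contributing one backbone bead carrying two donor
#' oxygens (so 3 groups / 6 oxygens emulate a DFO-like chelator and
#' 4 groups / 8 oxygens a 4HMS-like one). Backbone beads form a bonded
#' chain and are weakly tethered near a ring of radius \code{ring_radius}
#' so the chelator can open and close around the ion. A
#' coordination-number CV over the ligand oxygens with switching cutoff
#' \code{r0 = 5} (reduced) is attached as the first CV.
#'
#' @param n_groups number of binding groups, 2..4.
#' @param ring_radius radius of the backbone anchor ring (default 4).
#' @param tether_k backbone tether spring constant (default 2).
#' @param seed integer seed for the small random jitter on starting
#'   coordinates (topology is deterministic).
#' @param r0 switching cutoff of the attached ligand CV (default 5).
#' @return a [toy_system()] with \code{1 + 3 n_groups} particles.
#' @export
build_toy_chelator <- function(n_groups = 3, ring_radius = 4, tether_k = 2,
                               seed = 1, r0 = 5) {
  stopifnot(n_groups >= 2, n_groups <= 4, ring_radius > 0, tether_k > 0)
  set.seed(as.integer(seed))
  n <- 1L + 3L * n_groups
  pos <- matrix(0, n, 3)
  roles <- character(n)
  roles[1] <- "ion"
  bonds <- list()
  tether <- NULL
  bb <- integer(n_groups)
  theta <- 2 * pi * (seq_len(n_groups) - 1) / n_groups
  idx <- 2L
  for (g in seq_len(n_groups)) {
    anchor <- ring_radius * c(cos(theta[g]), sin(theta[g]), 0)
    bb[g] <- idx
    roles[idx] <- "backbone"
    pos[idx, ] <- anchor
    tether <- rbind(tether, data.frame(index = idx, k = tether_k,
                                       x = anchor[1], y = anchor[2],
                                       z = anchor[3]))
    for (o in 1:2) {
      oi <- idx + o
      roles[oi] <- "ligand_oxygen"
      # oxygens start between backbone and ion, offset out of plane
      pos[oi, ] <- anchor * 0.6 + c(0, 0, ifelse(o == 1, 0.8, -0.8))
      bonds[[length(bonds) + 1L]] <-
        list(i = idx, j = oi, params = bond_params(k_bond = 100, r_eq = 1.4))
    }
    idx <- idx + 3L
  }
  for (g in seq_len(n_groups - 1))
    bonds[[length(bonds) + 1L]] <-
      list(i = bb[g], j = bb[g + 1], params = bond_params(k_bond = 20,
        r_eq = sqrt(sum((pos[bb[g], ] - pos[bb[g + 1], ])^2))))
  pos <- pos + matrix(rnorm(3 * n, sd = 0.05), n, 3)
  pos[1, ] <- 0
  charges <- ifelse(roles == "ion", 4, ifelse(roles == "ligand_oxygen", -0.5, 0))
  cv <- cv_spec(center_particle = 1L, member_particles = which(roles == "ligand_oxygen"),
                switching = switching_params(r0 = r0), label = "cv_ligand")
  toy_system(pos, roles, charges = charges, bonds = bonds,
             pair_table = .default_pair_table(), tether = tether,
             cv_specs = list(cv))
}

#' Add tethered solvent oxygens to a toy system
#'
#' Scatters \code{n} solvent oxygens uniformly in a sphere of radius
#' \code{box_radius} around the ion and tethers each to its initial site
#' (the tether replaces periodic boundaries). A water-coordination CV with
#' switching cutoff \code{r0 = 2.5} (reduced) is appended to the system's
#' CV list.
#'
#' @param sys a [toy_system()].
#' @param n number of solvent oxygens.
#' @param box_radius placement radius (default 8).
#' @param tether_k solvent tether spring constant (default 0.5).
#' @param seed integer seed for placement.
#' @param r0 switching cutoff of the appended water CV (default 2.5).
#' @return the augmented [toy_system()].
#' @export
add_solvent <- function(sys, n, box_radius = 8, tether_k = 0.5, seed = 1,
                        r0 = 2.5) {
  stopifnot(inherits(sys, "toy_system"), n >= 1)
  set.seed(as.integer(seed))
  n0 <- nrow(sys$positions)
  ion <- which(sys$roles == "ion")
  pts <- matrix(rnorm(3 * 4 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * box_radius * runif(4 * n)^(1 / 3)
  # keep sites at least 2 apart from existing particles
  keep <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(sys$positions) - p)^2))) > 2)
  pts <- head(pts[keep, , drop = FALSE], n)
  if (nrow(pts) < n) stop("could not place ", n, " solvent beads; shrink n")
  pts <- sweep(pts, 2, sys$positions[ion, ], `+`)
  pos <- rbind(sys$positions, pts)
  roles <- c(sys$roles, rep("solvent_oxygen", n))
  tether <- rbind(sys$tether,
                  data.frame(index = n0 + seq_len(n), k = tether_k,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  cv_w <- cv_spec(center_particle = ion, member_particles = n0 + seq_len(n),
                  switching = switching_params(r0 = r0), label = "cv_water")
  toy_system(pos, roles, charges = c(sys$charges, rep(-0.2, n)),
             masses = c(sys$masses, rep(1, n)), bonds = sys$bonds,
             pair_table = sys$pair_table, tether = tether,
             cv_specs = c(sys$cv_specs, list(cv_w)), coulomb = sys$coulomb)
}

#' Remove solvent oxygens from a toy system
#'
#' Drops all \code{solvent_oxygen} particles, their tethers, and any CV
#' whose members become empty; remaining indices (bonds, tethers, CV
#' members) are remapped. Used before inherent-structure quenches, which
#' optimise the bare complex.
#'
#' @param sys a [toy_system()].
#' @return the stripped [toy_system()].
#' @export
strip_solvent <- function(sys) {
  stopifnot(inherits(sys, "toy_system"))
  keep <- which(sys$roles != "solvent_oxygen")
  if (length(keep) == length(sys$roles)) return(sys)
  map <- integer(length(sys$roles))
  map[keep] <- seq_along(keep)
  bonds <- lapply(sys$bonds, function(b)
    if (map[b$i] > 0 && map[b$j] > 0)
      list(i = map[b$i], j = map[b$j], params = b$params) else NULL)
  bonds <- Filter(Negate(is.null), bonds)
  tether <- sys$tether
  if (!is.null(tether)) {
    tether <- tether[map[tether$index] > 0, , drop = FALSE]
    if (nrow(tether)) tether$index <- map[tether$index] else tether <- NULL
  }
  cvs <- lapply(sys$cv_specs, function(cv) {
    mem <- map[cv$member_particles]
    mem <- mem[mem > 0]
    if (!length(mem) || map[cv$center_particle] == 0) return(NULL)
    cv_spec(map[cv$center_particle], mem, cv$switching, cv$label)
  })
  toy_system(sys$positions[keep, , drop = FALSE], sys$roles[keep],
             charges = sys$charges[keep], masses = sys$masses[keep],
             bonds = bonds, pair_table = sys$pair_table, tether = tether,
             cv_specs = Filter(Negate(is.null), cvs), coulomb = sys$coulomb)
}

#' Single-ion benchmark system with a fixed donor ring
#'
#' A deliberately low-dimensional system whose free energy along the
#' coordination number is computable by direct quadrature: \code{n_oxygens}
#' donor oxygens are frozen on a ring in the xy-plane (their masses are
#' irrelevant; only the ion moves in practice) and the ion is pulled away
#' from the ring by a harmonic tether, creating competing bound and
#' unbound basins. Useful as an end-to-end ground truth for umbrella
#' sampling + WHAM.
#'
#' @param n_oxygens donors on the ring (default 6).
#' @param ring_radius ring radius (default 2.5).
#' @param tether_anchor 3-vector tether anchor for the ion.
#' @param tether_k ion tether spring constant.
#' @param r0 switching cutoff of the attached CV (default 5).
#' @param well_depth approximate depth (k_BT) of each ion-oxygen 12-6-4
#'   well at contact distance ~2.2.
#' @return a [toy_system()]; the ion is particle 1.
#' @export
build_ion_ring_system <- function(n_oxygens = 6, ring_radius = 2.5,
                                  tether_anchor = c(6, 0, 0), tether_k = 0.35,
                                  r0 = 5, well_depth = 1.2) {
  stopifnot(n_oxygens >= 2, ring_radius > 0, tether_k >= 0)
  theta <- 2 * pi * (seq_len(n_oxygens) - 1) / n_oxygens
  pos <- rbind(c(0, 0, 0.5),
               cbind(ring_radius * cos(theta), ring_radius * sin(theta), 0))
  roles <- c("ion", rep("ligand_oxygen", n_oxygens))
  # scale the 12-6-4 well to the requested depth at r* ~ 2.2
  c6 <- 226.9 * well_depth
  pt <- list(`ion:ligand_oxygen` = pair_params(c12 = 56.7 * c6, c6 = c6,
                                               c4 = 0))
  tether <- data.frame(index = 1, k = tether_k, x = tether_anchor[1],
                       y = tether_anchor[2], z = tether_anchor[3])
  cv <- cv_spec(1L, 1L + seq_len(n_oxygens), switching_params(r0 = r0),
                label = "cv_ligand")
  # infinite mass freezes the ring: only the ion's 3 coordinates evolve
  toy_system(pos, roles, masses = c(1, rep(Inf, n_oxygens)),
             pair_table = pt, tether = tether, cv_specs = list(cv))
}
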