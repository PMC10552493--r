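#' Chelate-angle scatter table and histograms
#'
#' For each binding group, computes the two chelate angles at the donor
#' oxygen — ion-O-N and ion-O-C in the real chelator, ion-O-partner in the
#' toy model — for every frame, and returns the scatter table plus
#' unit-area histograms of each angle family.
#'
#' @param traj list of N x 3 position matrices.
#' @param groups list of group definitions, each a list with elements
#'   \code{ion}, \code{o}, \code{n}, \code{c} (indices; \code{n} or
#'   \code{c} may be NA, in which case the group is skipped with a
#'   warning).
#' @param breaks histogram breaks in degrees (default 0..180 by 4).
#' @return list with \code{table} (frame, group, angle_on, angle_oc),
#'   \code{hist_on} and \code{hist_oc} (data frames: mid, density,
#'   normalised to unit area).
#' @export
angle_scatter_table <- function(traj, groups, breaks = seq(0, 180, by = 4)) {
  if (is.matrix(traj)) traj <- list(traj)
  keep <- vapply(groups, function(g)
    !(is.na(g$n) || is.na(g$c)), logical(1))
  if (any(!keep))
    warning(sprintf("%d group(s) skipped: undefined partner particle",
                    sum(!keep)))
  groups <- groups[keep]
  if (!length(groups)) stop("no usable groups")
  rows <- lapply(seq_along(traj), function(t) {
    pos <- traj[[t]]
    do.call(rbind, lapply(seq_along(groups), function(gi) {
      g <- groups[[gi]]
      data.frame(frame = t, group = gi,
                 angle_on = chelate_angles(pos, list(c(g$ion, g$o, g$n))),
                 angle_oc = chelate_angles(pos, list(c(g$ion, g$o, g$c))))
    }))
  })
  tab <- do.call(rbind, rows)
  hist_df <- function(x) {
    h <- hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, density = h$density)
  }
  list(table = tab, hist_on = hist_df(tab$angle_on),
       hist_oc = hist_df(tab$angle_oc))
}

#' Ligand/solvent split of the partial coordination curve
#'
#' Partial coordination numbers n(r) around the ion computed separately
#' for ligand oxygens and solvent oxygens (the solid and dotted curves of
#' a coordination-structure plot); their sum equals the all-oxygen curve
#' exactly.
#'
#' @param traj list of N x 3 position matrices.
#' @param center ion index.
#' @param ligand_members,solvent_members disjoint index sets.
#' @param r_grid radii, sorted ascending.
#' @return data frame with columns \code{r, n_ligand, n_solvent, n_total}.
#' @export
coordination_split_curve <- function(traj, center, ligand_members,
                                     solvent_members, r_grid) {
  if (length(intersect(ligand_members, solvent_members)))
    stop("ligand and solvent member sets overlap")
  lig <- partial_coordination_curve(traj, center, ligand_members, r_grid)
  sol <- if (length(solvent_members))
    partial_coordination_curve(traj, center, solvent_members, r_grid)
  else data.frame(r = r_grid, n = 0)
  data.frame(r = r_grid, n_ligand = lig$n, n_solvent = sol$n,
             n_total = lig$n + sol$n)
}

#' Level-crossing summary of a CV time series
#'
#' Segments a coordination-number trace into dwells around given levels
#' and reports the crossings between them — e.g. the drop from CN ~ 5.5
#' to CN ~ 3.5 marking the collapse of a coordination shell. Detection
#' uses dual-threshold hysteresis: the running-mean-smoothed series must
#' enter the band level +/- \code{band} of a different level before a
#' crossing is declared, which suppresses noise-induced chatter.
#'
#' @param series numeric CV trace, or a \code{cv_series} (first CV used).
#' @param levels at least 2 reference levels, sorted ascending.
#' @param band half-width of each level's band (default 0.25 CV units).
#' @param smooth_window running-mean window in frames (default 50); the
#'   series must be at least this long.
#' @return list with \code{segments} (data frame: level, start, end) and
#'   \code{crossings} (data frame: index, from, to), indices in frames of
#'   the original series.
#' @export
cn_transition_summary <- function(series, levels, band = 0.25,
                                  smooth_window = 50) {
  if (inherits(series, "cv_series"))
    series <- series$series[[setdiff(names(series$series), "time")[1]]]
  x <- as.numeric(series)
  if (length(levels) < 2 || is.unsorted(levels))
    stop("need >= 2 levels, sorted ascending")
  if (length(x) < smooth_window)
    stop("series shorter than the smoothing window")
  sm <- as.numeric(stats::filter(x, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  in_band <- function(v) {
    hit <- which(abs(v - levels) <= band)
    if (length(hit)) hit[1] else NA_integer_
  }
  cur <- in_band(sm[1])  # NA: not yet committed to any level
  seg_start <- 1L
  segments <- NULL
  crossings <- NULL
  for (t in seq_along(sm)) {
    b <- in_band(sm[t])
    if (!is.na(b) && (is.na(cur) || b != cur)) {
      if (!is.na(cur)) {
        segments <- rbind(segments,
                          data.frame(level = levels[cur], start = seg_start,
                                     end = t - 1L))
      }
      crossings <- rbind(crossings,
                         data.frame(index = t,
                                    from = if (is.na(cur)) NA_real_ else
                                      levels[cur],
                                    to = levels[b]))
      cur <- b
      seg_start <- t
    }
  }
  last_level <- if (is.na(cur)) levels[which.min(abs(sm[1] - levels))] else
    levels[cur]
  segments <- rbind(segments,
                    data.frame(level = last_level, start = seg_start,
                               end = length(sm)))
  # entering the first band from an uncommitted start is not a level-to-level
  # transition unless the series truly began inside another band; keep it as
  # a crossing with from = NA so ramp entries are still counted per band
  list(segments = segments,
       crossings = if (is.null(crossings))
         data.frame(index = integer(0), from = numeric(0), to = numeric(0))
       else crossings)
}
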