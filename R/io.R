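#' Write a multi-frame XYZ trajectory
#'
#' Standard XYZ text format: atom count, comment line, then one
#' \code{role x y z} line per particle, repeated per frame. Coordinates
#' are written with 17 significant digits so write-then-read round-trips
#' exactly.
#'
#' @param traj list of N x 3 position matrices.
#' @param roles per-particle labels used as the element column.
#' @param path output file.
#' @param comments per-frame comment lines (default "frame i").
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(traj, roles, path, comments = NULL) {
  if (is.matrix(traj)) traj <- list(traj)
  if (is.null(comments)) comments <- sprintf("frame %d", seq_along(traj))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(traj)) {
    pos <- traj[[t]]
    if (nrow(pos) != length(roles))
      stop("frame ", t, ": position count does not match roles")
    writeLines(c(sprintf("%d", nrow(pos)), comments[t],
                 sprintf("%s %.17g %.17g %.17g", roles,
                         pos[, 1], pos[, 2], pos[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()] or any standard XYZ.
#' @return list with \code{frames} (list of N x 3 matrices), \code{roles}
#'   (from the first frame), \code{comments}. Malformed files raise
#'   line-numbered errors; frames must share one atom count.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  comments <- character(0)
  roles <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("%s:%d: expected an atom count, got '%s'", path, i,
                   lines[i]))
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop(sprintf("%s:%d: truncated frame (%d atoms declared)", path, i, n))
    comments <- c(comments, lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad))
      stop(sprintf("%s:%d: malformed atom line", path, i + 1L + bad[1]))
    r <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(as.numeric(vapply(parts, function(p) p[2:4],
                                    character(3))), ncol = 3, byrow = TRUE)
    if (any(is.na(xyz)))
      stop(sprintf("%s:%d: non-numeric coordinate", path, i + 1L))
    if (is.null(roles)) roles <- r
    else if (length(r) != length(roles))
      stop(sprintf("%s:%d: inconsistent atom count across frames", path, i))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop(path, ": no frames found")
  list(frames = frames, roles = roles, comments = comments)
}

#' Write a COLVAR-style CV table
#'
#' Whitespace table with the PLUMED-style header
#' \code{#! FIELDS time cv_ligand [cv_water]}; one row per frame, full
#' precision.
#'
#' @param series a \code{cv_series} or a data frame whose first column is
#'   time.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_colvar <- function(series, path) {
  df <- if (inherits(series, "cv_series")) series$series else series
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  writeLines(do.call(sprintf,
                     c(list(paste(rep("%.17g", ncol(df)), collapse = " ")),
                       unname(as.list(df)))), con)
  invisible(path)
}

#' Read a COLVAR-style CV table
#'
#' @param path file with a \code{#! FIELDS ...} header line.
#' @return data frame with the named columns.
#' @export
read_colvar <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#! FIELDS"))
    stop(path, ":1: expected a '#! FIELDS time ...' header line")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", first)), "\\s+")[[1]]
  df <- read.table(path, skip = 1, col.names = fields,
                   colClasses = "numeric")
  df
}

#' Write / read an umbrella window manifest
#'
#' Flat whitespace table (one row per window: \code{center k file})
#' linking window parameters to their COLVAR series files.
#'
#' @param windows list of [umbrella_window()]s.
#' @param files per-window COLVAR paths.
#' @param path manifest file.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(windows, files, path) {
  stopifnot(length(windows) == length(files))
  df <- data.frame(center = vapply(windows, `[[`, 0, "center"),
                   k = vapply(windows, `[[`, 0, "k"), file = files)
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check verify every referenced series file exists before any
#'   compute (default TRUE).
#' @return for \code{read_manifest}: data frame with columns
#'   \code{center, k, file}.
#' @export
read_manifest <- function(path, check = TRUE) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("center", "k", "file")
  if (!all(need %in% names(df)))
    stop(path, ": manifest must have columns center, k, file")
  if (check) {
    base <- dirname(path)
    resolved <- ifelse(file.exists(df$file), df$file,
                       file.path(base, df$file))
    missing <- !file.exists(resolved)
    if (any(missing))
      stop("manifest references absent series file(s): ",
           paste(df$file[missing], collapse = ", "))
    df$file <- resolved
  }
  df
}

#' Load an umbrella set from a manifest
#'
#' Reads each window's COLVAR table and attaches the window metadata,
#' producing the series list [wham_1d()] consumes.
#'
#' @param path manifest file (see [write_manifest()]).
#' @return list of \code{cv_series}.
#' @export
read_umbrella_set <- function(path) {
  man <- read_manifest(path)
  lapply(seq_len(nrow(man)), function(i) {
    structure(list(series = read_colvar(man$file[i]),
                   window = umbrella_window(man$center[i], man$k[i])),
              class = "cv_series")
  })
}

#' Write a free-energy profile as CSV
#'
#' Columns: bin_center, f_value, f_error, unsampled (explicit sentinel
#' column; unsampled bins have empty f_value, never 0).
#'
#' @param profile a [wham_1d()] result.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_fes_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fes_profile"))
  df <- data.frame(bin_center = profile$bin_centers,
                   f_value = profile$f_values,
                   f_error = profile$f_errors,
                   unsampled = profile$unsampled)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a 2D free-energy surface as CSV (long format)
#'
#' Columns: primary, secondary, f_value, unsampled.
#'
#' @param surface a [reweight_2d()] result.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_fes_surface <- function(surface, path) {
  stopifnot(inherits(surface, "fes_surface"))
  df <- expand.grid(primary = surface$primary_centers,
                    secondary = surface$secondary_centers)
  df$f_value <- as.vector(surface$f_values)
  df$unsampled <- as.vector(surface$unsampled)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.csv
NULL
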