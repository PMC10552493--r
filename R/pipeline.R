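#' Default study configuration
#'
#' The full toy-study configuration as a nested list (serialisable to
#' YAML). The two analogs mirror the production umbrella layouts: the
#' DFO-like chelator (3 groups, 6 donor oxygens) uses 9 windows with
#' centers 2 to 6 in steps of 0.5; the 4HMS-like chelator (4 groups,
#' 8 oxygens) uses 13 windows, centers 2 to 8. All windows share
#' k = 20 k_BT.
#'
#' @param analog \code{"dfo"} or \code{"4hms"}.
#' @param output_dir output directory.
#' @return nested configuration list (see [run_study()] for the schema).
#' @export
default_study_config <- function(analog = c("dfo", "4hms"),
                                 output_dir = "ionfes_study") {
  analog <- match.arg(analog)
  ng <- if (analog == "dfo") 3L else 4L
  to <- if (analog == "dfo") 6 else 8
  list(
    system = list(type = "chelator", n_groups = ng, ring_radius = 4,
                  tether_k = 2, seed = 11,
                  solvent = list(n = 12, box_radius = 8, tether_k = 0.5,
                                 r0 = 2.5)),
    windows = list(from = 2, to = to, step = 0.5, k = 20),
    simulation = list(dt = 0.002, gamma = 2, temperature = 1,
                      n_steps = 20000, save_stride = 10, seed = 101,
                      equil_frac = 0.1),
    estimator = list(bins = 80, tol = 1e-8, max_iter = 1e5, n_boot = 20,
                     block_frac = 0.05, seed = 7, bins2 = 30),
    quench = list(n_frames = 30, force_tol = 1e-4, strip_solvent = TRUE,
                  seed = 13),
    output = list(dir = output_dir)
  )
}

#' Read and validate a study configuration file
#'
#' YAML file with the schema of [default_study_config()]: top-level keys
#' \code{system} (type, n_groups, ring_radius, tether_k, seed, optional
#' solvent), \code{windows} (from, to, step, k), \code{simulation}
#' (dt, gamma, temperature, n_steps, save_stride, seed, equil_frac),
#' \code{estimator} (bins, tol, max_iter, n_boot, block_frac, seed,
#' bins2), \code{quench} (n_frames, force_tol, strip_solvent, seed), and
#' \code{output} (dir). Missing optional fields inherit defaults.
#'
#' @param path YAML configuration file.
#' @return validated configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_study_config()
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
    else for (key in names(defaults[[sec]]))
      if (is.null(cfg[[sec]][[key]])) cfg[[sec]][[key]] <- defaults[[sec]][[key]]
  }
  with(cfg, {
    stopifnot(system$n_groups %in% 2:4, windows$step > 0, windows$k >= 0,
              windows$to >= windows$from, simulation$dt > 0,
              simulation$n_steps >= 1, estimator$bins >= 2,
              estimator$n_boot >= 2, quench$n_frames >= 1)
  })
  cfg
}

.log_stage <- function(stage, msg, t0 = NULL, verbose = TRUE) {
  if (!verbose) return(invisible())
  wall <- if (is.null(t0)) "" else
    sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[%s] %s%s", stage, msg, wall))
}

#' Run the full toy chelation study
#'
#' Orchestrates every stage from one configuration: build the toy
#' chelator (+ solvent), run the umbrella set, write per-window XYZ and
#' COLVAR files plus the window manifest, reconstruct the 1D free-energy
#' profile with bootstrap errors, reweight to the 2D
#' (ligand CN, water CN) surface, quench sampled frames to inherent
#' structures, run the geometric analyses, and record every seed and
#' parameter in a machine-readable run record. Stage outputs are files;
#' with \code{resume = TRUE}, windows whose outputs already exist are not
#' re-simulated, so interrupted runs pick up where they stopped.
#' Estimator outputs are deterministic functions of the configuration.
#'
#' @param config a configuration list ([default_study_config()]) or the
#'   path to a YAML file ([read_study_config()]).
#' @param dry_run validate the configuration and print the stage plan
#'   without computing (default FALSE).
#' @param resume skip windows with existing COLVAR output (default TRUE).
#' @param verbose per-stage progress logging (default TRUE).
#' @return (invisibly) list with \code{profile}, \code{surface},
#'   \code{quench}, \code{analysis}, \code{dir}; or the stage plan if
#'   \code{dry_run}.
#' @export
run_study <- function(config, dry_run = FALSE, resume = TRUE,
                      verbose = TRUE) {
  cfg <- if (is.character(config)) read_study_config(config) else config
  centers <- seq(cfg$windows$from, cfg$windows$to, by = cfg$windows$step)
  plan <- c(
    sprintf("build: chelator analog with %d groups (%d ligand oxygens), %d solvent beads",
            cfg$system$n_groups, 2 * cfg$system$n_groups,
            if (is.null(cfg$system$solvent)) 0L else cfg$system$solvent$n),
    sprintf("simulate: %d umbrella windows (centers %g..%g step %g, k = %g), %d steps each",
            length(centers), cfg$windows$from, cfg$windows$to,
            cfg$windows$step, cfg$windows$k, cfg$simulation$n_steps),
    sprintf("wham: %d bins, tol %g; bootstrap: %d replicates",
            cfg$estimator$bins, cfg$estimator$tol, cfg$estimator$n_boot),
    "reweight2d: (ligand CN, water CN) surface",
    sprintf("quench: %d frames, force tol %g", cfg$quench$n_frames,
            cfg$quench$force_tol),
    "analyze: chelate angles, coordination split curves, CN transitions",
    sprintf("report: run record in %s", cfg$output$dir))
  if (dry_run) {
    if (verbose) message(paste(c("stage plan:", paste(" -", plan)),
                               collapse = "\n"))
    return(invisible(plan))
  }
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output$dir, ...)

  t0 <- as.numeric(Sys.time())
  sys <- build_toy_chelator(cfg$system$n_groups, cfg$system$ring_radius,
                            cfg$system$tether_k, cfg$system$seed)
  if (!is.null(cfg$system$solvent))
    sys <- add_solvent(sys, cfg$system$solvent$n,
                       cfg$system$solvent$box_radius,
                       cfg$system$solvent$tether_k,
                       seed = cfg$system$seed + 1,
                       r0 = cfg$system$solvent$r0)
  .log_stage("build", sprintf("%d particles", nrow(sys$positions)), t0,
             verbose)

  windows <- lapply(centers, umbrella_window, k = cfg$windows$k)
  scfg <- sim_config(cfg$simulation$dt, cfg$simulation$gamma,
                     cfg$simulation$temperature, cfg$simulation$n_steps,
                     cfg$simulation$save_stride, cfg$simulation$seed)
  colvar_files <- out(sprintf("window_%02d.colvar", seq_along(windows)))
  xyz_files <- out(sprintf("window_%02d.xyz", seq_along(windows)))
  have <- file.exists(colvar_files) & file.exists(xyz_files)
  series <- vector("list", length(windows))
  if (resume && any(have)) {
    for (i in which(have))
      series[[i]] <- structure(
        list(series = read_colvar(colvar_files[i]), window = windows[[i]]),
        class = "cv_series")
    .log_stage("simulate", sprintf("resumed %d window(s)", sum(have)),
               verbose = verbose)
  }
  todo <- which(!(resume & have))
  if (length(todo)) {
    t1 <- as.numeric(Sys.time())
    full <- run_umbrella_set(sys, windows, scfg,
                             equil_frac = cfg$simulation$equil_frac,
                             save_frames = TRUE)
    for (i in todo) {
      write_colvar(full[[i]], colvar_files[i])
      write_xyz(full[[i]]$frames, sys$roles, xyz_files[i])
      series[[i]] <- full[[i]]
    }
    .log_stage("simulate",
               sprintf("%d window(s), seeds %d..%d", length(todo),
                       scfg$seed + 1, scfg$seed + length(windows)), t1,
               verbose)
  }
  write_manifest(windows, basename(colvar_files), out("manifest.txt"))

  t1 <- as.numeric(Sys.time())
  profile <- wham_1d(series, bins = cfg$estimator$bins,
                     tol = cfg$estimator$tol,
                     max_iter = cfg$estimator$max_iter)
  profile <- bootstrap_errors(series, profile,
                              n_boot = cfg$estimator$n_boot,
                              seed = cfg$estimator$seed,
                              block_frac = cfg$estimator$block_frac)
  write_fes_profile(profile, out("fes_1d.csv"))
  .log_stage("wham", sprintf("converged: %s, %d iterations",
                             profile$converged, profile$n_iterations), t1,
             verbose)

  surface <- NULL
  if (length(sys$cv_specs) > 1) {
    t1 <- as.numeric(Sys.time())
    surface <- reweight_2d(series, profile, bins2 = cfg$estimator$bins2)
    write_fes_surface(surface, out("fes_2d.csv"))
    .log_stage("reweight2d", "surface written", t1, verbose)
  }

  t1 <- as.numeric(Sys.time())
  frames <- list()
  for (tr in series) if (!is.null(tr$frames)) frames <- c(frames, tr$frames)
  if (!length(frames)) {
    xyzs <- lapply(xyz_files, read_xyz)
    frames <- do.call(c, lapply(xyzs, `[[`, "frames"))
  }
  set.seed(cfg$quench$seed)
  pick <- sort(sample.int(length(frames),
                          min(cfg$quench$n_frames, length(frames))))
  quench <- inherent_structure_scan(sys, frames[pick],
                                    strip_solvent = cfg$quench$strip_solvent,
                                    force_tol = cfg$quench$force_tol)
  write.csv(quench, out("quench.csv"), row.names = FALSE)
  .log_stage("quench", sprintf("%d/%d converged", sum(quench$converged),
                               nrow(quench)), t1, verbose)

  t1 <- as.numeric(Sys.time())
  ion <- which(sys$roles == "ion")
  oxy <- which(sys$roles == "ligand_oxygen")
  bb_of <- function(o) {
    for (b in sys$bonds) {
      if (b$i == o) return(b$j)
      if (b$j == o) return(b$i)
    }
    NA_integer_
  }
  groups <- lapply(oxy, function(o) {
    partner <- bb_of(o)
    other_o <- setdiff(intersect(oxy, vapply(sys$bonds, function(b)
      if (b$i == partner) b$j else if (b$j == partner) b$i else NA_integer_,
      0L)), o)
    list(ion = ion, o = o, n = partner,
         c = if (length(other_o)) other_o[1] else NA_integer_)
  })
  ana_frames <- frames[pick]
  angles <- angle_scatter_table(ana_frames, groups)
  write.csv(angles$table, out("angles.csv"), row.names = FALSE)
  split <- coordination_split_curve(ana_frames, ion, oxy,
                                    which(sys$roles == "solvent_oxygen"),
                                    r_grid = seq(0.5, 10, by = 0.25))
  write.csv(split, out("coordination_split.csv"), row.names = FALSE)
  trans <- cn_transition_summary(series[[1]],
                                 levels = sort(unique(c(centers[1],
                                                        centers[length(centers)]))),
                                 smooth_window = min(50,
                                   nrow(series[[1]]$series) %/% 2))
  write.csv(trans$crossings, out("cn_crossings.csv"), row.names = FALSE)
  .log_stage("analyze", "tables written", t1, verbose)

  record <- list(package_version = as.character(utils::packageVersion("ionfes")),
                 config = cfg, stage_plan = plan,
                 window_seeds = scfg$seed + seq_along(windows),
                 n_particles = nrow(sys$positions),
                 wham_converged = profile$converged,
                 wham_iterations = profile$n_iterations,
                 timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(record, out("run_record.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  .log_stage("report", sprintf("complete in %s", cfg$output$dir), t0,
             verbose)
  invisible(list(profile = profile, surface = surface, quench = quench,
                 analysis = list(angles = angles, split = split,
                                 transitions = trans),
                 dir = cfg$output$dir))
}
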