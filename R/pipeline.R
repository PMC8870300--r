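#' Full run configuration
#'
#' Bundles acquisition, scene, tracker and classifier parameters with the
#' RNG seed into one serializable object. Two presets reproduce the study
#' designs: `"agarose"` (free diffusion of particles in a heterogeneous inert
#' gel, 21 px maximum jump -- the control used to derive the delta-lifetime
#' threshold) and `"cell"` (confined diffusion inside an elliptical cell
#' with a nucleus, compartment-dependent lifetimes, 5 px maximum jump).
#'
#' @param preset `"agarose"`, `"cell"` or `"custom"`.
#' @param seed integer RNG seed for the whole run.
#' @param acquisition an [acq_config()].
#' @param scene named list of scene parameters; values supplied here
#'   override the preset defaults (see Details).
#' @param tracker named list: `max_jump_px`, `band_low_px`, `band_high_px`,
#'   `size_window`, `brightness_min`, `min_track_length`.
#' @param classifier a [classifier_config()].
#' @param phasor_gates optional named list of phasor gates, each a list
#'   with `center` `c(G, S)` and `radius`; when set, the pipeline reports
#'   per-gate pixel fractions over time (`gate_fractions.csv`).
#' @param recompute_threshold recompute the delta-lifetime threshold from
#'   this run's own tracks (appropriate for control runs) instead of using
#'   `classifier$threshold_ns`.
#'
#' @details Scene parameters: `n_particles`, `n_crossers` (cell preset:
#'   particles scripted to cross the nuclear boundary by directed drift),
#'   `D_px2_s`, `n_frames`, `photons_per_particle_frame`, `background_rate`,
#'   `background_tau_ns`, `psf_sigma_px`, `medium_sigma_ns` (environmental
#'   lifetime heterogeneity of the medium), `lifetime_table_ns` (named:
#'   extracellular/cytoplasm/nucleus), `transition_frames`, `cell_radii`,
#'   `nucleus_radii`, `band_px`.
#' @return A `run_config` object.
#' @export
run_config <- function(preset = c("cell", "agarose", "custom"), seed = 1,
                       acquisition = acq_config(frame_shape = c(64L, 64L)),
                       scene = list(), tracker = list(),
                       classifier = classifier_config(),
                       phasor_gates = NULL,
                       recompute_threshold = (preset[1] == "agarose")) {
  preset <- match.arg(preset)
  scene_def <- list(
    n_particles = 10L, n_crossers = 0L, D_px2_s = 3, n_frames = 30L,
    photons_per_particle_frame = 1000, background_rate = 0.2,
    background_tau_ns = 2.0, psf_sigma_px = 1,
    medium_sigma_ns = 0, transition_frames = 0L,
    lifetime_table_ns = c(extracellular = 2.0, cytoplasm = 3.0,
                          nucleus = 3.8),
    cell_radii = 26, nucleus_radii = 9, band_px = 2)
  if (preset == "agarose") {
    scene_def$medium_sigma_ns <- 0.35
    scene_def$lifetime_table_ns <- c(extracellular = 3.0)
    scene_def$D_px2_s <- 3
  } else if (preset == "cell") {
    scene_def$D_px2_s <- 0.2
    scene_def$n_crossers <- 5L
  }
  scene <- utils::modifyList(scene_def, scene)
  tracker_def <- list(max_jump_px = if (preset == "agarose") 21 else 5,
                      band_low_px = 0.75, band_high_px = 1,
                      size_window = c(0.85, 1.5), brightness_min = 750,
                      min_track_length = 10L)
  tracker <- utils::modifyList(tracker_def, tracker)
  structure(list(preset = preset, seed = as.integer(seed),
                 acquisition = acquisition, scene = scene, tracker = tracker,
                 classifier = classifier, phasor_gates = phasor_gates,
                 recompute_threshold = isTRUE(recompute_threshold)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config: preset '%s', seed %d\n", x$preset, x$seed))
  cat(sprintf("  scene: %d particles (%d crossers), %d frames, D = %g px^2/s\n",
              x$scene$n_particles, x$scene$n_crossers, x$scene$n_frames,
              x$scene$D_px2_s))
  cat(sprintf("  tracker: max jump %g px, min length %d\n",
              x$tracker$max_jump_px, x$tracker$min_track_length))
  cat(sprintf("  classifier threshold: %s\n",
              if (x$recompute_threshold) "recomputed from this run's tracks"
              else sprintf("%.3f ns", x$classifier$threshold_ns)))
  invisible(x)
}

#' Serialize / parse a run configuration (YAML)
#'
#' Only constructor arguments are stored (derived quantities such as the
#' pulse period are rebuilt on parse), so `read_run_config(write_run_config(x))`
#' reproduces `x` exactly.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  a <- config$acquisition
  payload <- list(
    preset = config$preset, seed = config$seed,
    acquisition = list(
      rep_rate_hz = a$rep_rate_hz, dwell_time_s = a$dwell_time_s,
      dead_time_s = a$dead_time_s, n_microtime_bins = a$n_microtime_bins,
      frame_shape = a$frame_shape, frame_interval_s = a$frame_interval_s,
      irf_sigma_s = a$irf_sigma_s),
    # named atomic vectors serialize as YAML sequences (names dropped);
    # store the lifetime table as a map
    scene = utils::modifyList(
      config$scene,
      list(lifetime_table_ns = as.list(config$scene$lifetime_table_ns))),
    tracker = config$tracker,
    classifier = unclass(config$classifier),
    phasor_gates = config$phasor_gates,
    recompute_threshold = config$recompute_threshold)
  writeLines(yaml::as.yaml(payload, precision = 17), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  acq <- do.call(acq_config, utils::modifyList(
    y$acquisition, list(frame_shape = as.integer(unlist(y$acquisition$frame_shape)))))
  scene <- y$scene
  scene$lifetime_table_ns <- unlist(scene$lifetime_table_ns)
  scene$cell_radii <- as.numeric(unlist(scene$cell_radii))
  scene$nucleus_radii <- as.numeric(unlist(scene$nucleus_radii))
  for (f in c("n_particles", "n_crossers", "n_frames", "transition_frames"))
    scene[[f]] <- as.integer(scene[[f]])
  tracker <- y$tracker
  tracker$size_window <- as.numeric(unlist(tracker$size_window))
  tracker$min_track_length <- as.integer(tracker$min_track_length)
  gates <- y$phasor_gates
  if (!is.null(gates)) {
    gates <- lapply(gates, function(g)
      list(center = as.numeric(unlist(g$center)), radius = g$radius))
  }
  run_config(preset = y$preset, seed = y$seed, acquisition = acq,
             scene = scene, tracker = tracker,
             classifier = do.call(classifier_config, y$classifier),
             phasor_gates = gates,
             recompute_threshold = y$recompute_threshold)
}

#' Generate the ground-truth scene of a run
#'
#' Builds the compartment map (cell preset), simulates particle motion
#' (free for agarose, confined with scripted nuclear-boundary crossers for
#' cells) and assigns per-frame lifetimes.
#'
#' @param config a [run_config()]. Uses the current RNG state; seed the run
#'   with `set.seed(config$seed)` or use [run_pipeline()].
#' @return list with `map` (`NULL` for agarose) and `ground_truth`.
#' @export
simulate_scene <- function(config) {
  sc <- config$scene
  shape <- config$acquisition$frame_shape
  dt <- config$acquisition$frame_interval_s
  if (config$preset == "agarose" ||
      (config$preset == "custom" && is.null(sc$cell_radii))) {
    gt <- simulate_tracks(sc$n_particles, "free", sc$D_px2_s, sc$n_frames,
                          dt, shape,
                          start = cbind(runif(sc$n_particles, 5, shape[2] - 6),
                                        runif(sc$n_particles, 5, shape[1] - 6)))
    gt <- assign_lifetimes(gt, NULL, sc$lifetime_table_ns,
                           transition_frames = sc$transition_frames,
                           medium_sigma_ns = sc$medium_sigma_ns)
    return(list(map = NULL, ground_truth = gt))
  }
  map <- make_compartment_map(shape, cell_radii = sc$cell_radii,
                              nucleus_radii = sc$nucleus_radii,
                              band_px = sc$band_px)
  n <- sc$n_particles
  ncross <- min(sc$n_crossers, n)
  nc_center <- map$nucleus_center
  nuc_r <- mean(map$nucleus_radii)
  cell_r <- mean(map$cell_radii)
  start <- matrix(NA_real_, n, 2)
  drift <- matrix(0, n, 2)
  if (ncross > 0) {
    # crossers start in the cytoplasm just outside the nuclear envelope and
    # drift radially inward (directed transport), crossing mid-movie and
    # settling on a ring inside the nucleus (evenly spaced angles keep them
    # resolvable from one another throughout)
    theta <- seq(0, 2 * pi, length.out = ncross + 1)[-1] +
      runif(1, 0, 2 * pi / max(ncross, 1))
    r0 <- nuc_r + 5
    start[seq_len(ncross), ] <- cbind(nc_center[1] + r0 * cos(theta),
                                      nc_center[2] + r0 * sin(theta))
    r_end <- max(nuc_r - 4, 2)
    speed <- (r0 - r_end) / sc$n_frames
    drift[seq_len(ncross), ] <- -cbind(cos(theta), sin(theta)) * speed
  }
  if (n > ncross) {
    # the rest dwell in the outer cytoplasm, away from the nucleus, at
    # evenly spaced angles
    idx <- (ncross + 1):n
    theta <- seq(0, 2 * pi, length.out = length(idx) + 1)[-1] +
      runif(1, 0, 2 * pi / length(idx))
    rr <- runif(length(idx), nuc_r + 8, cell_r - 4)
    start[idx, ] <- cbind(map$cell_center[1] + rr * cos(theta),
                          map$cell_center[2] + rr * sin(theta))
  }
  gt <- simulate_tracks(n, "confined", sc$D_px2_s, sc$n_frames, dt, shape,
                        region = map, start = start, drift_px_frame = drift)
  gt <- assign_lifetimes(gt, map, sc$lifetime_table_ns,
                         transition_frames = sc$transition_frames,
                         medium_sigma_ns = sc$medium_sigma_ns)
  list(map = map, ground_truth = gt)
}

#' Run the full simulate-render-track-classify pipeline
#'
#' Executes every stage with a single seed and writes all stage outputs and
#' a manifest into `out_dir`: ground truth (CSV + JSON), the two-channel
#' intensity/lifetime TIFF stack, the phasor cloud (CSV), detections and
#' tracks (CSV), per-track classification (CSV), a JSON summary (threshold,
#' class counts, boundary odds ratio, photon totals and sustained count
#' rate) and a manifest with MD5 checksums of every output. Identical
#' configurations and seeds produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`scene`, `movie`, `tracks`, `classified`, `summary`, `files`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  path <- function(f) file.path(out_dir, f)
  files <- character(0)

  write_run_config(config, path("run_config.yaml"))
  files <- c(files, "run_config.yaml")

  scene <- simulate_scene(config)
  write_ground_truth(scene$ground_truth, path("ground_truth.csv"))
  files <- c(files, "ground_truth.csv", "ground_truth.csv.json")

  sc <- config$scene
  movie <- render_movie(scene$ground_truth, config$acquisition,
                        psf_sigma_px = sc$psf_sigma_px,
                        photons_per_particle_frame = sc$photons_per_particle_frame,
                        background_rate = sc$background_rate,
                        background_tau_ns = sc$background_tau_ns,
                        collapse = TRUE, phasor = TRUE)
  write_two_channel_tiff(movie, path("movie.tif"))
  files <- c(files, "movie.tif", "movie.tif.json")
  write.csv(movie$phasor, path("phasor.csv"), row.names = FALSE)
  files <- c(files, "phasor.csv")
  if (!is.null(config$phasor_gates) && nrow(movie$phasor)) {
    gates <- lapply(names(config$phasor_gates), function(nm)
      phasor_gate(nm, config$phasor_gates[[nm]]$center,
                  config$phasor_gates[[nm]]$radius))
    write.csv(gate_fractions(movie$phasor, gates),
              path("gate_fractions.csv"), row.names = FALSE)
    files <- c(files, "gate_fractions.csv")
  }

  trk <- config$tracker
  detections <- detect_movie(movie, trk$band_low_px, trk$band_high_px,
                             trk$size_window, trk$brightness_min)
  write.csv(detections, path("detections.csv"), row.names = FALSE)
  files <- c(files, "detections.csv")
  tracks <- link_tracks(detections, trk$max_jump_px, trk$min_track_length)
  write_track_table(tracks, path("tracks.csv"))
  files <- c(files, "tracks.csv")

  cls_cfg <- config$classifier
  cls_cfg$min_track_length <- trk$min_track_length
  threshold_src <- "config"
  if (config$recompute_threshold && nrow(tracks)) {
    series <- lapply(split(tracks, tracks$track_id), sample_track_lifetimes,
                     lifetime_images = movie,
                     sampling_radius_px = cls_cfg$sampling_radius_px)
    ds <- delta_stats(series)
    cls_cfg$threshold_ns <- ds$mean_delta_ns
    threshold_src <- sprintf("recomputed from %d deltas", ds$n)
  }
  classified <- classify_tracks(tracks, movie, cls_cfg)
  cls_out <- as.data.frame(classified)
  orat <- NULL
  if (!is.null(scene$map) && nrow(cls_out)) {
    brep <- boundary_report(classified, scene$map, sc$band_px)
    cls_out$zone <- brep$zone
    orat <- brep$odds_ratio
  }
  write.csv(cls_out, path("classified.csv"), row.names = FALSE)
  files <- c(files, "classified.csv")

  total_photons <- sum(vapply(movie$images, function(f) sum(f$intensity),
                              numeric(1)))
  frame_pixels <- prod(config$acquisition$frame_shape)
  live_time <- frame_pixels * config$acquisition$dwell_time_s
  summary <- list(
    preset = config$preset, seed = config$seed,
    threshold_ns = cls_cfg$threshold_ns, threshold_source = threshold_src,
    n_tracks = length(unique(tracks$track_id)),
    class_counts = as.list(table(cls_out$label)),
    boundary_odds_ratio = orat,
    total_photons = total_photons,
    sustained_rate_mcps = total_photons /
      (length(movie$images) * live_time) / 1e6)
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, "summary.json")

  manifest <- list(
    package = "flimtrack",
    version = as.character(utils::packageVersion("flimtrack")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(path("run_config.yaml"))),
    outputs = as.list(vapply(files, function(f)
      unname(tools::md5sum(path(f))), character(1))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(scene = scene, movie = movie, tracks = tracks,
                 classified = classified, summary = summary,
                 files = c(files, "manifest.json")))
}
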