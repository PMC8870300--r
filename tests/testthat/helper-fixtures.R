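# Shared fixtures: small jitter-free acquisition configs, analytic decay
# histograms, and an event-driven reference detector written independently
# of the C++ simulator (used as the brute-force oracle for dead-time
# throughput).

test_cfg <- function(dead_ns = 0, irf_ns = 0, frame_shape = c(32L, 32L),
                     nbins = 250L, frame_interval_s = 1) {
  acq_config(dead_time_s = dead_ns * 1e-9, irf_sigma_s = irf_ns * 1e-9,
             n_microtime_bins = nbins, frame_shape = frame_shape,
             frame_interval_s = frame_interval_s)
}

# noiseless histogram of a monoexponential decay wrapped into one period
analytic_decay <- function(tau_ns, config, total = 1e6) {
  nb <- config$n_microtime_bins
  period <- pulse_period_ns(config)
  edges <- seq(0, period, length.out = nb + 1)
  p <- exp(-edges[-(nb + 1)] / tau_ns) - exp(-edges[-1] / tau_ns)
  p / sum(p) * total
}

# independent event-driven detector: emit Bernoulli(p) (or Poisson) photons
# pulse by pulse, apply a non-paralyzable dead time by a plain R loop
oracle_detect <- function(p, tau_ns, dead_ns, period_ns, n_pulses,
                          poisson = FALSE) {
  n <- if (poisson) rpois(n_pulses, p) else rbinom(n_pulses, 1, min(p, 1))
  tot <- sum(n)
  pulse <- rep(seq_len(n_pulses) - 1, n)
  t <- sort(pulse * period_ns + rexp(tot, 1 / tau_ns))
  last <- -Inf
  keep <- logical(length(t))
  for (i in seq_along(t)) {
    if (t[i] - last >= dead_ns) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  list(micro = t[keep] %% period_ns, n_detected = sum(keep),
       n_emitted = tot,
       rate_cps = sum(keep) / (n_pulses * period_ns * 1e-9))
}

# ground truth scene + rendered movie used by the tracking and
# classification tests: confined cell scene with scripted nuclear-boundary
# crossers (positives) and outer-cytoplasm dwellers (negatives)
make_cell_run <- function(n_crossers = 8, n_dwellers = 12, n_frames = 25,
                          frame_px = 64, photons = 1000, seed = 1,
                          nucleus_radii = 12) {
  cfg <- acq_config(frame_shape = c(frame_px, frame_px),
                    frame_interval_s = 2.62)
  config <- run_config("cell", seed = seed, acquisition = cfg,
                       scene = list(n_particles = n_crossers + n_dwellers,
                                    n_crossers = n_crossers,
                                    n_frames = n_frames,
                                    nucleus_radii = nucleus_radii,
                                    photons_per_particle_frame = photons))
  set.seed(seed)
  scene <- simulate_scene(config)
  movie <- render_movie(scene$ground_truth, cfg,
                        photons_per_particle_frame = photons,
                        background_rate = config$scene$background_rate)
  list(config = config, scene = scene, movie = movie)
}

make_agarose_run <- function(n_particles = 14, n_frames = 25, frame_px = 64,
                             photons = 1000, seed = 2) {
  cfg <- acq_config(frame_shape = c(frame_px, frame_px),
                    frame_interval_s = 2.62)
  config <- run_config("agarose", seed = seed, acquisition = cfg,
                       scene = list(n_particles = n_particles,
                                    n_frames = n_frames,
                                    photons_per_particle_frame = photons))
  set.seed(seed)
  scene <- simulate_scene(config)
  movie <- render_movie(scene$ground_truth, cfg,
                        photons_per_particle_frame = photons,
                        background_rate = config$scene$background_rate)
  list(config = config, scene = scene, movie = movie)
}

# match each track to the nearest ground-truth particle by mean distance
# over shared frames; returns the particle id (or NA)
match_tracks_to_truth <- function(tracks, ground_truth, max_dist = 3) {
  gt <- ground_truth$tracks
  vapply(unique(tracks$track_id), function(id) {
    tr <- tracks[tracks$track_id == id, ]
    best <- NA_integer_; bestd <- Inf
    for (pid in unique(gt$particle)) {
      g <- gt[gt$particle == pid, ]
      common <- intersect(tr$frame, g$frame)
      if (length(common) < 3) next
      d <- sqrt((tr$x[match(common, tr$frame)] -
                   g$x[match(common, g$frame)])^2 +
                (tr$y[match(common, tr$frame)] -
                   g$y[match(common, g$frame)])^2)
      if (mean(d) < bestd) { bestd <- mean(d); best <- pid }
    }
    if (bestd <= max_dist) best else NA_integer_
  }, integer(1))
}
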