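test_that("compartment map builds nested cell geometry", {
  map <- make_compartment_map(c(64, 64), cell_radii = 25, nucleus_radii = 8)
  expect_setequal(unique(as.vector(map$labels)),
                  c("extracellular", "cytoplasm", "nucleus"))
  # nucleus strictly inside the cell: every nucleus pixel is within the cell
  nuc <- map$labels == "nucleus"
  inside_cell <- map$labels != "extracellular"
  expect_true(all(inside_cell[nuc]))
  expect_lt(sum(nuc), sum(inside_cell))
})

test_that("degenerate nucleus and invalid geometry are handled", {
  map <- make_compartment_map(c(64, 64), cell_radii = 25, nucleus_radii = 0)
  expect_setequal(unique(as.vector(map$labels)),
                  c("extracellular", "cytoplasm"))
  expect_error(make_compartment_map(c(64, 64), cell_radii = 10,
                                    nucleus_radii = 15),
               "not contained")
})

test_that("boundary band pixel count matches a brute-force distance test", {
  # circular cell so the Euclidean distance to the boundary is exact
  shape <- c(64, 64); center <- c(31.5, 31.5); R <- 20; band <- 2
  map <- make_compartment_map(shape, cell_center = center, cell_radii = R,
                              nucleus_radii = 0, band_px = band)
  x <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  y <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1])
  dist <- sqrt((x - center[1])^2 + (y - center[2])^2)
  shell <- abs(dist - R) <= band
  expect_identical(map$boundary_masks$cell, shell)
  expect_equal(sum(map$boundary_masks$cell), sum(shell))
})

test_that("free Brownian steps reproduce the 2-D MSD 4 D dt", {
  D <- 2; dt <- 0.5
  gt <- simulate_tracks(50, "free", D, 40, dt, c(512, 512), seed = 11)
  tr <- gt$tracks
  steps <- do.call(rbind, lapply(split(tr, tr$particle), function(g) {
    cbind(diff(g$x), diff(g$y))
  }))
  msd <- mean(rowSums(steps^2))        # ~2000 steps
  expect_equal(msd, 4 * D * dt, tolerance = 0.1)
  expect_error(simulate_tracks(3, "free", -1, 10, 1, c(64, 64)))
})

test_that("confined motion never leaves the cell and is seed-reproducible", {
  map <- make_compartment_map(c(64, 64), cell_radii = 20, nucleus_radii = 6)
  gt1 <- simulate_tracks(8, "confined", 5, 30, 2, c(64, 64), region = map,
                         seed = 5)
  gt2 <- simulate_tracks(8, "confined", 5, 30, 2, c(64, 64), region = map,
                         seed = 5)
  expect_identical(gt1$tracks, gt2$tracks)
  rn <- ellipse_rnorm(gt1$tracks$x, gt1$tracks$y, map$cell_center,
                      map$cell_radii)
  expect_true(all(rn <= 1 + 1e-9))
  expect_false(any(gt1$tracks$exited))
})

test_that("lifetime assignment follows compartments with step or ramp", {
  map <- make_compartment_map(c(64, 64), cell_radii = 25, nucleus_radii = 8)
  tab <- c(extracellular = 2, cytoplasm = 3, nucleus = 3.8)
  # particle fixed in the cytoplasm
  gt <- simulate_tracks(1, "confined", 0, 10, 1, c(64, 64), region = map,
                        start = matrix(c(31.5 + 15, 31.5), 1), seed = 1)
  gt <- assign_lifetimes(gt, map, tab)
  expect_equal(gt$tracks$tau_ns, rep(3, 10))
  # scripted crossing: drift carries the particle into the nucleus
  gt2 <- simulate_tracks(1, "confined", 0, 20, 1, c(64, 64), region = map,
                         start = matrix(c(31.5 + 12, 31.5), 1),
                         drift_px_frame = c(-1, 0), seed = 1)
  gt2 <- assign_lifetimes(gt2, map, tab)
  expect_setequal(unique(gt2$tracks$tau_ns), c(3, 3.8))
  # k = 0 transition is a step at the crossing frame (no intermediates)
  expect_true(all(gt2$tracks$tau_ns %in% c(3, 3.8)))
  # ramped transition inserts intermediate values
  gt3 <- assign_lifetimes(gt2, map, tab, transition_frames = 3)
  expect_true(any(!(gt3$tracks$tau_ns %in% c(3, 3.8))))
  expect_error(assign_lifetimes(gt2, map, c(cytoplasm = 3)), "missing")
})

test_that("zero-dead-time histogram follows the truncated exponential law", {
  cfg <- test_cfg(dead_ns = 0, nbins = 50)
  d <- simulate_pixel_photons(0.5, 4, cfg, n_pulses = 1e5, seed = 3)
  expect_gte(d$n_detected, 1e4)
  period <- pulse_period_ns(cfg)
  edges <- seq(0, period, length.out = 51)
  p <- exp(-edges[-51] / 4) - exp(-edges[-1] / 4)
  gof <- suppressWarnings(chisq.test(d$counts, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
  # and its mean matches the closed form within sampling error
  m <- sum(d$counts * (seq_len(50) - 0.5) * period / 50) / d$n_detected
  expect_equal(m, truncated_exp_mean(4, period),
               tolerance = 3 * 4 / sqrt(d$n_detected) / 4)
})

test_that("detector throughput is non-increasing in dead time and matches the oracle", {
  rates <- vapply(c(0, 2, 10, 25, 50, 100), function(dead) {
    d <- simulate_pixel_photons(1, 3, test_cfg(dead_ns = dead),
                                n_pulses = 2e5, seed = 7)
    sustained_rate_cps(d)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # brute-force event-driven oracle at saturating emission
  set.seed(8)
  o50 <- oracle_detect(1, 3, 50, 25, 2e5)
  o2 <- oracle_detect(1, 3, 2, 25, 2e5)
  d50 <- simulate_pixel_photons(1, 3, test_cfg(dead_ns = 50),
                                n_pulses = 2e5, seed = 9)
  d2 <- simulate_pixel_photons(1, 3, test_cfg(dead_ns = 2),
                               n_pulses = 2e5, seed = 9)
  expect_equal(sustained_rate_cps(d50), o50$rate_cps, tolerance = 0.02)
  expect_equal(sustained_rate_cps(d2), o2$rate_cps, tolerance = 0.02)
  # short dead time sustains ~the repetition rate
  expect_equal(sustained_rate_cps(d2), 40e6, tolerance = 0.01)
})

test_that("multi-photon pileup skews the decay early at a generic long dead time", {
  # 48 ns dead time (not an exact multiple of the 25 ns period): the first
  # eligible photon of a period is preferentially early, shortening the
  # apparent lifetime as the emission rate rises
  cfg <- test_cfg(dead_ns = 48)
  taus <- vapply(c(0.01, 0.1, 0.5, 1), function(lam) {
    np <- if (lam < 0.05) 2e6 else 5e5
    d <- simulate_pixel_photons(lam, 3, cfg, n_pulses = np,
                                emission_model = "poisson", seed = 21)
    fast_lifetime(d, cfg)
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_lt(taus[4], 2.8)
})

test_that("photon simulation is reproducible under a fixed seed", {
  cfg <- test_cfg(dead_ns = 2, irf_ns = 0.2)
  a <- simulate_pixel_photons(0.3, 3, cfg, n_pulses = 1e4, seed = 42)
  b <- simulate_pixel_photons(0.3, 3, cfg, n_pulses = 1e4, seed = 42)
  expect_identical(a$counts, b$counts)
})

test_that("rendered movies conserve photons and place particles correctly", {
  cfg <- test_cfg(dead_ns = 2, frame_shape = c(24L, 24L))
  # background only: total counts ~ Poisson with the configured mean
  empty <- render_movie(NULL, cfg, background_rate = 2, collapse = FALSE,
                        seed = 1)
  tot <- sum(empty$images[[1]]$intensity)
  expect_equal(tot, 2 * 24 * 24, tolerance = 5 / sqrt(2 * 576))
  # conservation: intensity channel equals the histogram totals exactly
  expect_identical(sum(empty$decays[[1]]), as.integer(tot))
  # one bright static particle: the intensity maximum is at its pixel
  gt <- simulate_tracks(1, "free", 0, 2, 1, c(24, 24),
                        start = matrix(c(10, 14), 1), seed = 2)
  gt <- assign_lifetimes(gt, NULL, c(extracellular = 3))
  mv <- render_movie(gt, cfg, photons_per_particle_frame = 2000,
                     background_rate = 0.1, seed = 3)
  peak <- which(mv$images[[1]]$intensity == max(mv$images[[1]]$intensity),
                arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(14 + 1, 10 + 1))  # (row, col) of (x=10, y=14)
  # determinism
  mv2 <- render_movie(gt, cfg, photons_per_particle_frame = 2000,
                      background_rate = 0.1, seed = 3)
  expect_identical(mv$images[[1]]$intensity, mv2$images[[1]]$intensity)
})
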