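uniform_image <- function(tau, shape = c(16, 16), counts = 100) {
  structure(list(intensity = matrix(counts, shape[1], shape[2]),
                 lifetime_ns = matrix(tau, shape[1], shape[2]),
                 frame_index = 1L, frame_time_s = 0),
            class = "lifetime_image")
}

test_that("track lifetimes are intensity-weighted neighborhood means", {
  imgs <- list(uniform_image(3), uniform_image(3))
  track <- data.frame(frame = c(1, 2), x = c(8, 8.4), y = c(8, 8.1))
  expect_equal(sample_track_lifetimes(track, imgs, 3), c(3, 3))
  # stated weighting: tau 2 ns at 100 counts with tau 4 ns at 300 counts
  img <- uniform_image(NA_real_, counts = 0)
  img$lifetime_ns[8, 8] <- 2; img$intensity[8, 8] <- 100
  img$lifetime_ns[8, 9] <- 4; img$intensity[8, 9] <- 300
  got <- sample_track_lifetimes(data.frame(frame = 1, x = 7.5, y = 7),
                                list(img), 3)
  expect_equal(got, (2 * 100 + 4 * 300) / 400)
  # no defined pixel in the neighborhood: undefined entry, track retained
  far <- sample_track_lifetimes(data.frame(frame = c(1, 1), x = c(1, 7.5),
                                           y = c(1, 7)), list(img), 2)
  expect_true(is.na(far[1]) && far[2] == 3.5)
  expect_error(sample_track_lifetimes(data.frame(frame = 9, x = 1, y = 1),
                                      list(img), 3), "outside")
})

test_that("moving-median smoothing removes spikes, keeps endpoints, skips NA", {
  expect_equal(smooth_series(c(2, 2, 2, 2)), c(2, 2, 2, 2))
  # single-frame spike removed
  expect_equal(smooth_series(c(2, 2, 3.5, 2, 2)), c(2, 2, 2, 2, 2))
  # endpoint pass-through
  expect_equal(smooth_series(c(1, 4, 1)), c(1, 1, 1))
  # undefined entries are excluded from windows, not interpolated
  expect_equal(smooth_series(c(2, NA, 3, 2.5, 2)), c(2, NA, 2.75, 2.5, 2))
  allna <- rep(NA_real_, 5)
  expect_equal(smooth_series(allna), allna)
  expect_error(smooth_series(1:5, window = 2))
})

test_that("smoothing never increases the lifetime range", {
  set.seed(43)
  for (i in 1:50) {
    s <- rnorm(sample(5:30, 1), 3, 0.5)
    s[sample(length(s), 2)] <- NA
    sm <- smooth_series(s)
    if (sum(!is.na(sm)) < 2 || sum(!is.na(s)) < 2) next
    expect_lte(diff(range(sm, na.rm = TRUE)), diff(range(s, na.rm = TRUE)))
  }
})

test_that("delta statistics pool consecutive defined pairs", {
  fit <- delta_stats(list(c(2.0, 2.2, 2.1)))
  expect_equal(fit$deltas_ns, c(0.2, 0.1))
  expect_equal(fit$mean_delta_ns, 0.15)
  expect_equal(fit$n, 2)
  # constant series: zero variation
  expect_equal(delta_stats(list(rep(3, 7)))$mean_delta_ns, 0)
  # NA breaks adjacency: no delta is formed across the gap
  fit2 <- delta_stats(list(c(2, NA, 3, 3.4)))
  expect_equal(fit2$deltas_ns, 0.4)
  expect_error(delta_stats(list(c(1), c(NA, 2))), "no valid")
})

test_that("control delta mean scales with photon noise as 1/sqrt(photons)", {
  # homogeneous-medium controls so the deltas are photon-noise dominated:
  # halving the photons per frame should inflate the mean |delta| by ~sqrt(2)
  sim_mean_delta <- function(photons, seed) {
    set.seed(seed)
    series <- replicate(60, {
      ests <- vapply(1:12, function(f) {
        h <- rexp(photons, 1 / 3) %% 25
        counts <- tabulate(pmin(floor(h / 0.1) + 1, 250), 250)
        fast_lifetime(counts, test_cfg())
      }, numeric(1))
      ests
    }, simplify = FALSE)
    delta_stats(series)$mean_delta_ns
  }
  m1 <- sim_mean_delta(400, 47)
  m2 <- sim_mean_delta(200, 48)
  expect_equal(m2 / m1, sqrt(2), tolerance = 0.15)
})

test_that("classification thresholds the smoothed range with a strict rule", {
  cfg <- classifier_config(threshold_ns = 0.39, min_track_length = 4)
  # range 0.50 ns exceeds the 0.39 ns threshold
  up <- classify_series(c(3, 3.1, 3.5, 3.5, 3.45, 3.5), cfg)
  expect_equal(up$label, "above_threshold")
  expect_gt(up$lifetime_range_ns, 0.39)
  # constant series stays below
  expect_equal(classify_series(rep(3, 6), cfg)$label, "below_threshold")
  # a range of exactly the threshold is NOT above (strict inequality;
  # binary-exact values so the tie is a true tie)
  cfg_tie <- classifier_config(threshold_ns = 0.5, min_track_length = 4)
  tie <- classify_series(c(rep(3, 4), rep(3.5, 4)), cfg_tie)
  expect_identical(tie$lifetime_range_ns, 0.5)
  expect_equal(tie$label, "below_threshold")
  # too-short or too-sparse tracks are unclassified, not an error
  expect_equal(classify_series(c(3, 3.2), cfg)$label, "unclassified")
  expect_equal(classify_series(c(3, NA, NA, NA, NA, NA), cfg)$label,
               "unclassified")
})

test_that("classification is invariant to time reversal", {
  cfg <- classifier_config(min_track_length = 5)
  set.seed(51)
  for (i in 1:20) {
    s <- rnorm(12, 3, 0.3)
    a <- classify_series(s, cfg)
    b <- classify_series(rev(s), cfg)
    expect_equal(a$label, b$label)
    expect_equal(a$lifetime_range_ns, b$lifetime_range_ns)
  }
})

test_that("boundary report detects enrichment and has a calibrated null", {
  map <- make_compartment_map(c(64, 64), cell_radii = 24, nucleus_radii = 8)
  # complete separation: all above-threshold tracks at the cell boundary
  band <- which(boundary_band(map, 2), arr.ind = TRUE)
  interior_px <- which(map$labels == "cytoplasm" & !boundary_band(map, 2),
                       arr.ind = TRUE)
  mk <- function(px, label, ids) data.frame(
    track_id = ids, n_frames = 12, lifetime_range_ns = 0.5,
    label = label, median_x = px[seq_along(ids), 2] - 1,
    median_y = px[seq_along(ids), 1] - 1)
  cls <- rbind(mk(band, "above_threshold", 1:6),
               mk(interior_px, "below_threshold", 7:12))
  attr(cls, "threshold_ns") <- 0.39
  class(cls) <- c("classified_tracks", "data.frame")
  rep1 <- boundary_report(cls, map, band_px = 2)
  expect_true(rep1$complete_separation)
  expect_true(is.infinite(rep1$odds_ratio))
  expect_error(boundary_report(cls, map, band_px = 0))
  # permutation null: shuffled labels give odds ratios centered near 1
  set.seed(53)
  mixed <- rbind(mk(band, "above_threshold", 1:10),
                 mk(interior_px, "above_threshold", 11:20),
                 mk(band[11:20, ], "below_threshold", 21:30),
                 mk(interior_px[11:20, ], "below_threshold", 31:40))
  attr(mixed, "threshold_ns") <- 0.39
  class(mixed) <- c("classified_tracks", "data.frame")
  rep2 <- boundary_report(mixed, map, band_px = 2, n_perm = 100)
  gm <- exp(mean(log(rep2$perm_odds_ratios[is.finite(rep2$perm_odds_ratios) &
                                             rep2$perm_odds_ratios > 0])))
  expect_equal(gm, 1, tolerance = 0.5)
})
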