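gauss_spot <- function(shape, x0, y0, total, sigma = 1, offset = 0) {
  m <- matrix(offset, shape[1], shape[2])
  x <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  y <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1])
  m + total / (2 * pi * sigma^2) *
    exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
}

test_that("band-pass preprocessing removes offsets and large-scale gradients", {
  flat <- matrix(7, 48, 48)
  expect_lt(max(abs(preprocess_frame(flat))), 1e-6)
  # pure large-scale ramp: suppressed below 5% of its amplitude (interior)
  ramp <- matrix(rep(seq(0, 100, length.out = 48), each = 48), 48,
                 byrow = FALSE)
  f <- preprocess_frame(ramp)
  interior <- f[13:36, 13:36]
  expect_lt(max(abs(interior)), 0.05 * 100)
  # a particle-scale spot on a flat offset survives with its peak position
  img <- gauss_spot(c(48, 48), 20, 30, total = 1000, sigma = 0.9,
                    offset = 50)
  fs <- preprocess_frame(img)
  peak <- which(fs == max(fs), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(31, 21))  # (row, col) for (x=20, y=30)
  expect_gt(max(fs), 10)
  expect_error(preprocess_frame(flat, band_low_px = 1, band_high_px = 0.5))
})

test_that("spot detection refines to sub-pixel accuracy and applies filters", {
  set.seed(17)
  errs <- replicate(40, {
    x0 <- runif(1, 10, 20); y0 <- runif(1, 10, 20)
    img <- gauss_spot(c(32, 32), x0, y0, total = 2000, sigma = 1, offset = 5)
    img <- matrix(rpois(length(img), img), nrow(img))
    d <- detect_spots(preprocess_frame(img), raw = img,
                      brightness_min = 750)
    if (nrow(d) != 1) return(NA_real_)
    sqrt((d$x - x0)^2 + (d$y - y0)^2)
  })
  expect_true(all(!is.na(errs)))
  expect_lt(mean(errs), 0.15)
  # dim spots are removed by the brightness window
  dim_img <- gauss_spot(c(32, 32), 15, 15, total = 300, sigma = 1)
  expect_equal(nrow(detect_spots(dim_img, brightness_min = 750,
                                 peak_min = 1)), 0)
  # out-of-band widths are rejected
  wide <- gauss_spot(c(32, 32), 15, 15, total = 5000, sigma = 3)
  expect_equal(nrow(detect_spots(wide, size_window = c(0.85, 1.5),
                                 brightness_min = 100, peak_min = 1)), 0)
  # two separated spots give two detections
  two <- gauss_spot(c(32, 32), 10, 10, 2000) + gauss_spot(c(32, 32), 20, 20, 2000)
  d2 <- detect_spots(two, brightness_min = 750, peak_min = 10)
  expect_equal(nrow(d2), 2)
})

test_that("linking respects the jump gate and minimum track length", {
  # two detections 3 px apart in consecutive frames are linked ...
  d <- data.frame(frame = c(1, 2), x = c(10, 13), y = c(5, 5),
                  brightness = 1000)
  t1 <- link_tracks(d, max_jump_px = 5, min_track_length = 2)
  expect_equal(length(unique(t1$track_id)), 1)
  # ... 6 px apart they are not, and both fragments are discarded
  d$x[2] <- 16
  t2 <- link_tracks(d, max_jump_px = 5, min_track_length = 2)
  expect_equal(nrow(t2), 0)
})

test_that("two-particle instance is recovered exactly (brute-force check)", {
  # one moving + one static particle, far apart: the optimal per-pair
  # assignment (enumerated by hand for 2x2: match or cross) must link each
  # to itself
  frames <- 1:12
  det <- rbind(
    data.frame(frame = frames, x = 5 + 0.8 * (frames - 1), y = 5,
               brightness = 1000),
    data.frame(frame = frames, x = 40, y = 40, brightness = 900))
  tr <- link_tracks(det, max_jump_px = 5, min_track_length = 10)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    g <- tr[tr$track_id == id, ]
    expect_equal(g$frame, frames)
    # a track never mixes the two particles
    expect_true(all(g$y == 5) || all(g$y == 40))
  }
  # hard invariant: no emitted link exceeds the maximum jump
  jumps <- unlist(lapply(split(tr, tr$track_id), function(g)
    sqrt(diff(g$x)^2 + diff(g$y)^2)))
  expect_true(all(jumps <= 5))
})

test_that("linking is invariant to detection order within frames", {
  set.seed(19)
  det <- do.call(rbind, lapply(1:12, function(f)
    data.frame(frame = f, x = c(5, 15, 25) + rnorm(3, 0, 0.5),
               y = c(20, 10, 25) + rnorm(3, 0, 0.5), brightness = 1000)))
  shuffled <- det[sample(nrow(det)), ]
  a <- link_tracks(det, 5, 10)
  b <- link_tracks(shuffled, 5, 10)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("ground-truth links are recovered on a rendered low-density movie", {
  cfg <- test_cfg(dead_ns = 2, frame_shape = c(48L, 48L), irf_ns = 0.2,
                  frame_interval_s = 1)
  set.seed(23)
  gt <- simulate_tracks(3, "free", D_px2_s = 0.5, n_frames = 15,
                        frame_interval_s = 1, frame_shape = c(48, 48),
                        start = rbind(c(10, 10), c(38, 12), c(24, 38)))
  gt <- assign_lifetimes(gt, NULL, c(extracellular = 3))
  mv <- render_movie(gt, cfg, photons_per_particle_frame = 1500,
                     background_rate = 0.1)
  det <- detect_movie(mv, brightness_min = 750)
  tr <- link_tracks(det, max_jump_px = 5, min_track_length = 10)
  matched <- match_tracks_to_truth(tr, gt, max_dist = 1)
  expect_equal(length(unique(tr$track_id)), 3)
  expect_true(all(!is.na(matched)))
  expect_equal(sort(unique(matched)), 1:3)
  # link recovery: every consecutive ground-truth pair is present
  recovered <- sum(vapply(unique(tr$track_id), function(id)
    nrow(tr[tr$track_id == id, ]) - 1, numeric(1)))
  expect_gte(recovered / (3 * 14), 0.95)
})
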