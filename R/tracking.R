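#' Band-pass preprocessing of an intensity frame
#'
#' Subtracts the large-scale smooth background and suppresses sub-band noise
#' with a difference of Gaussians: the frame is smoothed at `band_low_px`
#' (noise scale) and the background is estimated by smoothing at
#' `bg_scale * band_high_px` (well above the particle scale), then
#' subtracted. Constant offsets and slowly varying gradients vanish; spots
#' of roughly `band_low_px`--`band_high_px` width are retained.
#'
#' @param frame numeric intensity matrix.
#' @param band_low_px lower band edge (px, `> 0`).
#' @param band_high_px upper band edge (px, `> band_low_px`).
#' @param bg_scale background smoothing scale as a multiple of
#'   `band_high_px`.
#' @return Filtered matrix of the same shape.
#' @export
preprocess_frame <- function(frame, band_low_px = 0.75, band_high_px = 1,
                             bg_scale = 8) {
  stopifnot(band_low_px > 0, band_high_px > band_low_px)
  sm <- gaussian_smooth(frame, band_low_px)
  bg <- gaussian_smooth(frame, bg_scale * band_high_px)
  sm - bg
}

# Gaussian smoothing with replicate boundary handling (EBImage::filter2 pads
# circularly by default, which leaks opposite edges into the background
# estimate).
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- EBImage::makeBrush(2 * r + 1, shape = "gaussian", sigma = sigma)
  pad <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)),
           c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r))]
  f <- EBImage::filter2(pad, k)
  f[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
}

#' Detect sub-pixel particles in a frame
#'
#' Finds local maxima of the (typically band-pass filtered) frame, refines
#' each with a 2-D Gaussian fit (amplitude, sub-pixel center, width, offset)
#' on a small window, and keeps detections whose fitted width lies within
#' `size_window` and whose brightness (total fitted spot counts,
#' `2 * pi * A * sigma^2`) reaches `brightness_min`.
#'
#' @param frame matrix used for local-maximum finding (band-pass filtered).
#' @param raw matrix used for the Gaussian fit and brightness measurement;
#'   defaults to `frame`. Use the unfiltered intensity channel so that
#'   brightness is in photon units.
#' @param size_window numeric `c(lo, hi)` of acceptable fitted Gaussian
#'   widths (px).
#' @param brightness_min minimum spot brightness (counts); dimmer spots are
#'   removed.
#' @param peak_min minimum filtered-frame value for a candidate maximum;
#'   defaults to 3 standard deviations of the filtered frame.
#' @param fit_radius half-width of the fit window (px).
#' @return data.frame of detections (`x, y, frame, brightness, sigma_px,
#'   peak`), 0-based sub-pixel coordinates; zero rows when nothing is found.
#' @export
detect_spots <- function(frame, raw = frame, size_window = c(0.85, 1.5),
                         brightness_min = 750, peak_min = NULL,
                         fit_radius = 3L) {
  stopifnot(length(size_window) == 2, size_window[1] > 0,
            size_window[2] > size_window[1], brightness_min >= 0)
  if (is.null(peak_min)) peak_min <- 3 * sd(as.vector(frame))
  nr <- nrow(frame); nc <- ncol(frame)
  empty <- data.frame(x = numeric(), y = numeric(), frame = integer(),
                      brightness = numeric(), sigma_px = numeric(),
                      peak = numeric())
  # 3x3 local maxima above the floor
  cand <- which(frame >= peak_min, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
               cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    frame[r, c] >= max(frame[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  dets <- lapply(seq_len(nrow(cand)), function(i) {
    fit_gaussian_spot(raw, cand[i, 1], cand[i, 2], fit_radius)
  })
  dets <- do.call(rbind, dets)
  dets <- dets[!is.na(dets$sigma_px), , drop = FALSE]
  if (!nrow(dets)) return(empty)
  keep <- dets$sigma_px >= size_window[1] & dets$sigma_px <= size_window[2] &
    dets$brightness >= brightness_min &
    dets$x >= 0 & dets$x <= nc - 1 & dets$y >= 0 & dets$y <= nr - 1
  dets <- dets[keep, , drop = FALSE]
  # merge duplicate maxima that converged to the same spot
  if (nrow(dets) > 1) {
    o <- order(-dets$brightness)
    dets <- dets[o, , drop = FALSE]
    sel <- rep(TRUE, nrow(dets))
    for (i in seq_len(nrow(dets))[-1]) {
      d2 <- (dets$x[seq_len(i - 1)] - dets$x[i])^2 +
            (dets$y[seq_len(i - 1)] - dets$y[i])^2
      if (any(sel[seq_len(i - 1)] & d2 < 1)) sel[i] <- FALSE
    }
    dets <- dets[sel, , drop = FALSE]
  }
  dets <- dets[order(dets$x, dets$y), , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

# least-squares 2-D Gaussian fit on a (2r+1)^2 window around a pixel maximum;
# returns NA sigma when the optimizer fails or wanders off the window
fit_gaussian_spot <- function(raw, row, col, r) {
  nr <- nrow(raw); nc <- ncol(raw)
  rows <- max(1, row - r):min(nr, row + r)
  cols <- max(1, col - r):min(nc, col + r)
  patch <- raw[rows, cols]
  ry <- rows - 1; cx <- cols - 1          # 0-based coordinates
  yy <- matrix(rep(ry, length(cx)), length(ry))
  xx <- matrix(rep(cx, each = length(ry)), length(ry))
  off0 <- min(patch)
  a0 <- max(patch) - off0
  p0 <- c(log(max(a0, 1e-6)), col - 1, row - 1, log(1), off0)
  obj <- function(p) {
    mu <- exp(p[1]) * exp(-((xx - p[2])^2 + (yy - p[3])^2) /
                            (2 * exp(2 * p[4]))) + p[5]
    sum((mu - patch)^2)
  }
  fit <- tryCatch(optim(p0, obj, method = "BFGS",
                        control = list(maxit = 300)),
                  error = function(e) NULL)
  bad <- data.frame(x = NA_real_, y = NA_real_, frame = NA_integer_,
                    brightness = NA_real_, sigma_px = NA_real_,
                    peak = NA_real_)
  if (is.null(fit)) return(bad)
  a <- exp(fit$par[1]); x0 <- fit$par[2]; y0 <- fit$par[3]
  s <- exp(fit$par[4])
  if (abs(x0 - (col - 1)) > r || abs(y0 - (row - 1)) > r) return(bad)
  data.frame(x = x0, y = y0, frame = NA_integer_,
             brightness = 2 * pi * a * s^2, sigma_px = s,
             peak = raw[row, col])
}

#' Detect particles in every frame of a movie
#'
#' Runs [preprocess_frame()] and [detect_spots()] on each intensity frame.
#'
#' @param movie a `flim_movie` or list of `lifetime_image` frames.
#' @inheritParams preprocess_frame
#' @inheritParams detect_spots
#' @return data.frame of detections with their 1-based `frame` index.
#' @export
detect_movie <- function(movie, band_low_px = 0.75, band_high_px = 1,
                         size_window = c(0.85, 1.5), brightness_min = 750,
                         peak_min = NULL) {
  frames <- movie_frames(movie)
  out <- lapply(seq_along(frames), function(f) {
    raw <- frames[[f]]$intensity
    filt <- preprocess_frame(raw, band_low_px, band_high_px)
    d <- detect_spots(filt, raw = raw, size_window = size_window,
                      brightness_min = brightness_min, peak_min = peak_min)
    if (nrow(d)) d$frame <- f
    d
  })
  do.call(rbind, out)
}

#' Link detections into tracks
#'
#' For each consecutive frame pair, solves the globally optimal one-to-one
#' assignment minimizing the summed squared displacement, with links beyond
#' `max_jump_px` forbidden (a detection is left unmatched rather than linked
#' farther than the jump bound). Unmatched detections start or end tracks;
#' there is no gap closing. Tracks spanning fewer than `min_track_length`
#' frames are discarded. Detections are first sorted by
#' `(frame, x, y, brightness)` so the result does not depend on input order.
#'
#' @param detections data.frame with columns `frame, x, y` (and optionally
#'   `brightness`, `sigma_px`).
#' @param max_jump_px maximum allowed frame-to-frame displacement (px, `> 0`).
#' @param min_track_length minimum number of (consecutive) frames.
#' @return A `track_table`: data.frame `track_id, frame, x, y, brightness`
#'   ordered by track and frame.
#' @export
link_tracks <- function(detections, max_jump_px, min_track_length = 10) {
  stopifnot(max_jump_px > 0, min_track_length >= 1)
  if (is.null(detections$brightness)) detections$brightness <- NA_real_
  d <- detections[order(detections$frame, detections$x, detections$y,
                        detections$brightness), , drop = FALSE]
  n <- nrow(d)
  track_of <- integer(n)
  next_id <- 1L
  if (n > 0) {
    frames <- sort(unique(d$frame))
    idx_by_frame <- split(seq_len(n), d$frame)
    # first frame: everything starts a track
    for (i in idx_by_frame[[as.character(frames[1])]]) {
      track_of[i] <- next_id; next_id <- next_id + 1L
    }
    gate2 <- max_jump_px^2
    BIG <- 1e12
    for (k in seq_along(frames)[-1]) {
      fa <- frames[k - 1]; fb <- frames[k]
      ib <- idx_by_frame[[as.character(fb)]]
      ia <- if (fb - fa == 1) idx_by_frame[[as.character(fa)]] else integer(0)
      matched_b <- rep(NA_integer_, length(ib))
      if (length(ia) && length(ib)) {
        n1 <- length(ia); n2 <- length(ib)
        cost <- outer(d$x[ia], d$x[ib], `-`)^2 + outer(d$y[ia], d$y[ib], `-`)^2
        cost[cost > gate2] <- BIG
        # augmented square matrix: unmatched rows/cols pay the gate cost, so
        # any in-gate pairing (cost <= gate2 < 2 * gate2) is preferred
        m <- n1 + n2
        full <- matrix(0, m, m)
        full[seq_len(n1), seq_len(n2)] <- cost
        full[seq_len(n1), n2 + seq_len(n1)] <-
          ifelse(diag(n1) == 1, gate2, BIG)
        full[n1 + seq_len(n2), seq_len(n2)] <-
          ifelse(diag(n2) == 1, gate2, BIG)
        assign <- solve_lsap(full)
        for (i in seq_len(n1)) {
          j <- assign[i]
          if (j <= n2 && cost[i, j] < BIG) matched_b[j] <- ia[i]
        }
      }
      for (jj in seq_along(ib)) {
        if (!is.na(matched_b[jj])) {
          track_of[ib[jj]] <- track_of[matched_b[jj]]
        } else {
          track_of[ib[jj]] <- next_id; next_id <- next_id + 1L
        }
      }
    }
  }
  d$track_id <- track_of
  keep_ids <- names(which(table(d$track_id) >= min_track_length))
  d <- d[d$track_id %in% as.integer(keep_ids), , drop = FALSE]
  d <- d[order(d$track_id, d$frame), ]
  # renumber compactly
  d$track_id <- as.integer(factor(d$track_id, levels = unique(d$track_id)))
  out <- d[, c("track_id", "frame", "x", "y", "brightness")]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("track table: %d tracks, %d detections, frames %d-%d\n",
              length(unique(x$track_id)), nrow(x),
              if (nrow(x)) min(x$frame) else NA,
              if (nrow(x)) max(x$frame) else NA))
  NextMethod()
}

#' Read / write track tables
#'
#' The CSV schema (`track_id, frame, x, y, brightness`) matches the exported
#' format, so externally produced track tables in the same layout can enter
#' the analysis here.
#' @param path CSV file path.
#' @return `read_track_table`: a `track_table` data.frame.
#' @export
read_track_table <- function(path) {
  d <- read.csv(path)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(d)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  if (is.null(d$brightness)) d$brightness <- NA_real_
  class(d) <- c("track_table", "data.frame")
  d
}

#' @rdname read_track_table
#' @param tracks a `track_table`.
#' @export
write_track_table <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
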