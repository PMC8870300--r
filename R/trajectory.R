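#' Classifier configuration for trajectory lifetime analysis
#'
#' @param threshold_ns delta-lifetime threshold (ns, `> 0`). The shipped
#'   default 0.39 ns is the published control-derived value; analyses of
#'   synthetic data should recompute their own threshold from control tracks
#'   via [delta_stats()].
#' @param smoothing_window moving-median window in frames (odd, `>= 1`).
#' @param sampling_radius_px radius for per-frame lifetime sampling around
#'   the track position (px, `>= 0`).
#' @param min_track_length minimum frames for a classifiable track.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(threshold_ns = 0.39, smoothing_window = 3,
                              sampling_radius_px = 3, min_track_length = 10) {
  stopifnot(threshold_ns > 0, smoothing_window >= 1,
            smoothing_window %% 2 == 1, sampling_radius_px >= 0,
            min_track_length >= 2)
  structure(list(threshold_ns = threshold_ns,
                 smoothing_window = as.integer(smoothing_window),
                 sampling_radius_px = sampling_radius_px,
                 min_track_length = as.integer(min_track_length)),
            class = "classifier_config")
}

#' Sample the per-frame lifetime along a track
#'
#' For each frame of the track, takes the intensity-weighted mean of the
#' defined lifetime pixels within `sampling_radius_px` of the sub-pixel
#' position. Frames where no pixel in the neighborhood has a defined
#' lifetime yield `NA` (the track is retained).
#'
#' @param track data.frame with columns `frame, x, y` for one track
#'   (0-based positions).
#' @param lifetime_images list of `lifetime_image` frames indexed by frame
#'   number, or a `flim_movie`.
#' @param sampling_radius_px neighborhood radius (px).
#' @return Numeric vector of lifetimes (ns), one per track frame, `NA`
#'   where undefined.
#' @export
sample_track_lifetimes <- function(track, lifetime_images,
                                   sampling_radius_px = 3) {
  frames <- movie_frames(lifetime_images)
  if (all(track$frame > length(frames) | track$frame < 1))
    stop("track lies entirely outside the image stack")
  vapply(seq_len(nrow(track)), function(i) {
    f <- track$frame[i]
    if (f < 1 || f > length(frames)) return(NA_real_)
    img <- frames[[f]]
    nr <- nrow(img$intensity); nc <- ncol(img$intensity)
    r <- sampling_radius_px
    x <- track$x[i]; y <- track$y[i]
    cols <- max(0, floor(x - r)):min(nc - 1, ceiling(x + r))
    rows <- max(0, floor(y - r)):min(nr - 1, ceiling(y + r))
    if (!length(cols) || !length(rows)) return(NA_real_)
    grid <- expand.grid(row = rows, col = cols)
    d2 <- (grid$col - x)^2 + (grid$row - y)^2
    grid <- grid[d2 <= r^2, , drop = FALSE]
    if (!nrow(grid)) return(NA_real_)
    idx <- cbind(grid$row + 1, grid$col + 1)
    tau <- img$lifetime_ns[idx]
    w <- img$intensity[idx]
    ok <- !is.na(tau) & w > 0
    if (!any(ok)) return(NA_real_)
    weighted.mean(tau[ok], w[ok])
  }, numeric(1))
}

#' Moving-median smoothing of a lifetime series
#'
#' Centered moving median; endpoint positions with incomplete windows pass
#' through unchanged, and undefined (`NA`) entries are excluded from each
#' window's median (an all-`NA` window leaves the original entry).
#' Smoothing a series can only shrink its range: it suppresses single-frame
#' lifetime spikes that would otherwise inflate a track's lifetime range.
#'
#' @param series numeric vector (may contain `NA`).
#' @param window odd window length (`>= 1`).
#' @return Smoothed vector of the same length.
#' @examples
#' smooth_series(c(2, 2, 3.5, 2, 2))  # the single-frame spike is removed
#' @export
smooth_series <- function(series, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(series)
  h <- (window - 1) / 2
  if (h == 0 || n < window) return(series)
  out <- series
  for (i in (h + 1):(n - h)) {
    w <- series[(i - h):(i + h)]
    if (!all(is.na(w)) && !is.na(series[i])) out[i] <- median(w, na.rm = TRUE)
  }
  out
}

#' Control-derived frame-to-frame lifetime variation
#'
#' Pools the absolute frame-to-frame lifetime differences |delta tau| over
#' all consecutive defined pairs of the supplied control-track series
#' (unsmoothed, as recorded). Their mean is the delta-lifetime threshold used
#' to call a biologically significant lifetime range. This is the "fit" of
#' the trajectory classifier: `predict()` applies the threshold to new
#' tracks.
#'
#' @param series_list list of numeric per-frame lifetime series (one per
#'   control track; `NA` entries are skipped, and differences are only taken
#'   between adjacent frames that are both defined).
#' @return An object of class `delta_stats`: list with `deltas_ns`,
#'   `mean_delta_ns` (the threshold), `n`, `n_tracks`.
#' @examples
#' fit <- delta_stats(list(c(2.0, 2.2, 2.1)))
#' fit$mean_delta_ns  # 0.15
#' @export
delta_stats <- function(series_list) {
  if (is.numeric(series_list)) series_list <- list(series_list)
  deltas <- unlist(lapply(series_list, function(s) {
    if (length(s) < 2) return(numeric(0))
    d <- abs(diff(s))
    d[!is.na(d)]   # NA wherever either neighbor is undefined
  }))
  if (!length(deltas))
    stop("no valid consecutive lifetime pairs in the control tracks")
  structure(list(deltas_ns = as.numeric(deltas),
                 mean_delta_ns = mean(deltas),
                 n = length(deltas),
                 n_tracks = length(series_list)),
            class = "delta_stats")
}

#' @export
print.delta_stats <- function(x, ...) {
  cat(sprintf(
    "delta-lifetime statistics: %d deltas from %d control tracks\n",
    x$n, x$n_tracks))
  cat(sprintf("  threshold (mean |delta tau|): %.3f ns\n", x$mean_delta_ns))
  invisible(x)
}

#' @export
summary.delta_stats <- function(object, ...) {
  q <- quantile(object$deltas_ns, c(0.5, 0.9, 0.99))
  cat(sprintf("Frame-to-frame |delta lifetime| over %d pairs (%d tracks)\n",
              object$n, object$n_tracks))
  cat(sprintf("  mean (threshold): %.3f ns\n", object$mean_delta_ns))
  cat(sprintf("  median %.3f, p90 %.3f, p99 %.3f ns\n", q[1], q[2], q[3]))
  invisible(object)
}

#' @export
plot.delta_stats <- function(x, ...) {
  hist(x$deltas_ns, breaks = 40, col = "grey80", border = "white",
       main = "Control frame-to-frame lifetime variation",
       xlab = expression(paste("|", Delta, " lifetime| (ns)")), ...)
  abline(v = x$mean_delta_ns, col = "red", lwd = 2)
  legend("topright", sprintf("threshold = %.3f ns", x$mean_delta_ns),
         lty = 1, col = "red", bty = "n")
  invisible(x)
}

#' Classify a single lifetime series
#'
#' Smooths the series with a centered moving median, computes its lifetime
#' range (max - min of the smoothed, defined entries) and labels the track
#' `above_threshold` iff the range strictly exceeds the threshold,
#' `below_threshold` otherwise. Tracks shorter than `min_track_length` or
#' with fewer than two defined smoothed entries are `unclassified`.
#'
#' @param series per-frame lifetime series (ns; `NA` = undefined).
#' @param config a [classifier_config()].
#' @return list with `label`, `lifetime_range_ns`, `smoothed_ns`.
#' @export
classify_series <- function(series, config = classifier_config()) {
  sm <- smooth_series(series, config$smoothing_window)
  def <- sm[!is.na(sm)]
  if (length(series) < config$min_track_length || length(def) < 2)
    return(list(label = "unclassified", lifetime_range_ns = NA_real_,
                smoothed_ns = sm))
  rng <- max(def) - min(def)
  list(label = if (rng > config$threshold_ns) "above_threshold"
       else "below_threshold",
       lifetime_range_ns = rng, smoothed_ns = sm)
}

#' Classify every track of a track table
#'
#' Samples per-frame lifetimes along each track, applies moving-median
#' smoothing and labels each track by whether its lifetime range exceeds the
#' threshold.
#'
#' @param tracks a `track_table` (see [link_tracks()]).
#' @param lifetime_images list of `lifetime_image` frames or a `flim_movie`.
#' @param config a [classifier_config()]; its `threshold_ns` is overridden
#'   by `threshold` when supplied.
#' @param threshold optional threshold (ns) or a [delta_stats()] fit.
#' @return A `classified_tracks` data.frame: one row per track with
#'   `track_id, n_frames, lifetime_range_ns, label, median_x, median_y`,
#'   and the per-frame series in the `series` attribute.
#' @export
classify_tracks <- function(tracks, lifetime_images,
                            config = classifier_config(), threshold = NULL) {
  if (inherits(threshold, "delta_stats")) threshold <- threshold$mean_delta_ns
  if (!is.null(threshold)) config$threshold_ns <- threshold
  ids <- unique(tracks$track_id)
  if (!length(ids)) {
    out <- data.frame(track_id = integer(), n_frames = integer(),
                      lifetime_range_ns = numeric(), label = character(),
                      median_x = numeric(), median_y = numeric())
    attr(out, "series") <- list()
    attr(out, "threshold_ns") <- config$threshold_ns
    class(out) <- c("classified_tracks", "data.frame")
    return(out)
  }
  series <- list()
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    s <- sample_track_lifetimes(tr, lifetime_images,
                                config$sampling_radius_px)
    cl <- classify_series(s, config)
    series[[as.character(id)]] <<- list(raw = s, smoothed = cl$smoothed_ns)
    data.frame(track_id = id, n_frames = nrow(tr),
               lifetime_range_ns = cl$lifetime_range_ns, label = cl$label,
               median_x = median(tr$x), median_y = median(tr$y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "series") <- series
  attr(out, "threshold_ns") <- config$threshold_ns
  class(out) <- c("classified_tracks", "data.frame")
  out
}

#' @export
print.classified_tracks <- function(x, ...) {
  cat(sprintf("classified tracks (threshold %.3f ns):\n",
              attr(x, "threshold_ns")))
  print(table(x$label))
  invisible(x)
}

#' @describeIn delta_stats classify a track table against the fitted
#'   threshold.
#' @param object a `delta_stats` fit.
#' @param tracks,lifetime_images,config passed to [classify_tracks()].
#' @param ... unused.
#' @export
predict.delta_stats <- function(object, tracks, lifetime_images,
                                config = classifier_config(), ...) {
  classify_tracks(tracks, lifetime_images, config,
                  threshold = object$mean_delta_ns)
}

#' Zone occupancy of classified tracks relative to compartment boundaries
#'
#' Assigns each classified track the zone of its median position (within
#' `band_px` of the cell or nuclear boundary = `"boundary"`, else
#' `"interior"`) and reports per-class counts, fractions and the odds ratio
#' of above-threshold tracks lying in the boundary band. Complete separation
#' (a zero cell) is flagged and the odds ratio reported as `Inf`/0 without a
#' continuity correction.
#'
#' @param classified a [classify_tracks()] result.
#' @param compartment_map a [make_compartment_map()].
#' @param band_px boundary band half-width (px, `> 0`).
#' @param n_perm optional number of label permutations for a null odds-ratio
#'   distribution (0 = skip).
#' @return A `boundary_report` list: `table` (class x zone counts),
#'   `odds_ratio`, `complete_separation`, `zone` per track, and
#'   `perm_odds_ratios` when requested.
#' @export
boundary_report <- function(classified, compartment_map, band_px = 2,
                            n_perm = 0) {
  if (band_px <= 0) stop("band_px must be > 0")
  band <- boundary_band(compartment_map, band_px)
  nr <- nrow(band); nc <- ncol(band)
  row <- pmin(pmax(round(classified$median_y) + 1, 1), nr)
  col <- pmin(pmax(round(classified$median_x) + 1, 1), nc)
  zone <- ifelse(band[cbind(row, col)], "boundary", "interior")
  lab <- classified$label
  use <- lab %in% c("above_threshold", "below_threshold")
  tab <- table(factor(lab[use], c("above_threshold", "below_threshold")),
               factor(zone[use], c("boundary", "interior")))
  orat <- odds_ratio_2x2(tab)
  perm <- NULL
  if (n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(i) {
      odds_ratio_2x2(table(
        factor(sample(lab[use]), c("above_threshold", "below_threshold")),
        factor(zone[use], c("boundary", "interior"))))
    }, numeric(1))
  }
  structure(list(table = tab, odds_ratio = orat,
                 complete_separation = any(tab == 0), zone = zone,
                 band_px = band_px, perm_odds_ratios = perm),
            class = "boundary_report")
}

odds_ratio_2x2 <- function(tab) {
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' @export
print.boundary_report <- function(x, ...) {
  cat("boundary zone occupancy (band", x$band_px, "px):\n")
  print(x$table)
  if (x$complete_separation) {
    cat("  complete separation between classes and zones\n")
  }
  cat(sprintf("  odds ratio (above-threshold in boundary band): %.3g\n",
              x$odds_ratio))
  if (!is.null(x$perm_odds_ratios))
    cat(sprintf("  permutation null: median OR %.3g (%d shuffles)\n",
                median(x$perm_odds_ratios, na.rm = TRUE),
                length(x$perm_odds_ratios)))
  invisible(x)
}

#' Overlay classified tracks on an intensity frame
#'
#' @param x a `classified_tracks` object.
#' @param tracks the `track_table` the classification was computed from.
#' @param image a `lifetime_image` whose intensity channel is the backdrop.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.classified_tracks <- function(x, tracks, image, ...) {
  z <- image$intensity
  graphics::image(0:(ncol(z) - 1), 0:(nrow(z) - 1), t(z),
                  col = grDevices::gray.colors(64, 0, 1), xlab = "x (px)",
                  ylab = "y (px)", useRaster = TRUE, ...)
  cols <- c(above_threshold = "red", below_threshold = "dodgerblue",
            unclassified = "grey60")
  for (i in seq_len(nrow(x))) {
    tr <- tracks[tracks$track_id == x$track_id[i], ]
    lines(tr$x, tr$y, col = cols[[x$label[i]]], lwd = 1.5)
  }
  legend("topright", names(cols), col = cols, lwd = 2, bg = "white",
         cex = 0.7)
  invisible(x)
}
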