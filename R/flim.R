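#' Mean micro-time of a truncated exponential decay
#'
#' For a monoexponential decay of lifetime `tau` observed modulo a pulse
#' period `T` (equivalently, truncated to one period), the expected photon
#' arrival time is `tau - T / (exp(T / tau) - 1)`.
#'
#' @param tau_ns lifetime (ns).
#' @param period_ns pulse period `T` (ns).
#' @return Expected micro-time (ns).
#' @export
truncated_exp_mean <- function(tau_ns, period_ns) {
  tau_ns - period_ns / expm1(period_ns / tau_ns)
}

#' Invert the truncated-exponential mean
#'
#' Solves `truncated_exp_mean(tau, T) = m` for `tau` by bisection. The mean
#' of any decay truncated to one period lies in `(0, T/2)`; values at or
#' above `T/2` (flatter than uniform) are not invertible and return `NA`.
#'
#' @param mean_ns observed photon-weighted mean micro-time (ns).
#' @param period_ns pulse period (ns).
#' @param tol bisection tolerance (ns).
#' @return Corrected lifetime (ns), `0` for `mean_ns <= 0`, `NA` if not
#'   invertible.
#' @export
invert_truncated_mean <- function(mean_ns, period_ns, tol = 1e-9) {
  if (is.na(mean_ns)) return(NA_real_)
  if (mean_ns <= 0) return(0)
  if (mean_ns >= period_ns / 2) return(NA_real_)
  f <- function(tau) truncated_exp_mean(tau, period_ns) - mean_ns
  uniroot(f, lower = 1e-6, upper = 1e6, tol = tol)$root
}

#' Fast (mean arrival time) lifetime estimator
#'
#' Estimates the lifetime of a pixel decay as the photon-weighted mean
#' micro-time (evaluated at bin centers) minus the IRF centroid, optionally
#' corrected for truncation of the exponential to the integration gate by
#' inverting `E[t | T] = tau - T / (exp(T / tau) - 1)`.
#'
#' The mean is taken over a gate `[0, T - tail_trim_ns)` rather than the
#' full period: IRF jitter wraps a small fraction of photons to the very end
#' of the micro-time window, and each such photon displaces the plain mean
#' by almost a full period, adding both an offset and substantial count
#' noise. Trimming the last nanosecond (several IRF sigma) excludes them,
#' and the truncation correction with the effective gate length remains
#' exact for an exponential decay.
#'
#' @param decay a `pixel_decay` from [simulate_pixel_photons()], or a bare
#'   numeric vector of micro-time bin counts.
#' @param config an [acq_config()] object.
#' @param irf_centroid_ns centroid of the instrument response (ns),
#'   subtracted from the mean arrival time.
#' @param correct apply the truncation correction (default `TRUE`).
#' @param min_photons below this count inside the gate the lifetime is
#'   undefined and `NA` is returned (not an error).
#' @param tail_trim_ns length of micro-time window excluded at the end of
#'   the period (ns; whole bins). `0` integrates the full period.
#' @return Estimated lifetime (ns) or `NA` when undefined. If the truncation
#'   correction is not invertible (mean at or beyond half the gate) the
#'   uncorrected mean-based estimate is returned.
#' @examples
#' cfg <- acq_config(dead_time_s = 0)
#' d <- simulate_pixel_photons(0.05, 4, cfg, n_pulses = 2e5, seed = 1)
#' fast_lifetime(d, cfg)
#' @export
fast_lifetime <- function(decay, config, irf_centroid_ns = 0, correct = TRUE,
                          min_photons = 20, tail_trim_ns = 1) {
  counts <- if (inherits(decay, "pixel_decay")) decay$counts else decay
  nb <- length(counts)
  period <- pulse_period_ns(config)
  bw <- period / nb
  n_used <- max(2L, nb - as.integer(ceiling(tail_trim_ns / bw)))
  counts <- counts[seq_len(n_used)]
  gate <- n_used * bw
  n <- sum(counts)
  if (n < min_photons) return(NA_real_)
  centers <- (seq_len(n_used) - 0.5) * bw
  m <- sum(counts * centers) / n - irf_centroid_ns
  if (!correct) return(max(m, 0))
  tau <- invert_truncated_mean(m, gate)
  if (is.na(tau)) max(m, 0) else tau
}

#' Collapse a frame of pixel decays into a two-channel lifetime image
#'
#' Channel 1 is the per-pixel photon count; channel 2 the per-pixel fast
#' lifetime, undefined (`NA`) wherever the count is below `min_photons`.
#'
#' @param decay_frame integer array `rows x cols x n_microtime_bins` of
#'   per-pixel micro-time histograms (as produced by the simulator), or a
#'   list of `pixel_decay` objects covering the frame.
#' @inheritParams fast_lifetime
#' @param frame_index,frame_time_s bookkeeping stored on the result.
#' @return A `lifetime_image`: list with matrices `intensity` and
#'   `lifetime_ns` (`NA` = undefined), plus `frame_index`, `frame_time_s`.
#' @export
build_lifetime_image <- function(decay_frame, config, irf_centroid_ns = 0,
                                 correct = TRUE, min_photons = 20,
                                 tail_trim_ns = 1, frame_index = 1L,
                                 frame_time_s = 0) {
  if (is.list(decay_frame)) decay_frame <- decays_to_array(decay_frame, config)
  d <- dim(decay_frame)
  if (is.null(d) || length(d) != 3 || prod(d) == 0)
    stop("decay_frame must be a non-empty rows x cols x bins array")
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  period <- pulse_period_ns(config)
  bw <- period / nb
  n_used <- max(2L, nb - as.integer(ceiling(tail_trim_ns / bw)))
  gate <- n_used * bw
  centers <- (seq_len(n_used) - 0.5) * bw
  flat <- matrix(decay_frame, nr * nc, nb)
  # channel 1 counts the full histogram; the lifetime gate excludes the
  # wrap-contaminated tail bins
  intensity <- matrix(rowSums(flat), nr, nc)
  gated <- flat[, seq_len(n_used), drop = FALSE]
  gn <- matrix(rowSums(gated), nr, nc)
  msum <- matrix(as.vector(gated %*% centers), nr, nc)
  lifetime <- matrix(NA_real_, nr, nc)
  ok <- gn >= pmax(min_photons, 1)
  if (any(ok)) {
    m <- msum[ok] / gn[ok] - irf_centroid_ns
    lifetime[ok] <- vapply(m, function(mi) {
      if (!correct) return(max(mi, 0))
      tau <- invert_truncated_mean(mi, gate)
      if (is.na(tau)) max(mi, 0) else tau
    }, numeric(1))
  }
  structure(list(intensity = intensity, lifetime_ns = lifetime,
                 frame_index = as.integer(frame_index),
                 frame_time_s = frame_time_s),
            class = "lifetime_image")
}

decays_to_array <- function(decays, config) {
  stopifnot(length(decays) > 0)
  px <- t(vapply(decays, function(d) d$pixel, numeric(2)))
  nr <- max(px[, 1]); nc <- max(px[, 2])
  arr <- array(0L, c(nr, nc, config$n_microtime_bins))
  for (d in decays) arr[d$pixel[1], d$pixel[2], ] <- d$counts
  arr
}

#' @export
print.lifetime_image <- function(x, ...) {
  cat(sprintf("lifetime image %d x %d px (frame %d, t = %.3g s)\n",
              nrow(x$intensity), ncol(x$intensity), x$frame_index,
              x$frame_time_s))
  cat(sprintf("  photons: %g total; lifetime defined on %d px (%.1f%%)\n",
              sum(x$intensity), sum(!is.na(x$lifetime_ns)),
              100 * mean(!is.na(x$lifetime_ns))))
  invisible(x)
}

#' @export
plot.lifetime_image <- function(x, which = c("lifetime", "intensity"), ...) {
  which <- match.arg(which)
  z <- if (which == "lifetime") x$lifetime_ns else x$intensity
  image(t(z)[, nrow(z):1], col = hcl.colors(64, "viridis"), axes = FALSE,
        main = paste(which, "- frame", x$frame_index), ...)
  invisible(x)
}

#' Fold change in total photon counts between two movies
#'
#' Ratio of the summed intensity channels of two equally shaped movies, e.g.
#' a rapid (short-dead-time) acquisition versus a pileup-attenuated classic
#' one over the same duration.
#'
#' @param movie_a,movie_b lists of `lifetime_image` frames (or `flim_movie`
#'   objects) with equal frame counts and shapes.
#' @return `sum(intensity_a) / sum(intensity_b)`.
#' @export
total_photon_ratio <- function(movie_a, movie_b) {
  fa <- movie_frames(movie_a); fb <- movie_frames(movie_b)
  if (length(fa) != length(fb)) stop("movies differ in frame count")
  if (!identical(dim(fa[[1]]$intensity), dim(fb[[1]]$intensity)))
    stop("movies differ in frame shape")
  tb <- sum(vapply(fb, function(f) sum(f$intensity), numeric(1)))
  if (tb == 0) stop("denominator movie has zero total photons")
  ta <- sum(vapply(fa, function(f) sum(f$intensity), numeric(1)))
  ta / tb
}

movie_frames <- function(movie) {
  if (inherits(movie, "flim_movie")) movie$images else movie
}
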