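#' Acquisition configuration
#'
#' Describes the pulsed-excitation TCSPC acquisition: laser repetition rate,
#' per-pixel dwell time, detector dead time, micro-time binning, frame
#' geometry and timing, and the Gaussian instrument-response (IRF) jitter.
#' The defaults follow a typical rapid-FLIM setup: 40 MHz excitation (25 ns
#' pulse period), 10 microsecond pixel dwell, 2 ns detector dead time and
#' 0.1 ns micro-time bins. A classic TCSPC detector is obtained by setting
#' `dead_time_s = 50e-9`.
#'
#' @param rep_rate_hz excitation repetition rate (Hz).
#' @param dwell_time_s per-pixel dwell time (s).
#' @param dead_time_s detector dead time (s); `>= 0`.
#' @param n_microtime_bins number of micro-time histogram bins (`>= 2`).
#' @param frame_shape integer `c(rows, cols)` of the pixel grid.
#' @param frame_interval_s time between successive frames (s).
#' @param irf_sigma_s Gaussian IRF jitter standard deviation (s).
#'
#' @return An object of class `flim_acquisition`: a list with the above
#'   fields plus derived `pulse_period_s` (`1 / rep_rate_hz`) and
#'   `angular_freq` (`2 * pi * rep_rate_hz`, rad/s).
#' @examples
#' cfg <- acq_config()
#' pulse_period_ns(cfg)   # 25 ns at 40 MHz
#' @export
acq_config <- function(rep_rate_hz = 40e6,
                       dwell_time_s = 10e-6,
                       dead_time_s = 2e-9,
                       n_microtime_bins = 250L,
                       frame_shape = c(512L, 512L),
                       frame_interval_s = 2.62,
                       irf_sigma_s = 0.2e-9) {
  stopifnot(rep_rate_hz > 0, dwell_time_s > 0, dead_time_s >= 0,
            n_microtime_bins >= 2, length(frame_shape) == 2,
            all(frame_shape >= 1), frame_interval_s > 0, irf_sigma_s >= 0)
  structure(list(
    rep_rate_hz = rep_rate_hz,
    pulse_period_s = 1 / rep_rate_hz,
    dwell_time_s = dwell_time_s,
    dead_time_s = dead_time_s,
    n_microtime_bins = as.integer(n_microtime_bins),
    frame_shape = as.integer(frame_shape),
    frame_interval_s = frame_interval_s,
    irf_sigma_s = irf_sigma_s,
    angular_freq = 2 * pi * rep_rate_hz
  ), class = "flim_acquisition")
}

#' @export
print.flim_acquisition <- function(x, ...) {
  cat("TCSPC acquisition configuration\n")
  cat(sprintf("  repetition rate : %.3g MHz (period %.3g ns)\n",
              x$rep_rate_hz / 1e6, pulse_period_ns(x)))
  cat(sprintf("  dwell time      : %.3g us (%d pulses/pixel)\n",
              x$dwell_time_s * 1e6, pulses_per_pixel(x)))
  cat(sprintf("  dead time       : %.3g ns\n", x$dead_time_s * 1e9))
  cat(sprintf("  micro-time bins : %d (%.3g ns each)\n",
              x$n_microtime_bins, pulse_period_ns(x) / x$n_microtime_bins))
  cat(sprintf("  frame           : %d x %d px, every %.3g s\n",
              x$frame_shape[1], x$frame_shape[2], x$frame_interval_s))
  cat(sprintf("  IRF jitter sd   : %.3g ns\n", x$irf_sigma_s * 1e9))
  invisible(x)
}

#' Pulse period in nanoseconds
#' @param config a [acq_config()] object.
#' @return Pulse period `1 / rep_rate_hz` in ns.
#' @export
pulse_period_ns <- function(config) config$pulse_period_s * 1e9

#' Number of excitation pulses during one pixel dwell
#' @inheritParams pulse_period_ns
#' @return Integer pulse count `dwell_time_s * rep_rate_hz`.
#' @export
pulses_per_pixel <- function(config) {
  as.integer(round(config$dwell_time_s * config$rep_rate_hz))
}

#' Pileup-safe count-rate ceiling for a classic TCSPC detector
#'
#' The operating rule for long-dead-time TCSPC is to keep the detected count
#' rate below a fixed fraction (conventionally 10%) of the laser repetition
#' rate so that photon pileup does not skew the decay.
#'
#' @inheritParams pulse_period_ns
#' @param fraction fraction of the repetition rate considered safe
#'   (default 0.1, the 10% rule).
#' @return Maximum safe detected rate in counts per second.
#' @examples
#' pileup_safe_rate(acq_config()) / 1e6   # 4 Mcps at 40 MHz
#' @export
pileup_safe_rate <- function(config, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  fraction * config$rep_rate_hz
}

#' Total wall-clock time of a multi-frame acquisition
#' @param n_frames number of frames.
#' @param frame_interval_s time per frame (s).
#' @return Acquisition time in seconds.
#' @examples
#' acquisition_time_s(120, 2.62) / 60   # minutes for a 120-frame movie
#' @export
acquisition_time_s <- function(n_frames, frame_interval_s) {
  stopifnot(n_frames >= 1, frame_interval_s > 0)
  n_frames * frame_interval_s
}
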