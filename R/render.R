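#' Render a FLIM movie from ground-truth trajectories
#'
#' Composes per-frame, per-pixel emission rates from Gaussian point-spread
#' contributions of every particle plus a uniform background, and simulates
#' TCSPC photon detection pixel by pixel with the configured dead time. Each
#' pixel's decay uses the intensity-weighted mean lifetime of its
#' contributors (particles within reach of the PSF and the background); each
#' frame's micro-time histograms are collapsed to a two-channel
#' (intensity, fast lifetime) image and optionally kept and/or reduced to a
#' phasor cloud on the fly, so photon-level storage never exceeds one frame.
#'
#' @param ground_truth a [simulate_tracks()] object with lifetimes assigned
#'   via [assign_lifetimes()] (an empty/background-only movie is rendered if
#'   it has no particles in frame). May be `NULL` for pure background.
#' @param config an [acq_config()] object; `config$frame_shape` must match
#'   the ground truth.
#' @param psf_sigma_px Gaussian PSF standard deviation (px, `> 0`).
#' @param photons_per_particle_frame expected emitted photons per particle
#'   per frame (before dead-time losses).
#' @param background_rate expected emitted background photons per pixel per
#'   frame.
#' @param background_tau_ns lifetime of the background (ns).
#' @param collapse keep only the two-channel images (default); with
#'   `collapse = FALSE` the per-frame decay arrays are retained as well
#'   (memory: `rows * cols * n_microtime_bins` integers per frame).
#' @param phasor also accumulate a per-pixel phasor cloud (computed from each
#'   frame's histograms before they are discarded).
#' @param min_photons per-pixel photon floor for a defined lifetime or
#'   phasor point.
#' @param irf_centroid_ns IRF centroid passed to the lifetime estimator; the
#'   simulator's jitter is zero-mean so the true centroid is 0.
#' @param seed optional integer seed.
#' @return A `flim_movie`: list with `images` (list of `lifetime_image`),
#'   `decays` (list of decay arrays or `NULL`), `phasor` (data.frame or
#'   `NULL`), `config`, and the generator arguments.
#' @export
render_movie <- function(ground_truth, config, psf_sigma_px = 1,
                         photons_per_particle_frame = 1000,
                         background_rate = 0.5, background_tau_ns = 2.0,
                         collapse = TRUE, phasor = FALSE, min_photons = 20,
                         irf_centroid_ns = 0, seed = NULL) {
  stopifnot(psf_sigma_px > 0, background_rate >= 0, background_tau_ns > 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  n_frames <- if (is.null(ground_truth)) 1L else ground_truth$n_frames
  tr <- if (is.null(ground_truth)) NULL else ground_truth$tracks
  if (!is.null(tr) && is.null(tr$tau_ns))
    stop("ground truth has no lifetimes; call assign_lifetimes() first")
  n_pulses <- pulses_per_pixel(config)
  images <- vector("list", n_frames)
  decays <- if (collapse) NULL else vector("list", n_frames)
  clouds <- if (phasor) vector("list", n_frames) else NULL

  for (f in seq_len(n_frames)) {
    lam <- matrix(background_rate, nr, nc)          # expected photons/px/frame
    tausum <- matrix(background_rate * background_tau_ns, nr, nc)
    if (!is.null(tr)) {
      pf <- tr[tr$frame == f, ]
      for (i in seq_len(nrow(pf))) {
        k <- psf_kernel(pf$x[i], pf$y[i], psf_sigma_px, nr, nc)
        if (is.null(k)) next
        add <- photons_per_particle_frame * k$w
        lam[k$idx] <- lam[k$idx] + add
        tausum[k$idx] <- tausum[k$idx] + add * pf$tau_ns[i]
      }
    }
    tau <- matrix(background_tau_ns, nr, nc)
    pos <- lam > 0
    tau[pos] <- tausum[pos] / lam[pos]
    p <- pmin(lam / n_pulses, 1)
    arr <- sim_frame(p, tau, n_pulses, pulse_period_ns(config),
                     config$dead_time_s * 1e9, config$irf_sigma_s * 1e9,
                     config$n_microtime_bins)
    images[[f]] <- build_lifetime_image(
      arr, config, irf_centroid_ns = irf_centroid_ns,
      min_photons = min_photons, frame_index = f,
      frame_time_s = (f - 1) * config$frame_interval_s)
    if (phasor) clouds[[f]] <- phasor_cloud_frame(arr, config, min_photons, f)
    if (!collapse) decays[[f]] <- arr
  }
  structure(list(images = images, decays = decays,
                 phasor = if (phasor) do.call(rbind, clouds) else NULL,
                 config = config, psf_sigma_px = psf_sigma_px,
                 photons_per_particle_frame = photons_per_particle_frame,
                 background_rate = background_rate,
                 background_tau_ns = background_tau_ns, seed = seed),
            class = "flim_movie")
}

# normalized Gaussian PSF weights on the pixel grid within 4 sigma of (x, y);
# NULL when the particle is entirely off-frame
psf_kernel <- function(x, y, sigma, nr, nc) {
  r <- ceiling(4 * sigma)
  cols <- max(0, floor(x - r)):min(nc - 1, ceiling(x + r))
  rows <- max(0, floor(y - r)):min(nr - 1, ceiling(y + r))
  if (!length(cols) || !length(rows) || x < -r || x > nc - 1 + r ||
      y < -r || y > nr - 1 + r) return(NULL)
  w <- outer(rows, cols, function(rr, cc)
    exp(-((cc - x)^2 + (rr - y)^2) / (2 * sigma^2)))
  s <- sum(w)
  if (s <= 0) return(NULL)
  idx <- as.matrix(expand.grid(row = rows + 1, col = cols + 1))
  list(idx = idx, w = as.vector(w) / s)
}

#' @export
print.flim_movie <- function(x, ...) {
  n <- length(x$images)
  tot <- sum(vapply(x$images, function(f) sum(f$intensity), numeric(1)))
  cat(sprintf("FLIM movie: %d frames of %d x %d px, %g photons total\n",
              n, nrow(x$images[[1]]$intensity), ncol(x$images[[1]]$intensity),
              tot))
  if (!is.null(x$phasor))
    cat(sprintf("  phasor cloud: %d points\n", nrow(x$phasor)))
  invisible(x)
}
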