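#' First-harmonic phasor transform of a pixel decay
#'
#' Maps a micro-time histogram to phasor coordinates
#' `G = sum I(t) cos(wt) / sum I(t)` and `S = sum I(t) sin(wt) / sum I(t)`,
#' evaluated at bin centers, with `w = 2 * pi * f` the angular repetition
#' frequency. Monoexponential decays fall on the universal semicircle
#' `(G - 1/2)^2 + S^2 = 1/4`, at `G = 1 / (1 + (w tau)^2)`,
#' `S = w tau G`; because the micro-time is recorded modulo the pulse period
#' and `w` is the exact first harmonic, this holds exactly for the wrapped
#' decay as well.
#'
#' @inheritParams fast_lifetime
#' @return Named numeric `c(G, S)`.
#' @examples
#' cfg <- acq_config()
#' phasor_reference_point(2.5, cfg)  # closed form, on the semicircle
#' @export
phasor_transform <- function(decay, config) {
  counts <- if (inherits(decay, "pixel_decay")) decay$counts else decay
  n <- sum(counts)
  if (n <= 0) stop("phasor transform needs a decay with positive total counts")
  nb <- length(counts)
  period <- pulse_period_ns(config)
  centers <- (seq_len(nb) - 0.5) * period / nb
  w <- config$angular_freq * 1e-9  # rad/ns
  c(G = sum(counts * cos(w * centers)) / n,
    S = sum(counts * sin(w * centers)) / n)
}

#' Closed-form phasor coordinates of a monoexponential lifetime
#' @param tau_ns lifetime (ns).
#' @param config an [acq_config()] object.
#' @return Named numeric `c(G, S)` on the universal semicircle.
#' @export
phasor_reference_point <- function(tau_ns, config) {
  wt <- config$angular_freq * 1e-9 * tau_ns
  g <- 1 / (1 + wt^2)
  c(G = g, S = wt * g)
}

#' Per-pixel phasor cloud of a movie
#'
#' One phasor point per pixel per frame for every pixel whose total photon
#' count reaches `min_photons`.
#'
#' @param decay_frames a list of `rows x cols x bins` decay arrays (one per
#'   frame), a single such array, or a `flim_movie` rendered with
#'   `collapse = FALSE`.
#' @param config an [acq_config()] object.
#' @param min_photons minimum photons per pixel for a point.
#' @return A data.frame (`frame, row, col, G, S, counts`); zero rows (with a
#'   warning) if no pixel qualifies.
#' @export
phasor_cloud <- function(decay_frames, config, min_photons = 20) {
  if (inherits(decay_frames, "flim_movie")) {
    if (is.null(decay_frames$decays))
      stop("movie was rendered without decay histograms (collapse = TRUE)")
    decay_frames <- decay_frames$decays
  }
  if (!is.list(decay_frames)) decay_frames <- list(decay_frames)
  out <- vector("list", length(decay_frames))
  for (f in seq_along(decay_frames)) {
    out[[f]] <- phasor_cloud_frame(decay_frames[[f]], config, min_photons, f)
  }
  cloud <- do.call(rbind, out)
  if (nrow(cloud) == 0) warning("no pixel reached min_photons; empty cloud")
  cloud
}

phasor_cloud_frame <- function(arr, config, min_photons, frame) {
  d <- dim(arr)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  period <- pulse_period_ns(config)
  centers <- (seq_len(nb) - 0.5) * period / nb
  w <- config$angular_freq * 1e-9
  flat <- matrix(arr, nr * nc, nb)
  n <- rowSums(flat)
  keep <- which(n >= pmax(min_photons, 1))
  if (!length(keep))
    return(data.frame(frame = integer(), row = integer(), col = integer(),
                      G = numeric(), S = numeric(), counts = numeric()))
  G <- as.vector(flat[keep, , drop = FALSE] %*% cos(w * centers)) / n[keep]
  S <- as.vector(flat[keep, , drop = FALSE] %*% sin(w * centers)) / n[keep]
  data.frame(frame = frame,
             row = (keep - 1) %% nr + 1,
             col = (keep - 1) %/% nr + 1,
             G = G, S = S, counts = n[keep])
}

#' Define a circular phasor gate
#' @param name gate label, e.g. `"short"`, `"intermediate"`, `"long"`.
#' @param center numeric `c(G, S)` center of the gate.
#' @param radius gate radius in phasor units (`> 0`).
#' @return A `phasor_gate` object.
#' @export
phasor_gate <- function(name, center, radius) {
  stopifnot(radius > 0, length(center) == 2)
  structure(list(name = name, center = as.numeric(center), radius = radius),
            class = "phasor_gate")
}

#' Per-gate pixel fractions over time
#'
#' Assigns every phasor point to at most one of a set of pairwise-disjoint
#' circular gates and reports the fraction of points in each gate (plus the
#' unassigned remainder) per frame. Fractions sum to 1 within each frame.
#'
#' @param cloud a [phasor_cloud()] data.frame.
#' @param gates list of [phasor_gate()] objects; must be pairwise disjoint.
#' @param frame_range optional integer vector of frames to include.
#' @return A data.frame (`frame, gate, n, fraction`), with an `"unassigned"`
#'   row per frame.
#' @export
gate_fractions <- function(cloud, gates, frame_range = NULL) {
  stopifnot(length(gates) >= 1)
  for (i in seq_along(gates)) {
    for (j in seq_len(i - 1)) {
      d <- sqrt(sum((gates[[i]]$center - gates[[j]]$center)^2))
      if (d < gates[[i]]$radius + gates[[j]]$radius)
        stop("gates '", gates[[j]]$name, "' and '", gates[[i]]$name,
             "' overlap")
    }
  }
  if (!is.null(frame_range)) cloud <- cloud[cloud$frame %in% frame_range, ]
  frames <- sort(unique(cloud$frame))
  out <- list()
  for (f in frames) {
    pts <- cloud[cloud$frame == f, ]
    assigned <- rep(NA_character_, nrow(pts))
    for (g in gates) {
      inside <- (pts$G - g$center[1])^2 + (pts$S - g$center[2])^2 <=
        g$radius^2
      assigned[inside & is.na(assigned)] <- g$name
    }
    tab <- c(vapply(gates, function(g) sum(assigned == g$name, na.rm = TRUE),
                    numeric(1)),
             sum(is.na(assigned)))
    names(tab) <- c(vapply(gates, `[[`, character(1), "name"), "unassigned")
    out[[length(out) + 1]] <- data.frame(
      frame = f, gate = names(tab), n = as.numeric(tab),
      fraction = as.numeric(tab) / nrow(pts))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
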