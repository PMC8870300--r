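#' Simulate ground-truth particle trajectories
#'
#' Brownian motion of sub-resolution particles, either free (agarose-like
#' controls) or confined by reflecting elliptical walls (caged intracellular
#' diffusion). Free-motion step displacements are Gaussian with variance
#' `2 * D * dt` per axis. An optional per-particle drift models directed
#' transport and is used to script boundary-crossing particles. Positions are
#' 0-based pixel coordinates (x = column, y = row).
#'
#' @param n_particles number of particles.
#' @param motion_model `"free"` or `"confined"`.
#' @param D_px2_s diffusion coefficient (px^2/s, `>= 0`).
#' @param n_frames number of frames.
#' @param frame_interval_s time between frames (s).
#' @param frame_shape integer `c(rows, cols)`.
#' @param region for confined motion, either a [make_compartment_map()]
#'   (the cell ellipse confines) or a list with `center` `c(x, y)` and
#'   `radii` `c(rx, ry)`.
#' @param start optional `n_particles x 2` matrix of initial `(x, y)`;
#'   defaults to uniform positions in the frame (free) or in the region
#'   (confined).
#' @param drift_px_frame optional per-frame drift: numeric `c(dx, dy)`
#'   applied to all particles or an `n_particles x 2` matrix.
#' @param seed optional integer seed.
#'
#' @return A `ground_truth` object: list with `tracks` (data.frame
#'   `particle, frame, x, y, exited`), `n_frames`, `frame_shape`,
#'   `frame_interval_s`, `motion_model`, `D_px2_s`, `seed`. Frames are
#'   1-based. `exited` flags positions outside the frame bounds (free model
#'   only; confined particles never leave).
#' @examples
#' gt <- simulate_tracks(3, "free", D_px2_s = 2, n_frames = 20,
#'                       frame_interval_s = 1, frame_shape = c(64, 64),
#'                       seed = 1)
#' head(gt$tracks)
#' @export
simulate_tracks <- function(n_particles, motion_model = c("free", "confined"),
                            D_px2_s, n_frames, frame_interval_s, frame_shape,
                            region = NULL, start = NULL,
                            drift_px_frame = NULL, seed = NULL) {
  motion_model <- match.arg(motion_model)
  if (D_px2_s < 0) stop("diffusion coefficient D must be >= 0")
  stopifnot(n_particles >= 1, n_frames >= 1, frame_interval_s > 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (motion_model == "confined") {
    if (is.null(region)) stop("confined motion requires a region")
    if (inherits(region, "compartment_map")) {
      region <- list(center = region$cell_center, radii = region$cell_radii)
    }
  }
  if (is.null(start)) {
    if (motion_model == "free") {
      start <- cbind(runif(n_particles, 0, nc - 1),
                     runif(n_particles, 0, nr - 1))
    } else {
      # uniform in the confining ellipse by rejection
      start <- matrix(NA_real_, n_particles, 2)
      for (i in seq_len(n_particles)) {
        repeat {
          p <- c(runif(1, -1, 1), runif(1, -1, 1))
          if (sum(p^2) <= 1) break
        }
        start[i, ] <- region$center + p * region$radii
      }
    }
  }
  start <- matrix(start, ncol = 2)
  if (is.null(drift_px_frame)) drift_px_frame <- c(0, 0)
  drift <- matrix(drift_px_frame, ncol = 2)
  if (nrow(drift) == 1) drift <- drift[rep(1, n_particles), , drop = FALSE]

  sigma <- sqrt(2 * D_px2_s * frame_interval_s)
  pos <- start
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      step <- matrix(rnorm(2 * n_particles, 0, sigma), ncol = 2) + drift
      pos <- pos + step
      if (motion_model == "confined") {
        pos <- t(apply(pos, 1, reflect_into_ellipse,
                       center = region$center, radii = region$radii))
      }
    }
    out[[f]] <- data.frame(particle = seq_len(n_particles), frame = f,
                           x = pos[, 1], y = pos[, 2])
  }
  tracks <- do.call(rbind, out)
  tracks <- tracks[order(tracks$particle, tracks$frame), ]
  rownames(tracks) <- NULL
  tracks$exited <- tracks$x < 0 | tracks$x > nc - 1 |
                   tracks$y < 0 | tracks$y > nr - 1
  structure(list(tracks = tracks, n_frames = as.integer(n_frames),
                 frame_shape = as.integer(frame_shape),
                 frame_interval_s = frame_interval_s,
                 motion_model = motion_model, D_px2_s = D_px2_s,
                 seed = seed),
            class = "ground_truth")
}

# radial reflection at an elliptical wall, iterated in case a large step
# overshoots past the mirror position
reflect_into_ellipse <- function(p, center, radii) {
  for (it in 1:50) {
    u <- (p - center) / radii
    r <- sqrt(sum(u^2))
    if (r <= 1) return(p)
    u <- u / r * max(2 - r, 0)  # reflect the radial excess back inside
    p <- center + u * radii
    if (max(2 - r, 0) == 0) return(center)  # pathological overshoot
  }
  p
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d particles x %d frames (%s motion, D = %g px^2/s)\n",
              length(unique(x$tracks$particle)), x$n_frames, x$motion_model,
              x$D_px2_s))
  if (!is.null(x$tracks$tau_ns))
    cat(sprintf("  lifetimes assigned: %.3g-%.3g ns\n",
                min(x$tracks$tau_ns), max(x$tracks$tau_ns)))
  invisible(x)
}

#' Assign per-frame lifetimes to ground-truth particles
#'
#' Each particle-frame receives the monoexponential lifetime of the
#' compartment it currently occupies, from a named lookup table. Optionally
#' the step at a compartment crossing is smoothed linearly over
#' `transition_frames` frames, and an environmental heterogeneity term adds
#' iid Gaussian fluctuation (`medium_sigma_ns`) to every particle-frame --
#' the short-correlation-length limit of a particle moving quickly through a
#' spatially heterogeneous medium such as an agarose gel.
#'
#' @param ground_truth a [simulate_tracks()] object.
#' @param compartment_map a [make_compartment_map()], or `NULL` for a uniform
#'   medium (every position labelled `extracellular`).
#' @param lifetime_table_ns named numeric vector mapping every compartment
#'   label that occurs to a lifetime (ns, `> 0`).
#' @param transition_frames smooth a crossing over this many frames
#'   (0 = step change at the crossing frame).
#' @param medium_sigma_ns sd of iid per-particle-frame lifetime fluctuation
#'   (ns, `>= 0`).
#' @param seed optional integer seed (for the fluctuation term).
#' @return The `ground_truth` with `tau_ns` and `compartment` columns added.
#' @export
assign_lifetimes <- function(ground_truth, compartment_map, lifetime_table_ns,
                             transition_frames = 0, medium_sigma_ns = 0,
                             seed = NULL) {
  stopifnot(inherits(ground_truth, "ground_truth"), medium_sigma_ns >= 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ground_truth$tracks
  if (is.null(compartment_map)) {
    comp <- rep("extracellular", nrow(tr))
  } else {
    comp <- compartment_at(compartment_map, tr$x, tr$y)
  }
  missing <- setdiff(unique(comp), names(lifetime_table_ns))
  if (length(missing))
    stop("lifetime_table_ns is missing labels: ", paste(missing, collapse = ", "))
  if (any(lifetime_table_ns <= 0)) stop("lifetimes must be > 0")
  tau <- unname(lifetime_table_ns[comp])
  if (transition_frames > 0) {
    k <- as.integer(transition_frames)
    for (id in unique(tr$particle)) {
      idx <- which(tr$particle == id)
      tau[idx] <- smooth_transitions(tau[idx], k)
    }
  }
  if (medium_sigma_ns > 0) {
    tau <- pmax(tau + rnorm(length(tau), 0, medium_sigma_ns), 0.05)
  }
  tr$tau_ns <- tau
  tr$compartment <- comp
  ground_truth$tracks <- tr
  ground_truth
}

# linear ramp over k frames after each step change in a per-frame tau series
smooth_transitions <- function(tau, k) {
  n <- length(tau)
  out <- tau
  i <- 2
  while (i <= n) {
    if (tau[i] != tau[i - 1]) {
      j <- min(n, i + k - 1)
      ramp <- seq(out[i - 1], tau[i], length.out = j - i + 2)[-1]
      # do not overwrite a later, different compartment value
      stable <- tau[i:j] == tau[i]
      out[i:j][stable] <- ramp[stable]
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Write ground truth to CSV with a JSON metadata sidecar
#' @param ground_truth a [simulate_tracks()] object (with or without
#'   lifetimes assigned).
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write.csv(ground_truth$tracks, path, row.names = FALSE)
  meta <- ground_truth[setdiff(names(ground_truth), "tracks")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
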