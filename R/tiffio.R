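# Minimal 32-bit-float TIFF codec (little-endian, uncompressed, greyscale,
# SampleFormat = IEEE float). Written in-package because the installed TIFF
# bindings only store [0,1]-scaled unsigned integers, while the pipeline's
# interchange format is a two-channel float stack (channel 1 intensity
# counts, channel 2 lifetime in ns). The reader tolerates multi-strip files
# so stacks written by other float-TIFF tools can be ingested.

TIFF_SENTINEL_UNDEFINED <- -1

write_float_tiff <- function(matrices, path) {
  stopifnot(length(matrices) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w16(42)
  # strip data starts right after the 8-byte header; IFDs follow all strips
  sizes <- vapply(matrices, function(m) length(m) * 4L, numeric(1))
  offsets <- 8 + cumsum(c(0, sizes[-length(sizes)]))
  ifd0 <- 8 + sum(sizes)
  w32(ifd0)
  for (m in matrices) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
  }
  n_tags <- 10L
  ifd_size <- 2 + 12 * n_tags + 4
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    tag <- function(id, type, count, value) {
      w16(id); w16(type); w32(count)
      if (type == 3) { w16(value); w16(0) } else w32(value)
    }
    w16(n_tags)
    tag(256, 4, 1, ncol(m))            # ImageWidth
    tag(257, 4, 1, nrow(m))            # ImageLength
    tag(258, 3, 1, 32)                 # BitsPerSample
    tag(259, 3, 1, 1)                  # Compression: none
    tag(262, 3, 1, 1)                  # Photometric: BlackIsZero
    tag(273, 4, 1, offsets[i])         # StripOffsets
    tag(277, 3, 1, 1)                  # SamplesPerPixel
    tag(278, 4, 1, nrow(m))            # RowsPerStrip
    tag(279, 4, 1, sizes[i])           # StripByteCounts
    tag(339, 3, 1, 3)                  # SampleFormat: IEEE float
    next_ifd <- if (i < length(matrices)) ifd0 + i * ifd_size else 0
    w32(next_ifd)
  }
  invisible(path)
}

read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  r16 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
  r32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian ('II') TIFF files are supported")
  if (r16(3) != 42) stop("not a TIFF file")
  ifd <- r32(5)
  out <- list()
  while (ifd != 0) {
    n <- r16(ifd + 1)
    tags <- list()
    for (k in seq_len(n)) {
      at <- ifd + 2 + (k - 1) * 12
      id <- r16(at + 1); type <- r16(at + 3); count <- r32(at + 5)
      val_at <- at + 9
      values <- if (count == 1 && type %in% c(3, 4)) {
        if (type == 3) r16(val_at) else r32(val_at)
      } else {
        off <- r32(val_at)
        sz <- if (type == 3) 2 else 4
        vapply(seq_len(count), function(j) {
          a <- off + (j - 1) * sz + 1
          if (type == 3) r16(a) else r32(a)
        }, numeric(1))
      }
      tags[[as.character(id)]] <- values
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF tag ", id, " missing")
        default
      } else v
    }
    width <- need(256); height <- need(257)
    if (any(need(258) != 32) || need(339, 1) != 3)
      stop("expected 32-bit IEEE float samples")
    if (need(259, 1) != 1) stop("compressed TIFF not supported")
    if (need(277, 1) != 1)
      stop("expected 1 sample per pixel (planar two-channel layout)")
    so <- need(273); sbc <- need(279)
    vals <- unlist(lapply(seq_along(so), function(j) {
      readBin(raw[(so[j] + 1):(so[j] + sbc[j])], "numeric",
              n = sbc[j] / 4, size = 4, endian = "little")
    }))
    out[[length(out) + 1]] <- matrix(vals, height, width, byrow = TRUE)
    ifd <- r32(ifd + 2 + n * 12 + 1)
  }
  out
}

#' Write a two-channel (intensity, lifetime) TIFF stack
#'
#' Each frame is stored as two consecutive 32-bit float greyscale TIFF
#' directories: channel 1 the per-pixel photon counts, channel 2 the
#' per-pixel lifetime in ns. Undefined lifetimes (`NA`) are encoded with the
#' reserved sentinel `-1` (0 would be ambiguous since a zero lifetime is
#' meaningful); a JSON sidecar `<path>.json` records the channel layout,
#' units and sentinel.
#'
#' @param images list of `lifetime_image` frames or a `flim_movie`.
#' @param path output `.tif` path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_two_channel_tiff <- function(images, path, sidecar = TRUE) {
  frames <- movie_frames(images)
  stopifnot(length(frames) >= 1)
  mats <- vector("list", 2 * length(frames))
  for (f in seq_along(frames)) {
    lt <- frames[[f]]$lifetime_ns
    lt[is.na(lt)] <- TIFF_SENTINEL_UNDEFINED
    mats[[2 * f - 1]] <- frames[[f]]$intensity
    mats[[2 * f]] <- lt
  }
  write_float_tiff(mats, path)
  if (sidecar) {
    jsonlite::write_json(list(
      channels = c("intensity", "lifetime"),
      units = c(intensity = "photon counts", lifetime = "ns"),
      undefined_lifetime_sentinel = TIFF_SENTINEL_UNDEFINED,
      n_frames = length(frames)), paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a two-channel (intensity, lifetime) TIFF stack
#'
#' Expects frames stored as alternating intensity/lifetime 32-bit float
#' directories as written by [write_two_channel_tiff()]; lifetime pixels
#' equal to the sentinel (default `-1`, or as recorded in the sidecar) are
#' restored to `NA`.
#'
#' @param path `.tif` path.
#' @param frame_interval_s frame timing metadata to attach (s).
#' @return list of `lifetime_image` frames.
#' @export
read_two_channel_tiff <- function(path, frame_interval_s = 1) {
  mats <- read_float_tiff(path)
  if (length(mats) %% 2 != 0)
    stop("expected an even number of TIFF directories ",
         "(channel 1 intensity, channel 2 lifetime, per frame); got ",
         length(mats))
  sentinel <- TIFF_SENTINEL_UNDEFINED
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$undefined_lifetime_sentinel))
      sentinel <- meta$undefined_lifetime_sentinel
  }
  n <- length(mats) / 2
  lapply(seq_len(n), function(f) {
    lt <- mats[[2 * f]]
    lt[lt == sentinel] <- NA_real_
    structure(list(intensity = mats[[2 * f - 1]], lifetime_ns = lt,
                   frame_index = f, frame_time_s = (f - 1) * frame_interval_s),
              class = "lifetime_image")
  })
}
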