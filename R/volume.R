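#' Multi-channel time-lapse image volume
#'
#' The universal image container of the package: one or more channels of a
#' voxel grid over time, with physical voxel sizes (micrometres) and
#' per-frame timestamps. Arrays are indexed `[x, y, z, t]`; voxel `i` along
#' an axis has its center at `(i - 0.5) * voxel_size` with the origin at
#' the stack corner and z along the optical axis.
#'
#' @param channels named list of 4D numeric arrays `[x, y, z, t]` (a 3D
#'   array is treated as a single frame).
#' @param voxel_size numeric length-3, voxel size in um along (x, y, z).
#' @param frame_interval seconds between frames (NA for session series).
#' @param timestamps numeric per-frame acquisition times; must be
#'   non-decreasing. Units are seconds for time-lapse movies and hours for
#'   multi-session series (stored verbatim in `time_unit`).
#' @param time_unit `"s"` or `"h"`.
#' @param meta free-form list of acquisition provenance.
#' @return an object of class `tlv`.
#' @export
time_lapse_volume <- function(channels, voxel_size, frame_interval = NA_real_,
                              timestamps = NULL, time_unit = "s",
                              meta = list()) {
  if (is.array(channels)) channels <- list(ch1 = channels)
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  channels <- lapply(channels, function(a) {
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    stopifnot(length(dim(a)) == 4L)
    a
  })
  d <- dim(channels[[1L]])
  for (a in channels) stopifnot(identical(dim(a), d))
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(timestamps)) {
    timestamps <- if (is.na(frame_interval)) rep(NA_real_, d[4L]) else
      (seq_len(d[4L]) - 1L) * frame_interval
  }
  stopifnot(length(timestamps) == d[4L])
  ts <- timestamps[!is.na(timestamps)]
  if (length(ts) > 1L && any(diff(ts) < 0)) {
    stop("timestamps must be non-decreasing")
  }
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size),
                 frame_interval = frame_interval,
                 timestamps = as.numeric(timestamps), time_unit = time_unit,
                 meta = meta),
            class = "tlv")
}

#' @export
print.tlv <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<tlv> %d channel(s) [%s], grid %dx%dx%d, %d frame(s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um; extent %.3g x %.3g x %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3]))
  invisible(x)
}

#' Extract one 3D frame from a time-lapse volume
#'
#' @param vol a [time_lapse_volume()] object.
#' @param t frame index (1-based).
#' @param channel channel name or index.
#' @return a 3D numeric array `[x, y, z]`.
#' @export
tlv_frame <- function(vol, t = 1L, channel = 1L) {
  stopifnot(inherits(vol, "tlv"))
  a <- vol$channels[[channel]]
  stopifnot(t >= 1L, t <= dim(a)[4L])
  a[, , , t, drop = TRUE]
}

#' Number of frames in a time-lapse volume
#' @param vol a [time_lapse_volume()] object.
#' @return integer frame count.
#' @export
n_frames <- function(vol) dim(vol$channels[[1L]])[4L]

#' Physical extent of a volume in micrometres
#' @param vol a [time_lapse_volume()] object.
#' @return numeric length-3 (x, y, z) extent in um.
#' @export
tlv_extent <- function(vol) dim(vol$channels[[1L]])[1:3] * vol$voxel_size
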