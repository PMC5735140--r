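# Stack I/O: multi-page 32-bit float TIFF per channel per timepoint with a
# JSON sidecar carrying the physical metadata. Voxel metadata is mandatory
# on read: physical units pervade every downstream statistic, and failing
# loudly beats a silently wrong um^3.

#' Write a time-lapse volume to TIFF stacks with a JSON sidecar
#'
#' One multi-page float TIFF per channel per timepoint
#' (`<prefix>_<channel>_t<frame>.tif`, pages = z), plus
#' `<prefix>_meta.json` with voxel size, timestamps, channel names, the
#' intensity scale used for the float encoding, and any extra metadata.
#'
#' @param vol a [time_lapse_volume()].
#' @param prefix output path prefix (directories are created).
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(vol, prefix) {
  stopifnot(inherits(vol, "tlv"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$channels[[1L]])
  offset <- min(vapply(vol$channels, min, numeric(1)))
  scale <- max(1e-12,
               max(vapply(vol$channels, max, numeric(1))) - offset)
  files <- list()
  for (chn in names(vol$channels)) {
    ch <- vol$channels[[chn]]
    for (tt in seq_len(d[4L])) {
      pages <- lapply(seq_len(d[3L]), function(k) {
        (t(ch[, , k, tt]) - offset) / scale # TIFF pages are row = y, col = x
      })
      path <- sprintf("%s_%s_t%03d.tif", prefix, chn, tt)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      files[[length(files) + 1L]] <-
        list(channel = chn, frame = tt, file = basename(path))
    }
  }
  meta <- list(voxel_size_um = vol$voxel_size,
               grid = d[1:3],
               n_frames = d[4L],
               channels = names(vol$channels),
               frame_interval = if (is.na(vol$frame_interval)) NULL else
                 vol$frame_interval,
               timestamps = if (all(is.na(vol$timestamps))) NULL else
                 vol$timestamps,
               time_unit = vol$time_unit,
               intensity_scale = scale,
               intensity_offset = offset,
               files = files,
               meta = vol$meta)
  sidecar <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a time-lapse volume written by [write_stack()]
#'
#' @param prefix the path prefix used at write time, or the sidecar path.
#' @return a [time_lapse_volume()].
#' @export
read_stack <- function(prefix) {
  sidecar <- if (grepl("_meta\\.json$", prefix)) prefix else
    paste0(prefix, "_meta.json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar,
         " (voxel size metadata is mandatory)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um) || length(meta$voxel_size_um) != 3L ||
      any(meta$voxel_size_um <= 0)) {
    stop("sidecar lacks a valid voxel size")
  }
  d <- as.integer(meta$grid)
  nt <- as.integer(meta$n_frames)
  dirp <- dirname(sidecar)
  channels <- setNames(vector("list", length(meta$channels)), meta$channels)
  files <- meta$files
  for (chn in meta$channels) {
    ch <- array(NA_real_, c(d, nt))
    for (tt in seq_len(nt)) {
      row <- files[files$channel == chn & files$frame == tt, , drop = FALSE]
      if (nrow(row) != 1L) stop("sidecar misses file for ", chn, " frame ", tt)
      pages <- tiff::readTIFF(file.path(dirp, row$file), all = TRUE)
      if (length(pages) != d[3L]) {
        stop("inconsistent page count in ", row$file)
      }
      for (k in seq_len(d[3L])) {
        pg <- pages[[k]]
        if (!identical(dim(pg)[1:2], d[c(2L, 1L)])) {
          stop("inconsistent page shape in ", row$file)
        }
        ch[, , k, tt] <- t(pg) * meta$intensity_scale +
          (meta$intensity_offset %||% 0)
      }
    }
    channels[[chn]] <- ch
  }
  ts <- meta$timestamps
  if (!length(ts)) ts <- NULL else ts <- as.numeric(ts)
  fi <- meta$frame_interval
  if (!length(fi)) fi <- NA_real_
  time_lapse_volume(channels, meta$voxel_size_um,
                    frame_interval = fi, timestamps = ts,
                    time_unit = meta$time_unit %||% "s",
                    meta = as.list(meta$meta))
}
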