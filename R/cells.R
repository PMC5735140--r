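# B-lineage cell detection, volume-based classification, track linking,
# the track-length inclusion filter, and motility metrics.

#' Detect fluorescent cells in one 3D frame
#'
#' Gaussian smoothing, a global threshold (Otsu by default), 26-connected
#' components, and a watershed split of touching cells seeded at the local
#' maxima of the distance transform. Volumes are voxel counts times the
#' physical voxel volume.
#'
#' @param vol volume or 3D array; for a [time_lapse_volume()] pass the
#'   frame via `t`.
#' @param t frame index when `vol` is a time-lapse volume.
#' @param smoothing_fwhm smoothing FWHM in um.
#' @param threshold `"robust"` (background median plus `robust_k` times the
#'   scaled MAD; appropriate for sparse objects, where Otsu's two-class
#'   model fails), `"otsu"`, or a numeric intensity.
#' @param robust_k multiple of the background MAD for the robust threshold.
#' @param min_volume minimum detection volume in um^3.
#' @param split_touching watershed-split components with several distance
#'   maxima.
#' @param seed_separation minimum physical distance (um) between watershed
#'   seeds.
#' @param voxel_size voxel size for bare arrays.
#' @return data.frame with columns `frame`, `x`, `y`, `z` (um, centroid),
#'   `volume` (um^3), `mean_intensity`.
#' @export
detect_cells <- function(vol, t = 1L, smoothing_fwhm = 1.5,
                         threshold = "robust", min_volume = 30,
                         robust_k = 6, split_touching = TRUE,
                         seed_separation = 6, voxel_size = NULL) {
  a <- resolve_frame(vol, t)
  voxel_size <- resolve_voxel(vol, voxel_size)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), volume = numeric(0),
                      mean_intensity = numeric(0))
  if (diff(range(a)) == 0) return(empty)
  sm <- blur3d(a, rep(smoothing_fwhm, 3L), voxel_size)
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(sm)
  } else if (identical(threshold, "robust")) {
    median(sm) + robust_k * stats::mad(sm)
  } else {
    threshold
  }
  m <- sm > thr
  if (!any(m)) return(empty)
  lab <- label3d(m, 26L)
  if (split_touching) {
    edt <- edt3d(m, voxel_size)
    pr <- blur3d(edt, rep(min(voxel_size), 3L), voxel_size)
    cand <- which(local_maxima3d(pr) & m)
    if (length(cand)) {
      pts <- sweep(arrayInd(cand, dim(m)) - 0.5, 2L, voxel_size, "*")
      keep <- nms_points(pts, pr[cand], seed_separation)
      seeds <- array(0L, dim(m))
      seeds[cand[keep]] <- seq_along(keep)
      # only split components that contain more than one seed
      multi <- names(which(table(lab[cand[keep]]) > 1L))
      if (length(multi)) {
        sel <- array(lab %in% as.integer(multi), dim(m))
        seeds[!sel] <- 0L
        ws <- watershed3d(pr, sel, seeds)
        lab[sel] <- max(lab) + ws[sel]
      }
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  vv <- voxel_volume(voxel_size)
  out <- lapply(ids, function(id) {
    idx <- which(lab == id)
    if (length(idx) * vv < min_volume) return(NULL)
    pos <- arrayInd(idx, dim(m))
    ctr <- colMeans(sweep(pos - 0.5, 2L, voxel_size, "*"))
    data.frame(frame = as.integer(t), x = ctr[1], y = ctr[2], z = ctr[3],
               volume = length(idx) * vv, mean_intensity = mean(a[idx]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Detect cells in every frame of a movie
#'
#' @param vol a [time_lapse_volume()].
#' @param ... passed to [detect_cells()].
#' @return data.frame of per-frame detections.
#' @export
detect_cells_movie <- function(vol, ...) {
  stopifnot(inherits(vol, "tlv"))
  do.call(rbind, lapply(seq_len(n_frames(vol)),
                        function(tt) detect_cells(vol, t = tt, ...)))
}

#' Classify a cell by volume
#'
#' Cells with a volume above the threshold are plasma cells; all others
#' (ties included) are B cells. The default 500 um^3 boundary corresponds
#' to a sphere of about 10 um diameter.
#'
#' @param volume cell volume(s) in um^3; must be positive.
#' @param threshold class boundary in um^3.
#' @return character vector, `"B cell"` or `"plasma cell"`.
#' @export
classify_cell <- function(volume, threshold = 500) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("cell volumes must be positive")
  }
  ifelse(volume > threshold, "plasma cell", "B cell")
}

#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-first frame-to-frame assignment: all candidate
#' (active track, detection) pairs within `max_step` are sorted by distance
#' (ties broken by lower track id) and assigned greedily. A track that
#' misses a frame may bridge up to `max_gap` frames, with the step bound
#' scaled by the gap length. Unmatched detections start new tracks.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `z` and
#'   optionally `volume`, `mean_intensity`.
#' @param max_step maximum link distance per frame step, in um.
#' @param max_gap maximum number of bridged missing frames.
#' @return data.frame of the input rows plus a `track` id column, ordered
#'   by track then frame.
#' @export
link_tracks <- function(detections, max_step = 10, max_gap = 1L) {
  stopifnot(all(c("frame", "x", "y", "z") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track <- NA_integer_
  if (nrow(det) == 0L) return(det)
  frames <- sort(unique(det$frame))
  # active track state: id, last frame, last position
  state <- data.frame(track = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    live <- state[f - state$frame <= max_gap + 1L, , drop = FALSE]
    if (nrow(live) && length(rows)) {
      gap <- f - live$frame
      dx <- outer(live$x, det$x[rows], "-")
      dy <- outer(live$y, det$y[rows], "-")
      dz <- outer(live$z, det$z[rows], "-")
      dd <- sqrt(dx^2 + dy^2 + dz^2)
      lim <- matrix(max_step * gap, nrow(live), length(rows))
      cand <- which(dd <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dd[cand], live$track[cand[, 1L]])
        used_tr <- logical(nrow(live))
        used_det <- logical(length(rows))
        for (ci in ord) {
          i <- cand[ci, 1L]
          j <- cand[ci, 2L]
          if (used_tr[i] || used_det[j]) next
          used_tr[i] <- TRUE
          used_det[j] <- TRUE
          det$track[rows[j]] <- live$track[i]
        }
      }
    }
    new_rows <- rows[is.na(det$track[rows])]
    if (length(new_rows)) {
      det$track[new_rows] <- next_id + seq_along(new_rows) - 1L
      next_id <- next_id + length(new_rows)
    }
    upd <- det[rows, c("track", "frame", "x", "y", "z")]
    state <- state[!(state$track %in% upd$track), , drop = FALSE]
    state <- rbind(state, upd)
  }
  det <- det[order(det$track, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Exhaustive minimal-total-distance frame linking (test oracle)
#'
#' Optimal one-to-one frame-to-frame assignment by enumeration of all
#' permutations; only usable for tiny instances. Serves as the independent
#' reference for [link_tracks()].
#'
#' @param detections as in [link_tracks()].
#' @param max_step maximum link distance in um.
#' @return data.frame with a `track` column.
#' @export
link_tracks_exhaustive <- function(detections, max_step = 10) {
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track <- NA_integer_
  frames <- sort(unique(det$frame))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  prev_rows <- which(det$frame == frames[1L])
  det$track[prev_rows] <- seq_along(prev_rows)
  next_id <- length(prev_rows) + 1L
  for (f in frames[-1L]) {
    rows <- which(det$frame == f)
    stopifnot(length(rows) <= 6L, length(prev_rows) <= 6L)
    dmat <- sqrt(outer(det$x[prev_rows], det$x[rows], "-")^2 +
                   outer(det$y[prev_rows], det$y[rows], "-")^2 +
                   outer(det$z[prev_rows], det$z[rows], "-")^2)
    k <- min(length(rows), length(prev_rows))
    best <- NULL
    best_cost <- Inf
    for (psel in perms(seq_along(rows))) {
      sel <- psel[seq_len(k)]
      cost <- 0
      ok <- TRUE
      for (i in seq_len(k)) {
        if (dmat[i, sel[i]] > max_step) {
          ok <- FALSE
          break
        }
        cost <- cost + dmat[i, sel[i]]
      }
      if (ok && cost < best_cost) {
        best_cost <- cost
        best <- sel
      }
    }
    if (!is.null(best)) {
      for (i in seq_len(k)) {
        det$track[rows[best[i]]] <- det$track[prev_rows[i]]
      }
    }
    un <- rows[is.na(det$track[rows])]
    if (length(un)) {
      det$track[un] <- next_id + seq_along(un) - 1L
      next_id <- next_id + length(un)
    }
    prev_rows <- rows
  }
  det
}

#' Track-length inclusion filter
#'
#' Retains only tracks present for strictly more than `min_timepoints`
#' recorded time points; at the default 30-s frame interval every retained
#' track spans at least 5 min.
#'
#' @param tracks data.frame with `track` and `frame` columns.
#' @param min_timepoints inclusion bound (a track needs more than this many
#'   time points).
#' @param frame_interval seconds per frame (used for the duration check).
#' @return the retained rows.
#' @export
filter_tracks <- function(tracks, min_timepoints = 10L, frame_interval = 30) {
  if (nrow(tracks) == 0L) return(tracks)
  cnt <- table(tracks$track)
  keep <- names(cnt)[cnt > min_timepoints]
  tracks[as.character(tracks$track) %in% keep, , drop = FALSE]
}

#' Per-track motility metrics
#'
#' Mean velocity is the average of per-step speed (step distance over step
#' time); displacement rate is the straight start-to-end distance divided
#' by the track duration. Both are reported in um/min.
#'
#' @param tracks data.frame with `track`, `frame`, `x`, `y`, `z` and
#'   optionally `volume`.
#' @param frame_interval seconds per frame.
#' @return data.frame, one row per track: `track`, `n_timepoints`,
#'   `duration_min`, `mean_velocity`, `displacement_rate`, `volume`
#'   (mean over the track; NA when absent), `class`.
#' @export
motility_metrics <- function(tracks, frame_interval = 30) {
  stopifnot(nrow(tracks) > 0L)
  out <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2L) stop("motility metrics need at least 2 timepoints per track")
    dt_min <- diff(tr$frame) * frame_interval / 60
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    dur <- (tr$frame[n] - tr$frame[1L]) * frame_interval / 60
    disp <- sqrt((tr$x[n] - tr$x[1L])^2 + (tr$y[n] - tr$y[1L])^2 +
                   (tr$z[n] - tr$z[1L])^2)
    vol <- if ("volume" %in% names(tr)) mean(tr$volume) else NA_real_
    data.frame(track = tr$track[1L], n_timepoints = n, duration_min = dur,
               mean_velocity = mean(steps / dt_min),
               displacement_rate = disp / dur,
               volume = vol,
               class = if (is.na(vol)) NA_character_ else classify_cell(vol))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison of motility metrics between groups
#'
#' Two-sided Welch t-test per metric, with conventional significance
#' stars at 0.05 / 0.01 / 0.001.
#'
#' @param a,b data.frames of per-track metrics (as from
#'   [motility_metrics()]) for the two groups.
#' @param metrics columns to compare.
#' @return data.frame: `metric`, `mean_a`, `mean_b`, `t`, `df`, `p_value`,
#'   `stars`.
#' @export
compare_groups <- function(a, b, metrics = c("mean_velocity",
                                             "displacement_rate", "volume")) {
  metrics <- intersect(metrics, intersect(names(a), names(b)))
  stopifnot(length(metrics) >= 1L, nrow(a) >= 2L, nrow(b) >= 2L)
  out <- lapply(metrics, function(mcol) {
    xa <- a[[mcol]]
    xb <- b[[mcol]]
    xa <- xa[is.finite(xa)]
    xb <- xb[is.finite(xb)]
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- t.test(xa, xb)
    }
    p <- tt$p.value
    stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
      if (p < 0.05) "*" else "ns"
    data.frame(metric = mcol, mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = p, stars = stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
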