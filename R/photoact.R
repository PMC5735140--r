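# Photoactivated-GFP quantification: ROI signal over repeated sessions,
# exponential label decay, and implant positional stability.

#' Quantify a photoactivation ROI across imaging sessions
#'
#' For each session frame, reports the mean intensity inside a fixed cuboid
#' ROI, the above-threshold fluorescent volume (um^3), and the
#' intensity-weighted centroid of the above-threshold voxels. The ROI is
#' fixed in stack coordinates; the implant serves as the frame of
#' reference.
#'
#' @param vol a [time_lapse_volume()] whose frames are the sessions
#'   (timestamps in hours), or a list of 3D arrays plus `timestamps_h`.
#' @param roi list with `lo` and `hi` (um corner coordinates) or `extent`
#'   (length-3, centered in the volume). Default: the central
#'   75 x 75 x 30 um^3 activation volume.
#' @param signal_threshold intensity above which a voxel counts as
#'   fluorescent; default `"auto"` uses twice the ROI median of the first
#'   session (taken as the pre-activation reference), i.e. signal counts as
#'   detectable once it clearly exceeds the unactivated baseline.
#' @param timestamps_h session times (h) when `vol` is a list of arrays.
#' @param voxel_size voxel size (um) when `vol` is a list of arrays.
#' @return object of class `photoact_series`: data.frame `sessions`
#'   (`session`, `time_h`, `mean_intensity`, `volume_um3`, `cx`, `cy`,
#'   `cz`), the ROI bounds, the threshold used.
#' @export
quantify_roi <- function(vol, roi = list(extent = c(75, 75, 30)),
                         signal_threshold = "auto", timestamps_h = NULL,
                         voxel_size = NULL) {
  if (inherits(vol, "tlv")) {
    frames <- lapply(seq_len(n_frames(vol)), function(tt) tlv_frame(vol, tt))
    timestamps_h <- vol$timestamps
    voxel_size <- vol$voxel_size
  } else {
    frames <- vol
    stopifnot(!is.null(timestamps_h), !is.null(voxel_size))
  }
  stopifnot(length(frames) >= 1L, length(timestamps_h) == length(frames))
  d <- dim(frames[[1L]])
  ext <- d * voxel_size
  if (is.null(roi$lo)) {
    stopifnot(!is.null(roi$extent), all(roi$extent <= ext))
    roi$lo <- (ext - roi$extent) / 2
    roi$hi <- roi$lo + roi$extent
  }
  stopifnot(all(roi$lo >= 0), all(roi$hi <= ext + 1e-9))
  cent <- lapply(1:3, function(ax) axis_centers(d[ax], voxel_size[ax]))
  sel <- lapply(1:3, function(ax) {
    which(cent[[ax]] >= roi$lo[ax] & cent[[ax]] <= roi$hi[ax])
  })
  if (identical(signal_threshold, "auto")) {
    signal_threshold <- 2 * median(frames[[1L]][sel[[1]], sel[[2]], sel[[3]]])
  }
  vv <- voxel_volume(voxel_size)
  rows <- lapply(seq_along(frames), function(s) {
    sub <- frames[[s]][sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
    above <- sub > signal_threshold
    if (any(above)) {
      pos <- arrayInd(which(above), dim(sub))
      pos[, 1] <- sel[[1]][pos[, 1]]
      pos[, 2] <- sel[[2]][pos[, 2]]
      pos[, 3] <- sel[[3]][pos[, 3]]
      w <- sub[above]
      phys <- sweep(pos - 0.5, 2L, voxel_size, "*")
      ctr <- colSums(phys * w) / sum(w)
    } else {
      ctr <- c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(session = s, time_h = timestamps_h[s],
               mean_intensity = mean(sub), volume_um3 = sum(above) * vv,
               cx = ctr[1], cy = ctr[2], cz = ctr[3])
  })
  structure(list(sessions = do.call(rbind, rows), roi = roi,
                 signal_threshold = signal_threshold,
                 voxel_size = voxel_size),
            class = "photoact_series")
}

#' @export
print.photoact_series <- function(x, ...) {
  cat(sprintf("Photoactivation series, %d session(s); threshold %.3g\n",
              nrow(x$sessions), x$signal_threshold))
  print(x$sessions, row.names = FALSE)
  invisible(x)
}

#' Fold increase of ROI signal upon photoactivation
#'
#' Ratio of the ROI mean intensity in the first post-activation session to
#' the pre-activation session.
#'
#' @param series a [quantify_roi()] result.
#' @param pre_frame index of the pre-activation session (default 1).
#' @return the dimensionless post/pre ratio.
#' @export
activation_ratio <- function(series, pre_frame = 1L) {
  s <- series$sessions
  stopifnot(nrow(s) >= 2L, pre_frame >= 1L, pre_frame < nrow(s))
  s$mean_intensity[pre_frame + 1L] / s$mean_intensity[pre_frame]
}

#' Fit an exponential decay to a photoactivation series
#'
#' Least-squares fit of `I(t) = A exp(-k t) + C` to the post-activation
#' ROI means. The half-life is `ln(2) / k`.
#'
#' @param series a [quantify_roi()] result, or a data.frame with `time_h`
#'   and `mean_intensity`.
#' @param pre_frame pre-activation session to drop (set to 0 to use all
#'   rows).
#' @param fit_baseline fit the additive offset `C`; with `FALSE` the decay
#'   is fitted toward zero.
#' @return list of class `decay_fit`: `amplitude`, `rate_per_h`,
#'   `baseline`, `half_life_h`, `fitted` data.frame.
#' @export
fit_decay <- function(series, pre_frame = 1L, fit_baseline = TRUE) {
  s <- if (inherits(series, "photoact_series")) series$sessions else series
  if (pre_frame >= 1L && nrow(s) > pre_frame) s <- s[-seq_len(pre_frame), ]
  s <- s[is.finite(s$mean_intensity), , drop = FALSE]
  if (nrow(s) < 3L) stop("need at least 3 sessions with defined intensity")
  t_h <- s$time_h
  y <- s$mean_intensity
  if (diff(range(y)) < .Machine$double.eps * max(abs(y), 1)) {
    fitted <- data.frame(time_h = t_h, fitted = y)
    return(structure(list(amplitude = 0, rate_per_h = 0, baseline = y[1L],
                          half_life_h = Inf, fitted = fitted),
                     class = "decay_fit"))
  }
  if (y[length(y)] >= y[1L]) {
    warning("non-decreasing series: decay rate reported <= 0")
  }
  c0 <- if (fit_baseline) min(y) * 0.5 else 0
  pos <- pmax(y - c0, max(abs(y)) * 1e-6)
  lf <- lm(log(pos) ~ t_h)
  k0 <- unname(-coef(lf)[2L]) # may be negative for a non-decreasing series
  a0 <- unname(exp(coef(lf)[1L]))
  start <- if (fit_baseline) list(A = a0, k = k0, C = c0) else
    list(A = a0, k = k0)
  form <- if (fit_baseline) y ~ A * exp(-k * t_h) + C else y ~ A * exp(-k * t_h)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t_h = t_h, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear solution (e.g. ill-conditioned growth)
    k <- k0
    return(structure(list(amplitude = a0, rate_per_h = k, baseline = 0,
                          half_life_h = if (k > 0) log(2) / k else Inf,
                          fitted = data.frame(time_h = t_h,
                                              fitted = a0 * exp(-k * t_h))),
                     class = "decay_fit"))
  }
  p <- coef(fit)
  k <- unname(p["k"])
  structure(list(amplitude = unname(p["A"]), rate_per_h = k,
                 baseline = if (fit_baseline) unname(p["C"]) else 0,
                 half_life_h = if (k > 0) log(2) / k else Inf,
                 fitted = data.frame(time_h = t_h,
                                     fitted = unname(predict(fit)))),
            class = "decay_fit")
}

#' Positional-stability report of a photoactivation series
#'
#' Per-session Euclidean drift of the ROI signal centroid from the first
#' session with a defined centroid, the maximum drift, a pass/fail verdict
#' against a tolerance, and the persistence horizon (the last session time
#' with above-threshold fluorescent volume).
#'
#' @param series a [quantify_roi()] result.
#' @param drift_tolerance maximum acceptable drift in um.
#' @param reference_session index of the reference session; defaults to
#'   the first session with a defined centroid.
#' @return list of class `stability_report`: `drift` data.frame
#'   (`session`, `time_h`, `drift_um`), `max_drift_um`, `pass`,
#'   `persistence_horizon_h`.
#' @export
stability <- function(series, drift_tolerance = 10, reference_session = NULL) {
  s <- series$sessions
  defined <- which(is.finite(s$cx))
  if (length(defined) == 0L) stop("no session has a defined centroid")
  ref <- reference_session %||% defined[1L]
  if (!is.finite(s$cx[ref])) stop("reference session has no defined centroid")
  if (length(setdiff(seq_len(nrow(s)), defined))) {
    warning("sessions without above-threshold signal skipped: ",
            paste(setdiff(seq_len(nrow(s)), defined), collapse = ", "))
  }
  drift <- sqrt((s$cx - s$cx[ref])^2 + (s$cy - s$cy[ref])^2 +
                  (s$cz - s$cz[ref])^2)
  with_sig <- which(s$volume_um3 > 0)
  horizon <- if (length(with_sig)) max(s$time_h[with_sig]) else NA_real_
  md <- max(drift[defined])
  structure(list(drift = data.frame(session = s$session, time_h = s$time_h,
                                    drift_um = drift),
                 max_drift_um = md, pass = md <= drift_tolerance,
                 persistence_horizon_h = horizon),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Positional stability: max drift %.2f um (%s); persistence horizon %.1f h\n",
              x$max_drift_um, if (x$pass) "pass" else "FAIL",
              x$persistence_horizon_h))
  invisible(x)
}
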