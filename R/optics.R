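# PSF and signal-to-noise characterization of the microendoscope from
# bead / quantum-dot stacks.

#' Detect candidate beads in a single-frame 3D stack
#'
#' Finds local intensity maxima above an intensity percentile, suppresses
#' maxima closer than `min_separation` (the brighter one is kept), and
#' refines each candidate to a sub-voxel centroid by center of mass in a
#' 3x3x3 neighborhood.
#'
#' @param vol a [time_lapse_volume()] (first channel, first frame is used)
#'   or a 3D array; in the latter case supply `voxel_size`.
#' @param min_separation minimum physical distance (um) between candidates.
#' @param intensity_percentile percentile (0-100) of the intensity
#'   distribution used as the detection threshold.
#' @param voxel_size voxel size in um, required when `vol` is a bare array.
#' @return data.frame with columns `x`, `y`, `z` (um) and `intensity`.
#' @export
detect_beads <- function(vol, min_separation = 3, intensity_percentile = 99.9,
                         voxel_size = NULL) {
  a <- resolve_frame(vol)
  voxel_size <- resolve_voxel(vol, voxel_size)
  if (length(a) == 0L || diff(range(a)) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0)))
  }
  thr <- quantile(a, intensity_percentile / 100, names = FALSE)
  cand <- which(local_maxima3d(a) & a > thr)
  if (length(cand) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0)))
  }
  d <- dim(a)
  pos <- arrayInd(cand, d)
  pts <- sweep(pos - 0.5, 2L, voxel_size, "*")
  # a saturated plateau wider than min_separation shows up as many equal
  # maxima in one blob; flag it before suppression
  if (length(cand) > 2L) {
    eq <- abs(a[cand] - max(a[cand])) < .Machine$double.eps * max(a[cand])
    if (sum(eq) > 2L) {
      dd <- as.matrix(dist(pts[eq, , drop = FALSE]))
      if (any(dd > 0 & dd < min_separation)) {
        message("detect_beads: saturated plateau detected; ",
                "centroids may be unreliable")
      }
    }
  }
  keep <- nms_points(pts, a[cand], min_separation)
  pos <- pos[keep, , drop = FALSE]
  # center-of-mass refinement in a 3^3 neighborhood (background-subtracted)
  bg <- median(a)
  out <- matrix(NA_real_, nrow(pos), 3L)
  for (i in seq_len(nrow(pos))) {
    lo <- pmax(pos[i, ] - 1L, 1L)
    hi <- pmin(pos[i, ] + 1L, d)
    sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] - bg
    sub[sub < 0] <- 0
    w <- sum(sub)
    for (ax in 1:3) {
      cc <- axis_centers(d[ax], voxel_size[ax])[lo[ax]:hi[ax]]
      marg <- apply(sub, ax, sum)
      out[i, ax] <- if (w > 0) sum(cc * marg) / w else
        (pos[i, ax] - 0.5) * voxel_size[ax]
    }
  }
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
             intensity = a[cand][keep])
}

#' Fit a 3D Gaussian bead model
#'
#' Least-squares fit of an axially symmetric 3D Gaussian plus constant
#' background to the voxels in a window around a candidate centroid. The
#' reported widths are full widths at half maximum
#' (`2 sqrt(2 ln 2) * sigma`); the lateral FWHM is the mean of the x and y
#' fits.
#'
#' @param vol volume or 3D array (see [detect_beads()]).
#' @param centroid numeric length-3 seed position in um.
#' @param window numeric length-3 half-window (um) around the centroid;
#'   should contain the full bead image.
#' @param voxel_size voxel size in um when `vol` is a bare array.
#' @param max_residual fit rejection bound: root-mean-square residual as a
#'   fraction of the fitted amplitude.
#' @param max_shift_vox fit rejection bound: centroid shift from the seed,
#'   in voxels.
#' @return list of class `bead_fit`: `centroid` (um), `fwhm_lateral`,
#'   `fwhm_axial` (um), `amplitude`, `background`, `residual_rms`,
#'   `accepted`, `reason`.
#' @export
fit_bead <- function(vol, centroid, window = c(2.5, 2.5, 12),
                     voxel_size = NULL, max_residual = 0.2,
                     max_shift_vox = 1) {
  a <- resolve_frame(vol)
  voxel_size <- resolve_voxel(vol, voxel_size)
  d <- dim(a)
  lo <- pmax(1L, floor((centroid - window) / voxel_size))
  hi <- pmin(d, ceiling((centroid + window) / voxel_size))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  sub <- a[ix, iy, iz, drop = FALSE]
  cx <- axis_centers(d[1], voxel_size[1])[ix]
  cy <- axis_centers(d[2], voxel_size[2])[iy]
  cz <- axis_centers(d[3], voxel_size[3])[iz]
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  px <- rep(cx, times = ny * nz)
  py <- rep(rep(cy, each = nx), times = nz)
  pz <- rep(cz, each = nx * ny)
  val <- as.numeric(sub)
  bg0 <- min(val)
  amp0 <- max(val) - bg0
  start <- c(x0 = centroid[1], y0 = centroid[2], z0 = centroid[3],
             lsl = log(max(voxel_size[1], window[1] / 5)),
             lsa = log(max(voxel_size[3], window[3] / 5)),
             amp = amp0, bg = bg0)
  model <- function(p) {
    sl2 <- exp(2 * p["lsl"]); sa2 <- exp(2 * p["lsa"])
    p["amp"] * exp(-((px - p["x0"])^2 + (py - p["y0"])^2) / (2 * sl2) -
                     (pz - p["z0"])^2 / (2 * sa2)) + p["bg"]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) val - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  reject <- function(reason) {
    structure(list(centroid = centroid, fwhm_lateral = NA_real_,
                   fwhm_axial = NA_real_, amplitude = NA_real_,
                   background = NA_real_, residual_rms = NA_real_,
                   accepted = FALSE, reason = reason), class = "bead_fit")
  }
  if (is.null(fit) || fit$info %in% c(0, 9)) return(reject("fit not converged"))
  p <- fit$par
  sl <- exp(p[["lsl"]]); sa <- exp(p[["lsa"]])
  rms <- sqrt(mean(fit$fvec^2))
  fwhm_l <- fwhm_factor() * sl
  fwhm_a <- fwhm_factor() * sa
  fitted_c <- c(p[["x0"]], p[["y0"]], p[["z0"]])
  if (p[["amp"]] <= 0) return(reject("non-positive amplitude"))
  if (rms > max_residual * p[["amp"]]) return(reject("residual too large"))
  if (any(abs(fitted_c - centroid) / voxel_size > max_shift_vox)) {
    return(reject("centroid shifted from seed"))
  }
  win_extent <- (hi - lo + 1) * voxel_size
  if (fwhm_l > win_extent[1] || fwhm_a > win_extent[3]) {
    return(reject("FWHM at window boundary"))
  }
  structure(list(centroid = fitted_c, fwhm_lateral = fwhm_l,
                 fwhm_axial = fwhm_a, amplitude = p[["amp"]],
                 background = p[["bg"]], residual_rms = rms,
                 accepted = TRUE, reason = NA_character_),
            class = "bead_fit")
}

#' Summarize bead fits into a PSF estimate
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the lateral and axial FWHM over all accepted bead fits.
#'
#' @param fits list of [fit_bead()] results (rejected fits are dropped).
#' @return list of class `psf_estimate`: `n_beads`, `fwhm_lateral_mean`,
#'   `fwhm_lateral_sd`, `fwhm_axial_mean`, `fwhm_axial_sd`, `depth_range`
#'   (um, range of fitted z positions).
#' @export
summarize_psf <- function(fits) {
  if (inherits(fits, "bead_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$accepted), fits)
  if (length(fits) == 0L) stop("no accepted bead fits")
  fl <- vapply(fits, `[[`, numeric(1), "fwhm_lateral")
  fa <- vapply(fits, `[[`, numeric(1), "fwhm_axial")
  zz <- vapply(fits, function(f) f$centroid[3], numeric(1))
  n <- length(fits)
  if (n == 1L) {
    warning("single bead fit: standard deviation reported as 0")
    sdl <- sda <- 0
  } else {
    sdl <- sd(fl)
    sda <- sd(fa)
  }
  structure(list(n_beads = n, fwhm_lateral_mean = mean(fl),
                 fwhm_lateral_sd = sdl, fwhm_axial_mean = mean(fa),
                 fwhm_axial_sd = sda, depth_range = range(zz)),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf("PSF estimate from %d bead(s):\n", x$n_beads))
  cat(sprintf("  lateral FWHM %.2f +- %.2f um\n",
              x$fwhm_lateral_mean, x$fwhm_lateral_sd))
  cat(sprintf("  axial   FWHM %.2f +- %.2f um\n",
              x$fwhm_axial_mean, x$fwhm_axial_sd))
  invisible(x)
}

#' Signal-to-noise ratio quality-control metric
#'
#' SNR is defined as the foreground mean divided by the background
#' standard deviation. When no masks are supplied, foreground is taken
#' above the Otsu threshold and background as the voxels below the 20th
#' intensity percentile of the remaining (non-foreground) voxels.
#'
#' @param vol volume or 3D array.
#' @param foreground_mask,background_mask optional logical arrays; must be
#'   disjoint and non-empty.
#' @param background_percentile percentile defining the default background.
#' @return list of class `snr_report`: `foreground_mean`, `background_sd`,
#'   `snr`.
#' @export
compute_snr <- function(vol, foreground_mask = NULL, background_mask = NULL,
                        background_percentile = 20) {
  a <- resolve_frame(vol)
  if (is.null(foreground_mask) != is.null(background_mask)) {
    stop("supply both masks or neither")
  }
  if (is.null(foreground_mask)) {
    thr <- otsu_threshold(a)
    foreground_mask <- a > thr
    rest <- a[!foreground_mask]
    bq <- quantile(rest, background_percentile / 100, names = FALSE)
    background_mask <- !foreground_mask & a <= bq
  }
  stopifnot(any(foreground_mask), any(background_mask))
  if (any(foreground_mask & background_mask)) {
    stop("foreground and background masks overlap")
  }
  bsd <- sd(a[background_mask])
  if (!is.finite(bsd) || bsd == 0) stop("degenerate background (sd = 0)")
  fgm <- mean(a[foreground_mask])
  structure(list(foreground_mean = fgm, background_sd = bsd,
                 snr = fgm / bsd), class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR %.2f (foreground mean %.2f / background sd %.2f)\n",
              x$snr, x$foreground_mean, x$background_sd))
  invisible(x)
}

# accept either a tlv or a bare 3D array
resolve_frame <- function(vol, t = 1L, channel = 1L) {
  if (inherits(vol, "tlv")) return(tlv_frame(vol, t, channel))
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  vol
}

resolve_voxel <- function(vol, voxel_size) {
  if (inherits(vol, "tlv")) return(vol$voxel_size)
  if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  as.numeric(voxel_size)
}
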