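# Micro-CT bone morphometry: cortical thickness via a two-Gaussian
# intensity-profile fit, and bone volume / bone surface from binarized
# stacks.

#' Cortical thickness from a two-Gaussian intensity-profile fit
#'
#' Samples the intensity along a line crossing both cortical walls
#' (trilinear interpolation) and fits the sum of two Gaussians plus a
#' constant baseline by least squares. The width of each Gaussian reports
#' the thickness of the respective wall; the headline value is the full
#' width at half maximum (`2 sqrt(2 ln 2) * sigma`), with sigma also
#' returned.
#'
#' @param vol volume or 3D array of the CT reconstruction.
#' @param line list with `start` and `end` (um coordinates).
#' @param n_samples number of interpolation points along the line.
#' @param voxel_size voxel size (um) for bare arrays.
#' @return object of class `ct_profile_fit`: `profile` data.frame (`s` um
#'   along the line, `intensity`), `centers` (um along the line), `sigma`
#'   (um), `fwhm` (um; per-wall thickness), `amplitude`, `baseline`.
#' @export
profile_thickness <- function(vol, line, n_samples = 200L,
                              voxel_size = NULL) {
  a <- resolve_frame(vol)
  voxel_size <- resolve_voxel(vol, voxel_size)
  p0 <- as.numeric(line$start)
  p1 <- as.numeric(line$end)
  stopifnot(length(p0) == 3L, length(p1) == 3L, n_samples >= 10L)
  len <- sqrt(sum((p1 - p0)^2))
  s <- seq(0, len, length.out = n_samples)
  pts <- outer(s / len, p1 - p0) + matrix(p0, n_samples, 3L, byrow = TRUE)
  y <- trilinear_interp(a, pts, voxel_size)
  # initial guesses: the two strongest well-separated profile peaks
  pk <- which(diff(sign(diff(y))) == -2L) + 1L
  pk <- pk[order(y[pk], decreasing = TRUE)]
  min_sep <- len / 10
  sel <- integer(0)
  for (i in pk) {
    if (all(abs(s[i] - s[sel]) > min_sep)) sel <- c(sel, i)
    if (length(sel) == 2L) break
  }
  if (length(sel) < 2L) stop("walls unresolved: fewer than two peaks on the line")
  sel <- sort(sel)
  bg0 <- min(y)
  sig0 <- len / 30
  start <- list(c1 = s[sel[1L]], c2 = s[sel[2L]],
                ls1 = log(sig0), ls2 = log(sig0),
                a1 = y[sel[1L]] - bg0, a2 = y[sel[2L]] - bg0, bg = bg0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(s - c1)^2 / (2 * exp(2 * ls1))) +
        a2 * exp(-(s - c2)^2 / (2 * exp(2 * ls2))) + bg,
      data = data.frame(s = s, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) stop("two-Gaussian fit did not converge")
  p <- coef(fit)
  centers <- sort(c(p[["c1"]], p[["c2"]]))
  ord <- order(c(p[["c1"]], p[["c2"]]))
  sigma <- c(exp(p[["ls1"]]), exp(p[["ls2"]]))[ord]
  amp <- c(p[["a1"]], p[["a2"]])[ord]
  if (any(centers < 0) || any(centers > len)) {
    stop("walls unresolved: fitted center outside the sampled line")
  }
  if (diff(centers) < sum(sigma * fwhm_factor()) / 2) {
    stop("walls unresolved: center separation below half the summed widths")
  }
  structure(list(profile = data.frame(s = s, intensity = y),
                 line = list(start = p0, end = p1),
                 centers = centers, sigma = sigma,
                 fwhm = fwhm_factor() * sigma,
                 amplitude = amp, baseline = p[["bg"]]),
            class = "ct_profile_fit")
}

#' @export
print.ct_profile_fit <- function(x, ...) {
  cat(sprintf("Two-Gaussian wall fit: thickness (FWHM) %.1f and %.1f um at %.0f / %.0f um\n",
              x$fwhm[1L], x$fwhm[2L], x$centers[1L], x$centers[2L]))
  invisible(x)
}

#' Bone volume and bone surface morphometry
#'
#' Binarizes the CT stack at an intensity threshold; bone volume (BV) is
#' the foreground voxel count times the voxel volume, bone surface (BS)
#' the count of exposed voxel faces times the face area (grid-boundary
#' faces of foreground voxels count as exposed). Requires isotropic
#' voxels. Results are reported in mm^3 / mm^2 / mm.
#'
#' @param vol volume or 3D array.
#' @param threshold binarization intensity threshold, or `"otsu"`.
#' @param voxel_size voxel size (um) for bare arrays; must be isotropic.
#' @return object of class `bone_morphometry`: `BV_mm3`, `BS_mm2`,
#'   `BV_BS_mm`, `threshold`, `voxel_um`.
#' @export
bone_morphometry <- function(vol, threshold = "otsu", voxel_size = NULL) {
  a <- resolve_frame(vol)
  voxel_size <- resolve_voxel(vol, voxel_size)
  if (max(voxel_size) - min(voxel_size) > 1e-9 * max(voxel_size)) {
    stop("bone morphometry requires isotropic voxels")
  }
  v <- voxel_size[1L]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(a) else threshold
  m <- a > thr
  nf <- sum(m)
  if (nf == 0L) stop("empty foreground: BV = 0, BS undefined")
  faces <- count_exposed_faces(m)
  bv <- nf * (v * 1e-3)^3
  bs <- faces * (v * 1e-3)^2
  structure(list(BV_mm3 = bv, BS_mm2 = bs, BV_BS_mm = bv / bs,
                 threshold = thr, voxel_um = v, n_voxels = nf,
                 n_faces = faces),
            class = "bone_morphometry")
}

count_exposed_faces <- function(m) {
  d <- dim(m)
  faces <- 0L
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L)
    off[ax] <- 1L
    nb <- shift_arr(m, off, fill = FALSE) > 0   # neighbor below along ax
    nb2 <- shift_arr(m, -off, fill = FALSE) > 0 # neighbor above along ax
    faces <- faces + sum(m & !nb) + sum(m & !nb2)
  }
  faces
}

#' @export
print.bone_morphometry <- function(x, ...) {
  cat(sprintf("BV %.4g mm^3, BS %.4g mm^2, BV/BS %.4g mm (threshold %.3g)\n",
              x$BV_mm3, x$BS_mm2, x$BV_BS_mm, x$threshold))
  invisible(x)
}

#' Mirror a stack along one axis
#'
#' Contralateral femurs are measured at mirrored positions; flipping the
#' stack along the left-right axis before line placement lets one set of
#' line coordinates serve both sides.
#'
#' @param vol volume or 3D array.
#' @param axis axis to flip (1 = x).
#' @return the flipped array (or volume, matching the input).
#' @export
mirror_stack <- function(vol, axis = 1L) {
  flip <- function(a) {
    idx <- rev(seq_len(dim(a)[axis]))
    index_axis(a, axis, idx)
  }
  if (inherits(vol, "tlv")) {
    vol$channels <- lapply(vol$channels, function(ch) {
      for (tt in seq_len(dim(ch)[4L])) ch[, , , tt] <- flip(ch[, , , tt, drop = TRUE])
      ch
    })
    return(vol)
  }
  flip(vol)
}

#' Paired comparison of morphometric quantities
#'
#' Paired two-sided t-test per quantity between the implanted and the
#' contralateral femur.
#'
#' @param values_limb,values_contralateral numeric vectors (or data.frames
#'   of quantities) of equal length, paired by subject.
#' @return data.frame: `quantity`, `mean_limb`, `mean_contra`, `t`, `df`,
#'   `p_value`.
#' @export
paired_compare <- function(values_limb, values_contralateral) {
  if (is.numeric(values_limb)) {
    values_limb <- data.frame(value = values_limb)
    values_contralateral <- data.frame(value = values_contralateral)
  }
  stopifnot(identical(names(values_limb), names(values_contralateral)))
  if (nrow(values_limb) != nrow(values_contralateral)) {
    stop("paired comparison needs equal-length samples")
  }
  stopifnot(nrow(values_limb) >= 2L)
  out <- lapply(names(values_limb), function(q) {
    xa <- values_limb[[q]]
    xb <- values_contralateral[[q]]
    dd <- xa - xb
    if (sd(dd) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(dd) - 1),
                 p.value = if (mean(dd) == 0) 1 else 0)
    } else {
      tt <- t.test(xa, xb, paired = TRUE)
    }
    data.frame(quantity = q, mean_limb = mean(xa), mean_contra = mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
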