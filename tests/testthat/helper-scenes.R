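# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# analytic anisotropic Gaussian spot rendered at a sub-voxel position
render_gaussian_spot <- function(d, voxel, center, fwhm, amplitude = 1000,
                                 background = 0) {
  sig <- fwhm[c(1, 1, 2)] / (2 * sqrt(2 * log(2)))
  cx <- (seq_len(d[1]) - 0.5) * voxel[1]
  cy <- (seq_len(d[2]) - 0.5) * voxel[2]
  cz <- (seq_len(d[3]) - 0.5) * voxel[3]
  gx <- exp(-(cx - center[1])^2 / (2 * sig[1]^2))
  gy <- exp(-(cy - center[2])^2 / (2 * sig[2]^2))
  gz <- exp(-(cz - center[3])^2 / (2 * sig[3]^2))
  background + amplitude * outer(outer(gx, gy), gz)
}

# digital sphere mask (voxel-center convention)
sphere_mask <- function(d, voxel, center, radius) {
  cx <- (seq_len(d[1]) - 0.5) * voxel[1]
  cy <- (seq_len(d[2]) - 0.5) * voxel[2]
  cz <- (seq_len(d[3]) - 0.5) * voxel[3]
  array(outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
              (cz - center[3])^2, "+"), d) <= radius^2
}

# 6-connected binary dilation by one voxel
dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- s
      out <- out | (limbquant:::shift_arr(m, off, fill = FALSE) > 0)
    }
  }
  out
}

# Independent brute-force oracle for the remodeling statistic: plain
# voxel-by-voxel counting per 26-connected union component, written
# without reusing the package's partition logic.
brute_force_remodeling <- function(m0, m1, voxel) {
  vv <- prod(voxel)
  uni <- m0 | m1
  lab <- limbquant:::label3d(uni, 26L)
  out <- lapply(seq_len(max(lab)), function(comp) {
    idx <- which(lab == comp)
    n_app <- 0L; n_dis <- 0L; n_t1 <- 0L
    for (v in idx) {
      in0 <- m0[v]; in1 <- m1[v]
      if (in1) n_t1 <- n_t1 + 1L
      if (in1 && !in0) n_app <- n_app + 1L
      if (in0 && !in1) n_dis <- n_dis + 1L
    }
    data.frame(component = comp, V_t1 = n_t1 * vv, V_appear = n_app * vv,
               V_disappear = n_dis * vv,
               delta = if (n_t1 > 0) (n_app + n_dis) / n_t1 else NA_real_)
  })
  do.call(rbind, out)
}

# the printed toy fixture: one blob, 100 voxels at t0, 120 at t1, 90 shared
toy_masks_100_120_90 <- function() {
  d <- c(12, 20, 3)
  m0 <- array(FALSE, d)
  m1 <- array(FALSE, d)
  # shared core: 90 voxels (10 x 9 x 1)
  m0[2:11, 2:10, 2] <- TRUE
  m1[2:11, 2:10, 2] <- TRUE
  # t0-only: one extra row of 10 (total 100)
  m0[2:11, 11, 2] <- TRUE
  # t1-only: three extra rows of 10 (total 120)
  m1[2:11, 12:14, 2] <- TRUE
  list(t0 = m0, t1 = m1)
}
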