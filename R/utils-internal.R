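# Internal 3D image primitives. All operations honor anisotropic physical
# voxel sizes; arrays are indexed [x, y, z], voxel i has its center at
# (i - 0.5) * voxel_size (origin at the stack corner).

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derived from a single global seed.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) + 10007 * (h %% 104729)) %% 2147483629L)
}

voxel_volume <- function(voxel_size) prod(voxel_size)

# physical coordinates of voxel centers along one axis
axis_centers <- function(n, v) (seq_len(n) - 0.5) * v

gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox < 0.05) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

index_axis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable convolution along one axis with replicated (clamped) edges
conv_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(a * k)
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[j] * index_axis(a, axis, idx)
  }
  out
}

# separable anisotropic Gaussian blur; fwhm and voxel in micrometres (x,y,z)
blur3d <- function(a, fwhm_um, voxel_size) {
  fwhm_um <- rep(fwhm_um, length.out = 3L)
  sigma_vox <- (fwhm_um / (2 * sqrt(2 * log(2)))) / voxel_size
  for (axis in 1:3) {
    k <- gaussian_kernel1d(sigma_vox[axis])
    if (length(k) > 1L) a <- conv_axis(a, k, axis)
  }
  a
}

# ---- exact Euclidean distance transform (squared-parabola envelope) ----

dt1d <- function(f, w) {
  n <- length(f)
  x <- seq_len(n) * w
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(length(fin))
  z <- numeric(length(fin) + 1L)
  k <- 1L
  v[1L] <- fin[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(fin) > 1L) {
    isect <- function(q, p) {
      ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
    }
    for (q in fin[-1L]) {
      s <- isect(q, v[k])
      while (s <= z[k]) {
        k <- k - 1L
        s <- isect(q, v[k])
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    d[q] <- (x[q] - x[v[j]])^2 + f[v[j]]
  }
  d
}

dt_axis <- function(f, axis, w) {
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  m <- aperm(f, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1L])
  keep <- which(colSums(is.finite(m) & m > 0) > 0 | colSums(!is.finite(m)) > 0)
  for (jj in keep) m[, jj] <- dt1d(m[, jj], w)
  aperm(array(m, dm), order(perm))
}

# Euclidean distance (um) from every voxel to the nearest background voxel
# center; 0 on background. Foreground components that see no background in
# the grid get Inf.
edt3d <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L)
  f <- array(0, dim(mask))
  f[mask] <- Inf
  for (axis in 1:3) f <- dt_axis(f, axis, voxel_size[axis])
  sqrt(f)
}

# ---- connected-component labeling (6- or 26-connectivity) ----

neighbor_offsets <- function(connectivity = 26L, half = TRUE) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (half) {
    keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[keep, , drop = FALSE]
  }
  g
}

label3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  vox <- array(0L, d)
  vox[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity, half = TRUE)
  efrom <- integer(0)
  eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    np <- sweep(pos, 2L, offs[r, ], "+")
    ok <- np[, 1] >= 1L & np[, 1] <= d[1] &
      np[, 2] >= 1L & np[, 2] <= d[2] &
      np[, 3] >= 1L & np[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- (np[ok, 3] - 1L) * d[1] * d[2] + (np[ok, 2] - 1L) * d[1] + np[ok, 1]
    nid <- vox[nlin]
    hit <- nid > 0L
    efrom <- c(efrom, which(ok)[hit])
    eto <- c(eto, nid[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(efrom)) g <- igraph::add_edges(g, rbind(efrom, eto))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Fill 3D cavities: background components (6-connected) not touching the
# grid border become foreground.
fill_holes3d <- function(mask) {
  bg <- label3d(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  outside <- unique(bg[border & !mask])
  mask | (bg > 0L & !(bg %in% outside))
}

# ---- thresholding ----

otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# ---- local maxima (26-neighborhood, plateau-tolerant) ----

shift_arr <- function(a, off, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_max3d <- function(a) {
  offs <- neighbor_offsets(26L, half = FALSE)
  m <- array(-Inf, dim(a))
  for (r in seq_len(nrow(offs))) m <- pmax(m, shift_arr(a, offs[r, ]))
  m
}

local_maxima3d <- function(a, strict = FALSE) {
  nm <- neighbor_max3d(a)
  if (strict) a > nm else a >= nm
}

# greedy non-maximum suppression of candidate points by physical distance
nms_points <- function(pts, intensity, min_sep) {
  if (nrow(pts) == 0L) return(integer(0))
  ord <- order(intensity, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    dd <- sqrt(rowSums((pts[keep, , drop = FALSE] -
                          matrix(pts[i, ], length(keep), 3L, byrow = TRUE))^2))
    if (all(dd >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# ---- seeded watershed on a priority field (descending flood) ----

watershed3d <- function(priority, mask, seed_label = NULL) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  if (!is.null(seed_label)) lab[seed_label > 0L] <- seed_label[seed_label > 0L]
  ord <- idx[order(priority[idx], decreasing = TRUE)]
  offs <- neighbor_offsets(26L, half = FALSE)
  noff <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  pos <- arrayInd(ord, d)
  nextlab <- max(lab) + 1L
  for (i in seq_along(ord)) {
    v <- ord[i]
    if (lab[v] > 0L) next
    p <- pos[i, ]
    ok <- p[1] + offs[, 1] >= 1L & p[1] + offs[, 1] <= d[1] &
      p[2] + offs[, 2] >= 1L & p[2] + offs[, 2] <= d[2] &
      p[3] + offs[, 3] >= 1L & p[3] + offs[, 3] <= d[3]
    nb <- v + noff[ok]
    nl <- lab[nb]
    nb <- nb[nl > 0L]
    if (length(nb) == 0L) {
      lab[v] <- nextlab
      nextlab <- nextlab + 1L
    } else {
      lab[v] <- lab[nb[which.max(priority[nb])]]
    }
  }
  lab
}

# trilinear interpolation at physical points (n x 3 matrix, um)
trilinear_interp <- function(a, pts, voxel_size) {
  d <- dim(a)
  u <- sweep(pts, 2L, voxel_size, "/") + 0.5 # fractional voxel index
  u <- pmin(pmax(u, 1), matrix(d, nrow(pts), 3L, byrow = TRUE))
  i0 <- pmin(floor(u), matrix(d - 1L, nrow(pts), 3L, byrow = TRUE))
  fr <- u - i0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
      (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
      (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    lin <- (i0[, 3] + dz - 1) * d[1] * d[2] + (i0[, 2] + dy - 1) * d[1] +
      (i0[, 1] + dx)
    val <- val + w * a[lin]
  }
  val
}

fwhm_factor <- function() 2 * sqrt(2 * log(2))
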