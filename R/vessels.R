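# Vessel segmentation, local-thickness diameter mapping, and the
# diameter-stratified normalized volume-change remodeling statistic.

#' Segment the vessel channel of a 3D stack
#'
#' Gaussian smoothing, a global threshold (Otsu by default), removal of
#' connected components below a minimum physical volume, and filling of
#' fully enclosed holes.
#'
#' @param vol volume or 3D array (see [detect_beads()] for conventions).
#' @param smoothing_fwhm isotropic smoothing FWHM in um.
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_component minimum component volume in um^3.
#' @param voxel_size voxel size in um when `vol` is a bare array.
#' @param session_time optional session timestamp carried on the mask.
#' @return object of class `vessel_mask`: logical array `mask`,
#'   `voxel_size`, `session_time`.
#' @export
segment_vessels <- function(vol, smoothing_fwhm = 2.5, threshold = "otsu",
                            min_component = 100, voxel_size = NULL,
                            session_time = NA_real_) {
  a <- resolve_frame(vol)
  voxel_size <- resolve_voxel(vol, voxel_size)
  sm <- blur3d(a, rep(smoothing_fwhm, 3L), voxel_size)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else threshold
  m <- sm > thr
  if (!any(m)) {
    warning("segmentation produced an all-background mask")
    return(vessel_mask(m, voxel_size, session_time))
  }
  if (min_component > 0) {
    lab <- label3d(m, 26L)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * voxel_volume(voxel_size) < min_component)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  m <- fill_holes3d(m)
  vessel_mask(m, voxel_size, session_time)
}

#' Construct a vessel mask object
#' @param mask logical 3D array.
#' @param voxel_size voxel size (um).
#' @param session_time session timestamp.
#' @return object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, voxel_size, session_time = NA_real_) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask),
            length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size),
                 session_time = session_time), class = "vessel_mask")
}

#' Local vessel diameter map (maximal inscribed spheres)
#'
#' Local thickness in the Hildebrand-Ruegsegger sense: for every foreground
#' voxel, the diameter of the largest sphere that is inscribed in the
#' foreground and contains the voxel. Implemented from the exact Euclidean
#' distance transform with anisotropic physical spacing: candidate spheres
#' (radius = distance to the nearest background voxel center) are taken at
#' the distance ridge, spheres fully contained in an already accepted
#' larger sphere are discarded, and the accepted spheres are painted in
#' decreasing radius order. Components thinner than one voxel report one
#' voxel size, with a warning.
#'
#' @param mask a `vessel_mask` or logical 3D array.
#' @param voxel_size voxel size (um) for bare arrays.
#' @return object of class `diameter_map`: array `diameter` with local
#'   diameter in um on foreground voxels and `NA` elsewhere, plus
#'   `voxel_size`.
#' @export
local_diameter <- function(mask, voxel_size = NULL) {
  if (inherits(mask, "vessel_mask")) {
    voxel_size <- mask$voxel_size
    m <- mask$mask
  } else {
    stopifnot(!is.null(voxel_size))
    m <- mask
  }
  stopifnot(is.logical(m))
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  edt <- edt3d(m, voxel_size)
  r <- edt # inscribed-sphere radius per voxel
  r[!m] <- 0
  if (any(m & !is.finite(edt))) {
    # component without any background in the grid: clamp to grid extent
    r[m & !is.finite(edt)] <- max(d * voxel_size) / 2
  }
  # candidate sphere centers: distance-ridge voxels (plateau-tolerant local
  # maxima of the distance transform); spheres at non-ridge voxels are
  # contained in a ridge sphere, and every voxel keeps its own inscribed
  # sphere 2*r as a floor value below.
  ridge <- local_maxima3d(edt) & m
  idx <- which(ridge)
  ord <- idx[order(r[idx], decreasing = TRUE)]
  pos_all <- arrayInd(ord, d)
  phys <- sweep(pos_all - 0.5, 2L, voxel_size, "*")
  rr <- r[ord]
  # redundancy removal: sphere (y, ry) is redundant if contained in an
  # accepted sphere (c, rc), i.e. |y - c| + ry <= rc
  acc <- integer(0)
  n_acc <- 0L
  acc_pos <- matrix(NA_real_, 0L, 3L)
  acc_r <- numeric(0)
  for (i in seq_along(ord)) {
    if (n_acc > 0L) {
      dd <- sqrt((acc_pos[, 1] - phys[i, 1])^2 +
                   (acc_pos[, 2] - phys[i, 2])^2 +
                   (acc_pos[, 3] - phys[i, 3])^2)
      if (any(dd + rr[i] <= acc_r + 1e-9)) next
    }
    n_acc <- n_acc + 1L
    acc <- c(acc, i)
    acc_pos <- rbind(acc_pos, phys[i, ])
    acc_r <- c(acc_r, rr[i])
  }
  thick <- array(NA_real_, d)
  thick[m] <- 2 * r[m] # every voxel is covered at least by its own sphere
  cx <- axis_centers(d[1], voxel_size[1])
  cy <- axis_centers(d[2], voxel_size[2])
  cz <- axis_centers(d[3], voxel_size[3])
  for (j in seq_len(n_acc)) {
    ctr <- acc_pos[j, ]
    rad <- acc_r[j]
    lo <- pmax(1L, floor((ctr - rad) / voxel_size))
    hi <- pmin(d, ceiling((ctr + rad) / voxel_size))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    d2 <- array(outer(outer((cx[ix] - ctr[1])^2, (cy[iy] - ctr[2])^2, "+"),
                      (cz[iz] - ctr[3])^2, "+"), c(nx, ny, nz))
    inside <- d2 <= rad^2
    sub <- thick[ix, iy, iz, drop = FALSE]
    msub <- m[ix, iy, iz, drop = FALSE]
    upd <- inside & msub & (is.na(sub) | sub < 2 * rad)
    sub[upd] <- 2 * rad
    thick[ix, iy, iz] <- sub
  }
  lab <- label3d(m, 26L)
  comp_max_r <- tapply(r[m], lab[m], max)
  thin <- as.integer(names(comp_max_r)[comp_max_r <= min(voxel_size) + 1e-9])
  if (length(thin)) {
    warning("component(s) thinner than one voxel: diameter clamped to voxel size")
    sel <- m & array(lab %in% thin, d)
    thick[sel] <- min(voxel_size)
  }
  structure(list(diameter = thick, voxel_size = as.numeric(voxel_size)),
            class = "diameter_map")
}

#' Pair two vessel sessions into appearance / disappearance partitions
#'
#' Optionally registers the later mask to the earlier one by the integer
#' voxel translation maximizing the binary cross-correlation (computed via
#' FFT), then partitions the voxels into appearance (in t1 but not t0) and
#' disappearance (in t0 but not t1).
#'
#' @param mask_t0,mask_t1 `vessel_mask` objects (or logical arrays with
#'   `voxel_size`) on matching grids.
#' @param registration `"none"` or `"translation"`.
#' @param max_shift maximum translation searched, in voxels per axis.
#' @param voxel_size voxel size (um) for bare arrays.
#' @return object of class `vessel_pair`: `t0`, `t1` (registered),
#'   `appearance`, `disappearance` logical arrays, `shift` (voxels),
#'   `voxel_size`.
#' @export
pair_sessions <- function(mask_t0, mask_t1, registration = c("none", "translation"),
                          max_shift = 10L, voxel_size = NULL) {
  registration <- match.arg(registration)
  get_mask <- function(x) if (inherits(x, "vessel_mask")) x$mask else x
  m0 <- get_mask(mask_t0)
  m1 <- get_mask(mask_t1)
  if (inherits(mask_t0, "vessel_mask")) voxel_size <- mask_t0$voxel_size
  stopifnot(!is.null(voxel_size))
  if (!identical(dim(m0), dim(m1))) stop("session grids do not match")
  shift <- c(0L, 0L, 0L)
  if (registration == "translation" && any(m0) && any(m1)) {
    shift <- best_shift(m0, m1, max_shift)
    m1 <- shift_arr(m1, shift, fill = FALSE) > 0
  }
  structure(list(t0 = m0, t1 = m1, appearance = m1 & !m0,
                 disappearance = m0 & !m1, shift = shift,
                 voxel_size = as.numeric(voxel_size)),
            class = "vessel_pair")
}

# integer shift of b that maximizes sum(a & shifted b), via FFT correlation
best_shift <- function(a, b, max_shift) {
  d <- dim(a)
  fa <- fft(array(as.numeric(a), d))
  fb <- fft(array(as.numeric(b), d))
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / prod(d)
  # circular lag k means b shifted by +k aligns with a
  lags <- lapply(d, function(n) {
    l <- seq_len(n) - 1L
    ifelse(l > n / 2, l - n, l)
  })
  ok <- array(outer(outer(abs(lags[[1]]) <= max_shift,
                          abs(lags[[2]]) <= max_shift, "&"),
                    abs(lags[[3]]) <= max_shift, "&"), d)
  cc[!ok] <- -Inf
  w <- arrayInd(which.max(cc), d)
  as.integer(c(lags[[1]][w[1]], lags[[2]][w[2]], lags[[3]][w[3]]))
}

#' Normalized volume-change remodeling statistic per vessel
#'
#' Vessels are the 26-connected components of the union of both sessions'
#' masks. Each component is assigned a diameter class from the median local
#' diameter over its session-1 voxels (half-open bins; components with a
#' median diameter below the first edge are excluded). The per-vessel
#' statistic is the symmetric-difference volume (appearance plus
#' disappearance, in um^3) divided by the vessel's volume at the later
#' session. A signed variant `(V_appear - V_disappear) / V_t1` is available
#' via `signed = TRUE`.
#'
#' @param pair a [pair_sessions()] result.
#' @param dmap_t1 a [local_diameter()] map of the session-1 mask; computed
#'   on demand when `NULL`.
#' @param class_edges increasing numeric diameter-class edges in um; the
#'   default `c(5, 15, 35)` defines small (5-15), mid (15-35) and large
#'   (>35 um) classes.
#' @param signed report the signed volume change instead of the magnitude.
#' @return object of class `remodeling_result`: `records` data.frame
#'   (component, class, diameter_t1, V_t1, V_appear, V_disappear,
#'   delta_norm in um^3 / dimensionless), `by_class` summary (mean, sd, n),
#'   `n_fully_disappeared` (components absent at session 1, excluded from
#'   means), `n_below_min_diameter`.
#' @export
remodeling_statistic <- function(pair, dmap_t1 = NULL,
                                 class_edges = c(5, 15, 35), signed = FALSE) {
  stopifnot(inherits(pair, "vessel_pair"), length(class_edges) >= 1L,
            !is.unsorted(class_edges))
  vv <- voxel_volume(pair$voxel_size)
  uni <- pair$t0 | pair$t1
  if (!any(uni)) {
    stop("both sessions are empty")
  }
  if (is.null(dmap_t1)) {
    dmap_t1 <- if (any(pair$t1)) local_diameter(pair$t1, pair$voxel_size) else
      NULL
  }
  lab <- label3d(uni, 26L)
  ncomp <- max(lab)
  class_names <- c("small", "mid", "large")[seq_len(min(3L, length(class_edges)))]
  if (length(class_edges) != 3L) {
    class_names <- paste0("class", seq_along(class_edges))
  }
  rec <- data.frame(component = seq_len(ncomp), class = NA_character_,
                    diameter_t1 = NA_real_, V_t1 = NA_real_,
                    V_appear = NA_real_, V_disappear = NA_real_,
                    delta_norm = NA_real_, stringsAsFactors = FALSE)
  lab_v <- as.integer(lab)
  t1_v <- as.logical(pair$t1)
  app_v <- as.logical(pair$appearance)
  dis_v <- as.logical(pair$disappearance)
  dm_v <- if (!is.null(dmap_t1)) as.numeric(dmap_t1$diameter) else
    rep(NA_real_, length(lab_v))
  for (comp in seq_len(ncomp)) {
    in_c <- lab_v == comp
    v1 <- sum(in_c & t1_v) * vv
    va <- sum(in_c & app_v) * vv
    vd <- sum(in_c & dis_v) * vv
    med_d <- if (v1 > 0) median(dm_v[in_c & t1_v], na.rm = TRUE) else NA_real_
    rec$V_t1[comp] <- v1
    rec$V_appear[comp] <- va
    rec$V_disappear[comp] <- vd
    rec$diameter_t1[comp] <- med_d
    if (v1 > 0) {
      rec$delta_norm[comp] <- if (signed) (va - vd) / v1 else (va + vd) / v1
      # half-open bins [e1, e2), [e2, e3), [e_last, Inf)
      cl <- findInterval(med_d, class_edges)
      rec$class[comp] <- if (cl >= 1L) class_names[cl] else NA_character_
    }
  }
  n_gone <- sum(rec$V_t1 == 0)
  n_small <- sum(rec$V_t1 > 0 & is.na(rec$class))
  keep <- !is.na(rec$class)
  by_class <- do.call(rbind, lapply(class_names, function(cl) {
    x <- rec$delta_norm[keep & rec$class == cl]
    data.frame(class = cl, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) sd(x) else NA_real_)
  }))
  structure(list(records = rec, by_class = by_class,
                 n_fully_disappeared = n_gone,
                 n_below_min_diameter = n_small,
                 class_edges = class_edges, signed = signed),
            class = "remodeling_result")
}

#' @export
print.remodeling_result <- function(x, ...) {
  cat(sprintf("Vessel remodeling: %d component(s), %d fully disappeared, %d below minimum diameter\n",
              nrow(x$records), x$n_fully_disappeared, x$n_below_min_diameter))
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA of the remodeling statistic across diameter classes
#'
#' Tests whether the normalized volume change differs between diameter
#' classes, with Bonferroni-corrected pairwise follow-up comparisons.
#' Classes with fewer than two records are dropped with a warning.
#'
#' @param records a `remodeling_result` or its `records` data.frame (needs
#'   columns `class` and `delta_norm`).
#' @return list of class `class_comparison`: `F`, `df`, `p_value`,
#'   `pairwise` (Bonferroni-adjusted p-value matrix), `n_per_class`.
#' @export
compare_classes <- function(records) {
  if (inherits(records, "remodeling_result")) records <- records$records
  df <- records[!is.na(records$class) & !is.na(records$delta_norm), ,
                drop = FALSE]
  cnt <- table(df$class)
  drop <- names(cnt)[cnt < 2L]
  if (length(drop)) {
    warning("dropping class(es) with fewer than 2 records: ",
            paste(drop, collapse = ", "))
    df <- df[!(df$class %in% drop), , drop = FALSE]
  }
  if (length(unique(df$class)) < 2L) {
    stop("need at least two classes with >= 2 records")
  }
  df$class <- factor(df$class)
  fit <- aov(delta_norm ~ class, data = df)
  s <- summary(fit)[[1L]]
  pw <- pairwise.t.test(df$delta_norm, df$class, p.adjust.method = "bonferroni")
  structure(list(F = s[["F value"]][1L], df = s[["Df"]],
                 p_value = s[["Pr(>F)"]][1L], pairwise = pw$p.value,
                 n_per_class = table(df$class)),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA across diameter classes: F(%d, %d) = %.3g, p = %.3g\n",
              x$df[1L], x$df[2L], x$F, x$p_value))
  invisible(x)
}
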