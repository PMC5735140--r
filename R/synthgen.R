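#' Scene configuration for synthetic acquisitions
#'
#' Holds the acquisition geometry and noise model of a synthetic scene. The
#' defaults reproduce the microendoscopic acquisition settings: a circular
#' 280-um field of view inside a 350 x 350 um^2 frame sampled at
#' 507 x 507 pixels (0.69 um pixel pitch, rounded to 0.7 um), 70-um z-stacks
#' with a 6-um step, one stack every 30 s for 45 min, and a point spread
#' function of 0.8 um FWHM laterally and 5.2 um axially.
#'
#' @param fov_diameter diameter (um) of the circular endoscopic field of
#'   view; voxels outside it carry only background. Must not exceed the
#'   smaller lateral extent.
#' @param volume_extent numeric length-3 physical extent (x, y, z) in um.
#' @param voxel_size numeric length-3 voxel size (x, y, z) in um.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames.
#' @param psf_fwhm numeric length-2, lateral and axial PSF FWHM in um.
#' @param snr_target dimensionless target signal-to-noise ratio; the signal
#'   amplitude is scaled to `snr_target` times the background standard
#'   deviation `sqrt(background + read_noise_sd^2)`.
#' @param background mean background photon count per voxel.
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (counts).
#' @param seed integer seed; a fixed seed makes the generated scene
#'   byte-identical across runs.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(fov_diameter = 280,
                         volume_extent = c(350, 350, 70),
                         voxel_size = c(0.7, 0.7, 6),
                         frame_interval = 30,
                         n_frames = 90,
                         psf_fwhm = c(0.8, 5.2),
                         snr_target = 10,
                         background = 20,
                         read_noise_sd = 3,
                         seed = 1L) {
  stopifnot(all(volume_extent > 0), all(voxel_size > 0),
            fov_diameter > 0, fov_diameter <= min(volume_extent[1:2]),
            frame_interval > 0, n_frames >= 1,
            length(psf_fwhm) == 2L, all(psf_fwhm > 0),
            snr_target > 0, background >= 0, read_noise_sd >= 0)
  structure(list(fov_diameter = fov_diameter,
                 volume_extent = as.numeric(volume_extent),
                 voxel_size = as.numeric(voxel_size),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 psf_fwhm = as.numeric(psf_fwhm),
                 snr_target = snr_target,
                 background = background,
                 read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default scene geometry for static vessel-remodeling sessions
#'
#' Vessel remodeling is quantified on static per-session stacks rather than
#' a 30-s movie, so the default vessel scene trades temporal sampling for
#' isotropic 2-um voxels (small vessels of 5-15 um diameter are otherwise
#' undersampled along z at the 6-um movie step).
#'
#' @param ... overrides passed to [scene_config()].
#' @return a `scene_config`.
#' @export
vessel_scene_config <- function(...) {
  args <- list(fov_diameter = 200, volume_extent = c(200, 200, 80),
               voxel_size = c(2, 2, 2), frame_interval = 86400,
               n_frames = 2L)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

#' Default scene geometry for cell-motility movies
#' @param ... overrides passed to [scene_config()].
#' @return a `scene_config`.
#' @export
cell_scene_config <- function(...) {
  args <- list(fov_diameter = 150, volume_extent = c(150, 150, 60),
               voxel_size = c(2, 2, 3), frame_interval = 30, n_frames = 40L)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

#' Default scene geometry for photoactivation session series
#' @param ... overrides passed to [scene_config()].
#' @return a `scene_config`.
#' @export
photoact_scene_config <- function(...) {
  args <- list(fov_diameter = 200, volume_extent = c(200, 200, 60),
               voxel_size = c(2, 2, 6), frame_interval = 30, n_frames = 5L)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

# ---- shared rendering helpers ----

grid_dims <- function(config) {
  pmax(1L, as.integer(round(config$volume_extent / config$voxel_size)))
}

# logical mask of the circular endoscopic field of view (x-y plane)
fov_mask <- function(config) {
  d <- grid_dims(config)
  cx <- config$volume_extent[1] / 2
  cy <- config$volume_extent[2] / 2
  x <- axis_centers(d[1], config$voxel_size[1])
  y <- axis_centers(d[2], config$voxel_size[2])
  m2 <- outer(x - cx, y - cy, function(a, b) a^2 + b^2) <=
    (config$fov_diameter / 2)^2
  array(rep(m2, d[3]), d)
}

# paint a capsule (cylinder with hemispherical caps) into a logical array;
# p1, p2 in um, radius in um. A voxel is foreground if its center lies
# within `radius` of the segment.
paint_capsule <- function(mask, p1, p2, radius, voxel_size) {
  d <- dim(mask)
  lo <- pmax(1L, floor((pmin(p1, p2) - radius) / voxel_size - 0.5) + 1L)
  hi <- pmin(d, ceiling((pmax(p1, p2) + radius) / voxel_size + 0.5))
  if (any(lo > hi)) return(mask)
  xs <- axis_centers(d[1], voxel_size[1])[lo[1]:hi[1]]
  ys <- axis_centers(d[2], voxel_size[2])[lo[2]:hi[2]]
  zs <- axis_centers(d[3], voxel_size[3])[lo[3]:hi[3]]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  v <- p2 - p1
  vv <- sum(v^2)
  if (vv == 0) {
    d2 <- (px - p1[1])^2 + (py - p1[2])^2 + (pz - p1[3])^2
  } else {
    t0 <- ((px - p1[1]) * v[1] + (py - p1[2]) * v[2] + (pz - p1[3]) * v[3]) / vv
    t0 <- pmin(pmax(t0, 0), 1)
    d2 <- (px - p1[1] - t0 * v[1])^2 + (py - p1[2] - t0 * v[2])^2 +
      (pz - p1[3] - t0 * v[3])^2
  }
  sub <- array(d2 <= radius^2, c(nx, ny, nz))
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | sub
  mask
}

paint_sphere <- function(mask, center, radius, voxel_size) {
  paint_capsule(mask, center, center, radius, voxel_size)
}

# signal amplitude meeting the configured SNR given the background model
signal_amplitude <- function(config) {
  config$snr_target * sqrt(config$background + config$read_noise_sd^2)
}

# Poisson shot noise on the photon signal plus Gaussian read noise.
# lambda is the noiseless expected count field (background included).
apply_noise <- function(lambda, read_noise_sd) {
  n <- length(lambda)
  noisy <- rpois(n, lambda)
  if (read_noise_sd > 0) noisy <- noisy + rnorm(n, 0, read_noise_sd)
  array(noisy, dim(lambda))
}

# render a label field into a noisy photon-count stack
render_channel <- function(label, config, noise = TRUE) {
  sig <- blur3d(label * signal_amplitude(config), config$psf_fwhm[c(1, 1, 2)],
                config$voxel_size)
  sig <- sig * fov_mask(config)
  lambda <- config$background + sig
  if (noise) apply_noise(lambda, config$read_noise_sd) else lambda
}

# ---- vessel remodeling scenes ----

#' Generate a synthetic vessel-remodeling scene with known ground truth
#'
#' Renders a pair of imaging sessions of a bone-marrow-like vascular bed:
#' straight tubes (capsules) of three diameter classes, each of which
#' remodels between the sessions by exchanging a class-specific fraction of
#' its volume. Remodeling is realized as two disjoint interior slabs per
#' vessel: one present only at session 0 (disappearance) and one present
#' only at session 1 (appearance), so that each vessel's expected
#' normalized volume change (symmetric difference over the session-1
#' volume) equals the configured class rate. The noiseless label fields are
#' convolved with the anisotropic Gaussian PSF, Poisson shot noise plus
#' Gaussian read noise is added, and voxels outside the circular field of
#' view carry only background.
#'
#' @param config a [scene_config()]; defaults to [vessel_scene_config()].
#' @param remodel_rates named numeric: target normalized volume change per
#'   interval for the `small` (5-15 um), `mid` (15-35 um) and `large`
#'   (>35 um) diameter classes.
#' @param n_per_class integer length-3: vessels per class.
#' @param diameter_ranges list of length-2 numeric ranges (um) the class
#'   diameters are drawn from; the defaults keep at least one voxel of
#'   margin to the 5 / 15 / 35 um class edges, matching the one-voxel
#'   accuracy of the diameter measurement.
#' @param noise logical; `FALSE` returns the noiseless expected counts.
#' @param seed integer; overrides `config$seed`.
#' @param noise_seed optional integer decoupling the noise realization
#'   from the scene geometry: the same `seed` with different `noise_seed`
#'   values renders the identical vessel bed under independent noise.
#' @return list with `volume` (a [time_lapse_volume()] with channel
#'   `vessels`, frames = sessions), `truth` (data.frame: vessel id, class,
#'   diameter um, true normalized volume change recomputed from the
#'   noiseless label masks), and `labels` (list of two logical ground-truth
#'   masks).
#' @export
generate_vessel_scene <- function(config = vessel_scene_config(),
                                  remodel_rates = c(small = 0.4, mid = 0.15,
                                                    large = 0.05),
                                  n_per_class = c(2L, 2L, 1L),
                                  diameter_ranges = list(small = c(7, 13),
                                                         mid = c(17, 30),
                                                         large = c(38, 46)),
                                  noise = TRUE,
                                  seed = NULL, noise_seed = NULL) {
  stopifnot(inherits(config, "scene_config"),
            all(c("small", "mid", "large") %in% names(remodel_rates)),
            all(remodel_rates >= 0), length(n_per_class) == 3L)
  min_diam <- min(unlist(diameter_ranges))
  if (max(config$voxel_size) > min_diam) {
    stop("undersampled scene: voxel size exceeds the smallest vessel diameter")
  }
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, "vessel_scene"), {
    d <- grid_dims(config)
    ext <- config$volume_extent
    classes <- rep(c("small", "mid", "large"), times = n_per_class)
    nv <- length(classes)
    diams <- vapply(classes, function(cl) {
      r <- diameter_ranges[[cl]]
      runif(1, r[1], r[2])
    }, numeric(1))
    # wide vessels go to central slots (clear of the circular FOV edge and
    # of the grid walls); per vessel the axial (z) plane is chosen greedily
    # to maximize surface clearance to already placed tubes.
    slots_by_centrality <- order(abs(seq_len(nv) - (nv + 1) / 2))
    ord <- order(diams, decreasing = TRUE)
    slot <- integer(nv)
    slot[ord] <- slots_by_centrality
    spacing <- 0.9 * ext[1] / nv
    xpos <- ext[1] / 2 + (slot - (nv + 1) / 2) * spacing
    z_cands <- c(0.5, 0.23, 0.77) * ext[3]
    zpos <- numeric(nv)
    for (i in ord) {
      placed <- ord[seq_len(which(ord == i) - 1L)]
      clearance <- vapply(z_cands, function(zc) {
        if (!length(placed)) return(Inf)
        min(sqrt((xpos[placed] - xpos[i])^2 + (zpos[placed] - zc)^2) -
              (diams[placed] + diams[i]) / 2)
      }, numeric(1))
      zpos[i] <- z_cands[which.max(clearance)]
    }
    tube_len <- 0.48 * ext[2]
    # every tube must lie fully inside the circular field of view
    r_fov <- config$fov_diameter / 2
    corner <- sqrt((abs(xpos - ext[1] / 2) + diams / 2)^2 + (tube_len / 2)^2)
    if (any(corner > r_fov)) {
      stop("scene layout does not fit inside the field of view; ",
           "reduce vessel count or diameters, or enlarge the FOV")
    }
    n_seg <- 48L
    seg_len <- tube_len / n_seg
    truth <- data.frame(vessel = seq_len(nv), class = classes,
                        diameter = diams, rate = remodel_rates[classes],
                        delta_true = NA_real_, stringsAsFactors = FALSE)
    fm <- fov_mask(config)
    lab0 <- array(FALSE, d)
    lab1 <- array(FALSE, d)
    for (i in seq_len(nv)) {
      r <- diams[i] / 2
      y0 <- ext[2] / 2 - tube_len / 2
      p1 <- c(xpos[i], y0, zpos[i])
      p2 <- c(xpos[i], y0 + tube_len, zpos[i])
      full <- array(FALSE, d)
      full <- paint_capsule(full, p1, p2, r, config$voxel_size)
      # slab fraction per session: delta = 2f/(1-f)  =>  f = rate/(2+rate);
      # the hemispherical end caps add volume outside the segmented shaft,
      # so the segment count is scaled by the cap-equivalent length
      f <- remodel_rates[classes[i]] / (2 + remodel_rates[classes[i]])
      kf <- f * (n_seg + (4 * r / 3) / seg_len)
      k <- floor(kf) + (runif(1) < kf - floor(kf)) # unbiased rounding
      if (k > 0L) {
        # two disjoint runs of k segments, kept away from the tube ends so
        # that neither run is clipped by the circular field of view
        win <- floor(n_seg / 6L):(n_seg - floor(n_seg / 6L) - k)
        s0 <- sample(win, 1L)
        win2 <- setdiff(win, (s0 - k - 1L):(s0 + k + 1L))
        s1 <- if (length(win2)) sample(win2, 1L) else s0
        ymid <- axis_centers(d[2], config$voxel_size[2])
        in_run <- function(s) {
          ymid >= y0 + s * seg_len & ymid < y0 + (s + k) * seg_len
        }
        cut0 <- in_run(s0) # disappears after session 0
        cut1 <- in_run(s1) # appears at session 1
        m0 <- full
        m0[, cut1, ] <- FALSE
        m1 <- full
        m1[, cut0, ] <- FALSE
      } else {
        m0 <- m1 <- full
      }
      m0 <- m0 & fm
      m1 <- m1 & fm
      v1 <- sum(m1)
      truth$delta_true[i] <- if (v1 > 0) sum(xor(m0, m1)) / v1 else NA_real_
      lab0 <- lab0 | m0
      lab1 <- lab1 | m1
    }
    ch <- array(0, c(d, 2L))
    render_both <- function() {
      ch[, , , 1L] <<- render_channel(lab0, config, noise = noise)
      ch[, , , 2L] <<- render_channel(lab1, config, noise = noise)
    }
    if (is.null(noise_seed)) render_both() else
      withr::with_seed(derive_seed(noise_seed, "vessel_noise"), render_both())
    vol <- time_lapse_volume(list(vessels = ch), config$voxel_size,
                             frame_interval = config$frame_interval,
                             time_unit = "s",
                             meta = list(scene = "vessels", seed = seed))
    list(volume = vol, truth = truth, labels = list(t0 = lab0, t1 = lab1))
  })
}

# ---- cell motility scenes ----

#' Generate a synthetic B-lineage cell movie with known trajectories
#'
#' B cells (volume < 500 um^3) move by a persistent random walk at a
#' configured speed; plasma cells (volume > 500 um^3) show confined jitter
#' around a fixed niche position. Cells are rendered as spheres of their
#' configured volume, frame by frame at the configured interval.
#'
#' @param config a [scene_config()]; defaults to [cell_scene_config()].
#' @param n_b,n_pc number of B cells and plasma cells.
#' @param motion list: `b_speed` (um/min), `b_persistence` (direction
#'   correlation in [0,1]), `pc_speed` (um/min), `pc_confinement` (um
#'   confinement radius for plasma cells).
#' @param volume_ranges list of length-2 ranges (um^3) for B and plasma
#'   cell volumes; must respect the 500 um^3 class boundary.
#' @param render logical; `FALSE` skips image rendering (trajectories only).
#' @param noise logical noise switch for rendered frames.
#' @param seed integer; overrides `config$seed`.
#' @return list with `volume` (channel `cells`, or `NULL` when
#'   `render = FALSE`) and `truth`: `cells` (id, class, volume um^3) and
#'   `tracks` (id, frame, t_s, x, y, z in um).
#' @export
generate_cell_scene <- function(config = cell_scene_config(),
                                n_b = 20L, n_pc = 10L,
                                motion = list(b_speed = 4, b_persistence = 0.8,
                                              pc_speed = 0.5,
                                              pc_confinement = 3),
                                volume_ranges = list(b = c(150, 450),
                                                     pc = c(600, 1500)),
                                render = TRUE, noise = TRUE, seed = NULL) {
  stopifnot(inherits(config, "scene_config"), n_b >= 0L, n_pc >= 0L)
  stopifnot(max(volume_ranges$b) < 500, min(volume_ranges$pc) > 500)
  dt_min <- config$frame_interval / 60
  if (max(motion$b_speed, motion$pc_speed) * dt_min >
      min(config$volume_extent) / 2) {
    stop("requested speed per frame exceeds half the volume extent")
  }
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, "cell_scene"), {
    d <- grid_dims(config)
    ext <- config$volume_extent
    nt <- config$n_frames
    n <- n_b + n_pc
    cls <- rep(c("B cell", "plasma cell"), c(n_b, n_pc))
    vols <- c(runif(n_b, volume_ranges$b[1], volume_ranges$b[2]),
              runif(n_pc, volume_ranges$pc[1], volume_ranges$pc[2]))
    radii <- (3 * vols / (4 * pi))^(1 / 3)
    margin <- radii + 2
    pos <- t(vapply(seq_len(n), function(i) {
      c(runif(1, margin[i], ext[1] - margin[i]),
        runif(1, margin[i], ext[2] - margin[i]),
        runif(1, margin[i], ext[3] - margin[i]))
    }, numeric(3)))
    if (n == 0L) pos <- matrix(numeric(0), 0L, 3L)
    tracks <- vector("list", n)
    rand_dir <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    }
    for (i in seq_len(n)) {
      p <- pos[i, ]
      traj <- matrix(NA_real_, nt, 3L)
      traj[1L, ] <- p
      if (cls[i] == "B cell") {
        step <- motion$b_speed * dt_min
        dir <- rand_dir()
        if (nt > 1L) for (tt in 2:nt) {
          dir <- motion$b_persistence * dir +
            (1 - motion$b_persistence) * rand_dir()
          nd <- sqrt(sum(dir^2))
          dir <- if (nd > 0) dir / nd else rand_dir()
          p_new <- p + step * dir
          # reflect at the walls, preserving the step length
          for (ax in 1:3) {
            lo <- margin[i]; hi <- ext[ax] - margin[i]
            if (p_new[ax] < lo) {
              p_new[ax] <- 2 * lo - p_new[ax]
              dir[ax] <- -dir[ax]
            }
            if (p_new[ax] > hi) {
              p_new[ax] <- 2 * hi - p_new[ax]
              dir[ax] <- -dir[ax]
            }
            p_new[ax] <- min(max(p_new[ax], lo), hi)
          }
          p <- p_new
          traj[tt, ] <- p
        }
      } else {
        anchor <- p
        sdj <- motion$pc_confinement / 2
        step <- motion$pc_speed * dt_min
        if (nt > 1L) for (tt in 2:nt) {
          prop <- anchor + pmin(pmax(rnorm(3, 0, sdj), -motion$pc_confinement),
                                motion$pc_confinement)
          dirv <- prop - p
          nd <- sqrt(sum(dirv^2))
          if (nd > step) prop <- p + dirv / nd * step
          traj[tt, ] <- prop
          p <- prop
        }
        if (motion$pc_speed == 0) traj[] <- rep(anchor, each = nt)
      }
      if (motion$b_speed == 0 && cls[i] == "B cell") {
        traj[] <- rep(traj[1L, ], each = nt)
      }
      tracks[[i]] <- data.frame(id = i, frame = seq_len(nt),
                                t_s = (seq_len(nt) - 1L) * config$frame_interval,
                                x = traj[, 1], y = traj[, 2], z = traj[, 3])
    }
    truth <- list(cells = data.frame(id = seq_len(n), class = cls,
                                     volume = vols, stringsAsFactors = FALSE),
                  tracks = if (n) do.call(rbind, tracks) else
                    data.frame(id = integer(0), frame = integer(0),
                               t_s = numeric(0), x = numeric(0),
                               y = numeric(0), z = numeric(0)))
    vol_out <- NULL
    if (render) {
      ch <- array(0, c(d, nt))
      for (tt in seq_len(nt)) {
        lab <- array(FALSE, d)
        for (i in seq_len(n)) {
          lab <- paint_sphere(lab, as.numeric(tracks[[i]][tt, c("x", "y", "z")]),
                              radii[i], config$voxel_size)
        }
        ch[, , , tt] <- render_channel(lab, config, noise = noise)
      }
      vol_out <- time_lapse_volume(list(cells = ch), config$voxel_size,
                                   frame_interval = config$frame_interval,
                                   meta = list(scene = "cells", seed = seed))
    }
    list(volume = vol_out, truth = truth)
  })
}

# ---- photoactivation scenes ----

#' Generate a synthetic photoactivation session series
#'
#' Emulates photoactivatable-GFP labeling: a pre-activation frame at
#' baseline intensity, then post-activation sessions in which a central
#' cuboid ROI starts at `fold_increase` times baseline and decays
#' exponentially through protein turnover and emigration of labeled motile
#' cells out of the region.
#'
#' @param config a [scene_config()]; defaults to [photoact_scene_config()].
#' @param roi_extent numeric length-3 ROI extent (x, y, z) in um, centered
#'   in the field of view (default the 75 x 75 x 30 um^3 activation volume).
#' @param fold_increase dimensionless post/pre intensity ratio at t = 0
#'   (default 100); must be >= 1.
#' @param turnover_rate exponential label-turnover rate, per hour.
#' @param emigration_fraction exponential loss rate through emigration of
#'   motile labeled cells, per hour.
#' @param session_times_h post-activation imaging times in hours.
#' @param noise logical noise switch.
#' @param seed integer; overrides `config$seed`.
#' @return list with `volume` (channel `paGFP`; frame 1 = pre-activation,
#'   then one frame per session; timestamps in hours) and `truth` (baseline,
#'   fold increase, decay rate per hour, ROI bounds in um, pre-frame index).
#' @export
generate_photoactivation_scene <- function(config = photoact_scene_config(),
                                           roi_extent = c(75, 75, 30),
                                           fold_increase = 100,
                                           turnover_rate = 0,
                                           emigration_fraction = 0,
                                           session_times_h = c(0, 12, 24, 36),
                                           noise = FALSE, seed = NULL) {
  stopifnot(inherits(config, "scene_config"), length(roi_extent) == 3L)
  if (fold_increase < 1) stop("fold_increase must be >= 1")
  if (any(roi_extent > config$volume_extent)) {
    stop("ROI does not fit inside the volume")
  }
  stopifnot(all(diff(session_times_h) > 0), all(session_times_h >= 0))
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, "photoact_scene"), {
    d <- grid_dims(config)
    ext <- config$volume_extent
    lo <- (ext - roi_extent) / 2
    hi <- lo + roi_extent
    roi <- list(lo = lo, hi = hi)
    cent <- lapply(1:3, function(ax) axis_centers(d[ax], config$voxel_size[ax]))
    in_roi <- array(outer(outer(cent[[1]] >= lo[1] & cent[[1]] <= hi[1],
                                cent[[2]] >= lo[2] & cent[[2]] <= hi[2], "&"),
                          cent[[3]] >= lo[3] & cent[[3]] <= hi[3], "&"), d)
    baseline <- config$background
    rate <- turnover_rate + emigration_fraction
    nt <- length(session_times_h) + 1L
    ch <- array(0, c(d, nt))
    fm <- fov_mask(config)
    make_frame <- function(roi_level) {
      lam <- array(baseline, d)
      lam[in_roi] <- roi_level
      lam[!fm] <- baseline
      if (noise) apply_noise(lam, config$read_noise_sd) else lam
    }
    ch[, , , 1L] <- make_frame(baseline)
    for (s in seq_along(session_times_h)) {
      lvl <- baseline * fold_increase * exp(-rate * session_times_h[s])
      ch[, , , s + 1L] <- make_frame(lvl)
    }
    vol <- time_lapse_volume(list(paGFP = ch), config$voxel_size,
                             timestamps = c(0, session_times_h),
                             time_unit = "h",
                             meta = list(scene = "photoact", seed = seed,
                                         pre_frame = 1L))
    list(volume = vol,
         truth = list(baseline = baseline, fold_increase = fold_increase,
                      decay_rate_per_h = rate, roi = roi, pre_frame = 1L,
                      session_times_h = session_times_h))
  })
}

# ---- micro-CT phantoms ----

#' Generate a micro-CT phantom of two parallel cortical walls
#'
#' The cross-line intensity profile perpendicular to the walls is the sum
#' of two Gaussians whose full widths at half maximum equal the requested
#' wall thicknesses, matching the intensity-profile model used for cortical
#' thickness measurement.
#'
#' @param wall_thicknesses numeric length-2, wall FWHMs (w1, w2) in um.
#' @param wall_separation center-to-center wall distance in um; must exceed
#'   `w1 + w2`.
#' @param voxel isotropic voxel size in um (default 10.5); refused when
#'   larger than half the thinnest wall.
#' @param noise_sd Gaussian noise s.d. in intensity units.
#' @param amplitude peak intensity of each wall.
#' @param lateral_extent extent (um) of the phantom in the two in-wall axes.
#' @param seed integer seed for the noise.
#' @return list with `volume` (a [time_lapse_volume()], channel `ct`, walls
#'   perpendicular to x) and `truth` (wall centers um, FWHMs um, sigma um,
#'   amplitude).
#' @export
generate_ct_phantom <- function(wall_thicknesses = c(200, 250),
                                wall_separation = 1500,
                                voxel = 10.5, noise_sd = 0,
                                amplitude = 100,
                                lateral_extent = 220, seed = 1L) {
  w <- wall_thicknesses
  stopifnot(length(w) == 2L, all(w > 0), wall_separation > sum(w))
  if (voxel > min(w) / 2) stop("voxel size too coarse for the thinnest wall")
  margin <- 2 * max(w)
  len_x <- wall_separation + 2 * margin
  d <- c(round(len_x / voxel), round(lateral_extent / voxel),
         round(lateral_extent / voxel))
  x <- axis_centers(d[1], voxel)
  c1 <- margin
  c2 <- margin + wall_separation
  sig <- w / fwhm_factor()
  prof <- amplitude * (exp(-(x - c1)^2 / (2 * sig[1]^2)) +
                         exp(-(x - c2)^2 / (2 * sig[2]^2)))
  a <- array(rep(prof, times = d[2] * d[3]), d)
  if (noise_sd > 0) {
    withr::with_seed(derive_seed(seed, "ct_phantom"), {
      a <- a + array(rnorm(length(a), 0, noise_sd), d)
    })
  }
  vol <- time_lapse_volume(list(ct = a), rep(voxel, 3L),
                           meta = list(scene = "ct", seed = seed))
  list(volume = vol,
       truth = list(centers = c(c1, c2), fwhm = w, sigma = sig,
                    amplitude = amplitude))
}

# ---- bead stacks for PSF characterization ----

#' Generate a synthetic bead stack for PSF estimation
#'
#' Sub-resolution fluorescent beads imaged through a Gaussian PSF appear as
#' anisotropic Gaussian spots; beads are placed at random sub-voxel
#' positions with a minimum mutual separation.
#'
#' @param n_beads number of beads (default 23).
#' @param psf_fwhm numeric length-2 lateral/axial FWHM in um (default the
#'   single-GRIN system values 0.8 and 5.2 um).
#' @param voxel_size numeric length-3 voxel size in um.
#' @param extent numeric length-3 stack extent in um.
#' @param amplitude peak bead intensity (counts).
#' @param background mean background (counts).
#' @param noise logical; Poisson + read noise when `TRUE`.
#' @param read_noise_sd read noise s.d. (counts).
#' @param seed integer seed.
#' @return list with `volume` (channel `beads`, single frame) and `truth`
#'   (data.frame of bead positions um and the generating FWHMs).
#' @export
generate_bead_stack <- function(n_beads = 23L, psf_fwhm = c(0.8, 5.2),
                                voxel_size = c(0.2, 0.2, 0.8),
                                extent = c(26, 26, 50),
                                amplitude = 1000, background = 10,
                                noise = FALSE, read_noise_sd = 2,
                                seed = 3L) {
  stopifnot(n_beads >= 0L, all(psf_fwhm > 0))
  withr::with_seed(derive_seed(seed, "bead_stack"), {
    d <- pmax(1L, as.integer(round(extent / voxel_size)))
    sig <- psf_fwhm[c(1, 1, 2)] / fwhm_factor()
    margin <- 4 * sig + voxel_size
    sep_scale <- c(4, 4, 14) # exclusion ellipsoid semi-axes, um
    pos <- matrix(NA_real_, n_beads, 3L)
    placed <- 0L
    tries <- 0L
    while (placed < n_beads && tries < 20000L) {
      tries <- tries + 1L
      p <- runif(3, margin, extent - margin)
      if (placed > 0L) {
        dd <- sweep(pos[seq_len(placed), , drop = FALSE], 2L, p, "-")
        dd <- sweep(dd, 2L, sep_scale, "/")
        if (min(rowSums(dd^2)) < 1.2^2) next
      }
      placed <- placed + 1L
      pos[placed, ] <- p
    }
    if (placed < n_beads) stop("could not place all beads; enlarge the stack")
    a <- array(0, d)
    cent <- lapply(1:3, function(ax) axis_centers(d[ax], voxel_size[ax]))
    for (i in seq_len(n_beads)) {
      lo <- pmax(1L, floor((pos[i, ] - 4 * sig) / voxel_size))
      hi <- pmin(d, ceiling((pos[i, ] + 4 * sig) / voxel_size))
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      gx <- exp(-(cent[[1]][ix] - pos[i, 1])^2 / (2 * sig[1]^2))
      gy <- exp(-(cent[[2]][iy] - pos[i, 2])^2 / (2 * sig[2]^2))
      gz <- exp(-(cent[[3]][iz] - pos[i, 3])^2 / (2 * sig[3]^2))
      a[ix, iy, iz] <- a[ix, iy, iz] +
        amplitude * outer(outer(gx, gy), gz)
    }
    lam <- a + background
    out <- if (noise) apply_noise(lam, read_noise_sd) else lam
    vol <- time_lapse_volume(list(beads = out), voxel_size,
                             meta = list(scene = "beads", seed = seed))
    truth <- data.frame(bead = seq_len(n_beads), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3])
    list(volume = vol, truth = truth, psf_fwhm = psf_fwhm)
  })
}
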