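make_cell_frame <- function(centers, radii, d = c(60L, 60L, 24L),
                            vx = c(1.5, 1.5, 2.5), amplitude = 100) {
  lab <- array(FALSE, d)
  for (i in seq_len(nrow(centers))) {
    lab <- limbquant:::paint_sphere(lab, centers[i, ], radii[i], vx)
  }
  list(img = amplitude * lab, vx = vx)
}

test_that("non-touching spheres are detected with accurate volumes", {
  centers <- as.matrix(expand.grid(x = c(15.2, 45, 74.8),
                                   y = c(15, 44.6, 75), z = 16.5))
  radii <- rep(c(5, 5.5, 6), length.out = 9)
  vx <- c(1.5, 1.5, 1.5)
  f <- make_cell_frame(centers, radii, d = c(60L, 60L, 22L), vx = vx)
  det <- detect_cells(f$img, threshold = 50, voxel_size = f$vx,
                      smoothing_fwhm = 0)
  expect_equal(nrow(det), 9L)
  for (i in seq_len(nrow(det))) {
    j <- which.min((centers[, 1] - det$x[i])^2 + (centers[, 2] - det$y[i])^2 +
                     (centers[, 3] - det$z[i])^2)
    # detector volume equals the rendered digital volume ...
    dig <- sum(sphere_mask(dim(f$img), vx, centers[j, ], radii[j])) * prod(vx)
    expect_equal(det$volume[i], dig)
    # ... which in turn tracks the analytic ball at this sampling
    v_true <- 4 / 3 * pi * radii[j]^3
    expect_lt(abs(det$volume[i] - v_true) / v_true, 0.1)
    expect_lt(sqrt(sum((centers[j, ] - c(det$x[i], det$y[i], det$z[i]))^2)),
              max(f$vx))
  }
})

test_that("an empty frame yields no detections", {
  det <- detect_cells(array(0, c(20, 20, 10)), voxel_size = c(1, 1, 1))
  expect_equal(nrow(det), 0L)
})

test_that("touching spheres are split by the watershed", {
  centers <- rbind(c(20, 20, 12), c(20, 28.5, 12))
  f <- make_cell_frame(centers, c(5, 5), d = c(30L, 40L, 16L),
                       vx = c(1.5, 1.5, 1.5))
  expect_true(max(limbquant:::label3d(f$img > 50, 26L)) == 1L) # they touch
  det <- detect_cells(f$img, threshold = 50, voxel_size = f$vx,
                      smoothing_fwhm = 0, seed_separation = 6)
  expect_equal(nrow(det), 2L)
})

test_that("cells are classified by the 500 um^3 volume boundary", {
  expect_equal(classify_cell(400), "B cell")
  expect_equal(classify_cell(600), "plasma cell")
  expect_equal(classify_cell(500), "B cell") # tie goes to B cell
  # a 10 um diameter sphere is ~500 um^3 to the nearest hundred
  v_sphere <- 4 / 3 * pi * 5^3
  expect_equal(round(v_sphere, -2), 500)
  expect_equal(classify_cell(v_sphere), "plasma cell")
  expect_error(classify_cell(0), "positive")
  expect_error(classify_cell(-5), "positive")
})

test_that("stationary well-separated cells give clean tracks", {
  det <- do.call(rbind, lapply(1:10, function(f) {
    data.frame(frame = f, x = c(10, 60), y = c(10, 60), z = c(5, 5))
  }))
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track)), 2L)
  expect_true(all(table(tr$track) == 10L))
})

test_that("greedy linking matches the exhaustive oracle on small instances", {
  for (s in 1:6) {
    det <- withr::with_seed(300 + s, {
      pos0 <- matrix(runif(9, 10, 90), 3, 3)
      do.call(rbind, lapply(1:4, function(f) {
        pos <- pos0 + matrix(rnorm(9, 0, 1.5), 3, 3)
        pos0 <<- pos
        data.frame(frame = f, x = pos[, 1], y = pos[, 2], z = pos[, 3])
      }))
    })
    a <- link_tracks(det, max_step = 10, max_gap = 0)
    b <- link_tracks_exhaustive(det, max_step = 10)
    part <- function(df) {
      unname(split(paste(df$frame, round(df$x, 6)), df$track))
    }
    expect_setequal(part(a), part(b))
  }
})

test_that("linking is invariant to the detection input order", {
  det <- withr::with_seed(77, {
    do.call(rbind, lapply(1:6, function(f) {
      data.frame(frame = f, x = runif(5, 0, 80), y = runif(5, 0, 80),
                 z = runif(5, 0, 30))
    }))
  })
  a <- link_tracks(det)
  perm <- withr::with_seed(78, sample(nrow(det)))
  b <- link_tracks(det[perm, ], max_step = 10)
  key <- function(df) {
    df <- df[order(df$frame, df$x), ]
    unname(split(paste(df$frame, round(df$x, 6)), df$track))
  }
  expect_setequal(key(a), key(b))
})

test_that("linking recovers ground-truth identities on a synthetic scene", {
  sc <- generate_cell_scene(n_b = 10, n_pc = 5, render = FALSE, seed = 7,
                            config = cell_scene_config(n_frames = 30))
  g <- sc$truth$tracks
  det <- g[, c("frame", "x", "y", "z")]
  tr <- link_tracks(det)
  merged <- merge(tr, g, by = c("frame", "x", "y", "z"))
  # fraction of consecutive ground-truth steps preserved by the linker
  ok <- 0L; tot <- 0L
  for (id in unique(merged$id)) {
    sub <- merged[merged$id == id, ]
    sub <- sub[order(sub$frame), ]
    tot <- tot + nrow(sub) - 1L
    ok <- ok + sum(diff(sub$track) == 0)
  }
  expect_gte(ok / tot, 0.9)
})

test_that("track filter implements the strict more-than-10 rule", {
  mk <- function(id, n) data.frame(track = id, frame = seq_len(n),
                                   x = 0, y = 0, z = 0)
  tracks <- rbind(mk(1, 10), mk(2, 11), mk(3, 5))
  kept <- filter_tracks(tracks, min_timepoints = 10, frame_interval = 30)
  expect_equal(sort(unique(kept$track)), 2)
  mm <- motility_metrics(kept, frame_interval = 30)
  expect_true(all(mm$duration_min >= 5))
  # idempotence and empty input
  expect_identical(filter_tracks(kept), kept)
  expect_equal(nrow(filter_tracks(tracks[0, ])), 0L)
})

test_that("motility metrics satisfy their defining identities", {
  straight <- data.frame(track = 1, frame = 1:11,
                         x = seq(0, 50, by = 5), y = 0, z = 0)
  mm <- motility_metrics(straight, frame_interval = 30)
  expect_equal(mm$mean_velocity, 10)
  expect_equal(mm$displacement_rate, 10)
  back <- data.frame(track = 1, frame = 1:5, x = c(0, 5, 10, 5, 0),
                     y = 0, z = 0)
  mb <- motility_metrics(back, frame_interval = 30)
  expect_equal(mb$displacement_rate, 0)
  expect_gt(mb$mean_velocity, 0)
  expect_error(motility_metrics(data.frame(track = 1, frame = 1, x = 0,
                                           y = 0, z = 0), 30),
               "at least 2")
})

test_that("displacement rate never exceeds mean velocity", {
  tracks <- withr::with_seed(11, {
    do.call(rbind, lapply(1:25, function(id) {
      n <- sample(5:30, 1)
      data.frame(track = id, frame = seq_len(n),
                 x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                 z = cumsum(rnorm(n)))
    }))
  })
  mm <- motility_metrics(tracks, frame_interval = 30)
  expect_true(all(mm$displacement_rate <= mm$mean_velocity + 1e-9))
})

test_that("group motility recovers the generator speed within 15%", {
  sc <- generate_cell_scene(n_b = 50, n_pc = 0, render = FALSE, seed = 13,
                            config = cell_scene_config(n_frames = 40))
  g <- sc$truth$tracks
  g$track <- g$id
  mm <- motility_metrics(g, frame_interval = 30)
  expect_lt(abs(mean(mm$mean_velocity) - 4) / 4, 0.15)
})

test_that("group comparison flags separated groups and honors equality", {
  a <- withr::with_seed(21, data.frame(mean_velocity = rnorm(20, 4, 1)))
  b <- withr::with_seed(22, data.frame(mean_velocity = rnorm(20, 8, 1)))
  cmp <- compare_groups(a, b, metrics = "mean_velocity")
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
  same <- compare_groups(a, a, metrics = "mean_velocity")
  expect_equal(same$p_value, 1, tolerance = 1e-9)
})
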