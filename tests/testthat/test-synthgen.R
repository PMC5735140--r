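test_that("fixed seed gives byte-identical scenes and ground truth", {
  a <- generate_vessel_scene(seed = 11)
  b <- generate_vessel_scene(seed = 11)
  expect_identical(a$volume$channels, b$volume$channels)
  expect_identical(a$truth, b$truth)
  cc <- generate_cell_scene(n_b = 3, n_pc = 2, render = FALSE, seed = 4,
                            config = cell_scene_config(n_frames = 10))
  dd <- generate_cell_scene(n_b = 3, n_pc = 2, render = FALSE, seed = 4,
                            config = cell_scene_config(n_frames = 10))
  expect_identical(cc$truth, dd$truth)
  e <- generate_photoactivation_scene(noise = TRUE, seed = 2)
  f <- generate_photoactivation_scene(noise = TRUE, seed = 2)
  expect_identical(e$volume$channels, f$volume$channels)
})

test_that("vessel ground truth realizes the diameter-stratified regime", {
  sc <- generate_vessel_scene(remodel_rates = c(small = 0.4, mid = 0.15,
                                                large = 0.05), seed = 1)
  mu <- tapply(sc$truth$delta_true, sc$truth$class, mean)
  expect_gt(mu[["small"]], mu[["mid"]])
  expect_gt(mu[["mid"]], mu[["large"]])
  expect_true(all(sc$truth$delta_true >= 0))
  expect_true(all(sc$truth$diameter > 0))
})

test_that("zero remodel rates give identical noiseless sessions", {
  sc <- generate_vessel_scene(remodel_rates = c(small = 0, mid = 0, large = 0),
                              noise = FALSE, seed = 3)
  expect_identical(sc$labels$t0, sc$labels$t1)
  expect_equal(sc$truth$delta_true, rep(0, nrow(sc$truth)))
  expect_identical(tlv_frame(sc$volume, 1), tlv_frame(sc$volume, 2))
})

test_that("rendered cylinder volume matches the analytic value", {
  # tube spanning the whole grid along y: the in-grid part is a pure
  # cylinder, r = 10 um, L = 100 um
  d <- c(41L, 100L, 41L)
  vx <- c(1, 1, 1)
  m <- limbquant:::paint_capsule(array(FALSE, d), c(20.5, -30, 20.5),
                                 c(20.5, 130, 20.5), 10, vx)
  expect_lt(abs(sum(m) - pi * 100 * 100) / (pi * 100 * 100), 0.02)
  # full capsule: cylinder plus two hemispherical caps
  m2 <- limbquant:::paint_capsule(array(FALSE, c(41L, 140L, 41L)),
                                 c(20.5, 20, 20.5), c(20.5, 120, 20.5), 10, vx)
  v_exp <- pi * 100 * 100 + 4 / 3 * pi * 1000
  expect_lt(abs(sum(m2) - v_exp) / v_exp, 0.02)
})

test_that("vessel generator refuses undersampled scenes", {
  cfg <- vessel_scene_config(voxel_size = c(8, 8, 8))
  expect_error(generate_vessel_scene(cfg), "undersampled")
})

test_that("ground truth is consistent with the rendered label fields", {
  sc <- generate_vessel_scene(seed = 5, noise = FALSE)
  bf <- brute_force_remodeling(sc$labels$t0, sc$labels$t1,
                               sc$volume$voxel_size)
  # match components to vessels via the diameter ordering of delta values
  expect_equal(sort(bf$delta), sort(sc$truth$delta_true), tolerance = 0.02)
})

test_that("cell scene construction follows the requested census and motion", {
  sc <- generate_cell_scene(n_b = 20, n_pc = 10, render = FALSE, seed = 7)
  expect_equal(nrow(sc$truth$cells), 30L)
  expect_equal(sum(sc$truth$cells$volume < 500), 20L)
  expect_equal(sum(sc$truth$cells$volume > 500), 10L)
  expect_equal(length(unique(sc$truth$tracks$id)), 30L)
  ext <- sc$truth$tracks
  cfg_ext <- cell_scene_config()$volume_extent
  expect_true(all(ext$x >= 0 & ext$x <= cfg_ext[1]))
  expect_true(all(ext$z >= 0 & ext$z <= cfg_ext[3]))
})

test_that("zero motion speed freezes every trajectory", {
  sc <- generate_cell_scene(n_b = 4, n_pc = 3, render = FALSE, seed = 2,
                            motion = list(b_speed = 0, b_persistence = 0.8,
                                          pc_speed = 0, pc_confinement = 3),
                            config = cell_scene_config(n_frames = 12))
  disp <- vapply(split(sc$truth$tracks, sc$truth$tracks$id), function(tr) {
    max(abs(tr$x - tr$x[1]), abs(tr$y - tr$y[1]), abs(tr$z - tr$z[1]))
  }, numeric(1))
  expect_equal(unname(disp), rep(0, 7))
})

test_that("B-cell step length matches speed times frame interval", {
  sc <- generate_cell_scene(n_b = 15, n_pc = 0, render = FALSE, seed = 9,
                            motion = list(b_speed = 4, b_persistence = 0.8,
                                          pc_speed = 0.5, pc_confinement = 3),
                            config = cell_scene_config(n_frames = 90))
  steps <- unlist(lapply(split(sc$truth$tracks, sc$truth$tracks$id),
                         function(tr) {
                           sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
                         }))
  expect_equal(mean(steps), 4 * 30 / 60, tolerance = 0.03)
})

test_that("cell generator refuses per-frame steps beyond half the extent", {
  expect_error(
    generate_cell_scene(motion = list(b_speed = 1e5, b_persistence = 0.8,
                                      pc_speed = 0.5, pc_confinement = 3)),
    "speed")
})

test_that("photoactivation scene honors fold increase and decay", {
  sc <- generate_photoactivation_scene()
  pre <- tlv_frame(sc$volume, 1)
  post <- tlv_frame(sc$volume, 2)
  roi <- sc$truth$roi
  d <- dim(pre)
  vx <- sc$volume$voxel_size
  cent <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * vx[ax])
  inr <- array(outer(outer(cent[[1]] >= roi$lo[1] & cent[[1]] <= roi$hi[1],
                           cent[[2]] >= roi$lo[2] & cent[[2]] <= roi$hi[2],
                           "&"),
                     cent[[3]] >= roi$lo[3] & cent[[3]] <= roi$hi[3], "&"), d)
  expect_equal(mean(post[inr]) / mean(pre[inr]), 100)
  # no turnover, no emigration: all post frames identical
  expect_identical(tlv_frame(sc$volume, 2), tlv_frame(sc$volume, 5))
  # closed-form exponential: half-life 12 h leaves 12.5% at 36 h
  sc2 <- generate_photoactivation_scene(turnover_rate = log(2) / 12)
  f0 <- tlv_frame(sc2$volume, 2)
  f36 <- tlv_frame(sc2$volume, 5)
  expect_equal(mean(f36[inr]) / mean(f0[inr]), 0.125, tolerance = 1e-12)
})

test_that("photoactivation generator validates its inputs", {
  expect_error(generate_photoactivation_scene(fold_increase = 0.5),
               "fold_increase")
  expect_error(generate_photoactivation_scene(roi_extent = c(500, 75, 30)),
               "ROI")
})

test_that("CT phantom profile is exactly the configured two-Gaussian sum", {
  ph <- generate_ct_phantom(wall_thicknesses = c(200, 250),
                            wall_separation = 1500, voxel = 10.5,
                            noise_sd = 0)
  a <- tlv_frame(ph$volume)
  d <- dim(a)
  x <- (seq_len(d[1]) - 0.5) * 10.5
  sig <- ph$truth$sigma
  expected <- ph$truth$amplitude *
    (exp(-(x - ph$truth$centers[1])^2 / (2 * sig[1]^2)) +
       exp(-(x - ph$truth$centers[2])^2 / (2 * sig[2]^2)))
  expect_equal(a[, 1, 1], expected, tolerance = 1e-12)
  expect_equal(a[, 1, 1], a[, d[2], d[3]], tolerance = 1e-12) # uniform in y,z
})

test_that("equal walls give a symmetric phantom profile", {
  ph <- generate_ct_phantom(wall_thicknesses = c(200, 200),
                            wall_separation = 1000, voxel = 10)
  prof <- tlv_frame(ph$volume)[, 1, 1]
  mid <- mean(ph$truth$centers)
  x <- (seq_along(prof) - 0.5) * 10
  mirrored <- approx(2 * mid - x, prof, xout = x, rule = 2)$y
  expect_equal(prof, mirrored, tolerance = 1e-6)
})

test_that("CT phantom validates sampling and geometry", {
  expect_error(generate_ct_phantom(wall_thicknesses = c(100, 250),
                                   voxel = 60), "voxel")
  expect_error(generate_ct_phantom(wall_thicknesses = c(800, 800),
                                   wall_separation = 1500), "separation")
})

test_that("noise model variance is Poisson mean plus read-noise variance", {
  lambda <- 40
  rn <- 3
  x <- withr::with_seed(99, {
    limbquant:::apply_noise(array(lambda, c(100, 100, 1)), rn)
  })
  expect_equal(var(as.numeric(x)), lambda + rn^2, tolerance = 0.1)
  expect_equal(mean(x), lambda, tolerance = 0.02)
})
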