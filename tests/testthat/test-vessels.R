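test_that("segmentation overlaps the ground-truth labels", {
  sc <- generate_vessel_scene(seed = 1, noise = FALSE)
  vx <- sc$volume$voxel_size
  m <- segment_vessels(tlv_frame(sc$volume, 1), voxel_size = vx)
  jac <- sum(m$mask & sc$labels$t0) / sum(m$mask | sc$labels$t0)
  expect_gte(jac, 0.9)
})

test_that("all-background input yields an empty mask with a warning", {
  expect_warning(m <- segment_vessels(array(0, c(20, 20, 10)),
                                      voxel_size = c(1, 1, 1)),
                 "all-background")
  expect_false(any(m$mask))
})

test_that("segmentation is robust to the noise realization", {
  a <- generate_vessel_scene(seed = 1, noise_seed = 1)
  b <- generate_vessel_scene(seed = 1, noise_seed = 2)
  vx <- a$volume$voxel_size
  ma <- segment_vessels(tlv_frame(a$volume, 1), voxel_size = vx)
  mb <- segment_vessels(tlv_frame(b$volume, 1), voxel_size = vx)
  expect_false(identical(tlv_frame(a$volume, 1), tlv_frame(b$volume, 1)))
  jac <- sum(ma$mask & mb$mask) / sum(ma$mask | mb$mask)
  expect_gte(jac, 0.8)
})

test_that("local diameter of a digital cylinder is its true diameter", {
  d <- c(41L, 60L, 41L)
  vx <- c(1, 1, 1)
  m <- limbquant:::paint_capsule(array(FALSE, d), c(20.5, -20, 20.5),
                                 c(20.5, 80, 20.5), 10, vx)
  dm <- local_diameter(m, vx)
  expect_equal(median(dm$diameter[m]), 20, tolerance = 0.05) # within 1 voxel
  expect_true(all(is.na(dm$diameter[!m])))
  expect_true(all(dm$diameter[m] > 0))
})

test_that("an isolated voxel reports one voxel size with a warning", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  expect_warning(dm <- local_diameter(m, c(0.7, 0.7, 0.7)), "thinner")
  expect_equal(dm$diameter[5, 5, 5], 0.7)
})

test_that("dilation raises local diameters by zero to two voxel sizes", {
  d <- c(31L, 40L, 31L)
  vx <- c(1, 1, 1)
  m <- limbquant:::paint_capsule(array(FALSE, d), c(15.5, -10, 15.5),
                                 c(15.5, 50, 15.5), 7, vx)
  dm1 <- local_diameter(m, vx)
  md <- dilate6(m)
  dm2 <- local_diameter(md, vx)
  diffs <- dm2$diameter[m] - dm1$diameter[m]
  expect_true(all(diffs >= -1e-9))
  expect_true(all(diffs <= 2 + 1e-9))
})

test_that("session pairing partitions appearance and disappearance", {
  mm <- toy_masks_100_120_90()
  vx <- c(1, 1, 1)
  # identical masks: empty partitions
  p <- pair_sessions(mm$t0, mm$t0, voxel_size = vx)
  expect_false(any(p$appearance))
  expect_false(any(p$disappearance))
  # disjoint masks: appearance = t1, disappearance = t0
  m0 <- array(FALSE, c(10, 10, 3)); m0[2:3, 2:3, 2] <- TRUE
  m1 <- array(FALSE, c(10, 10, 3)); m1[7:8, 7:8, 2] <- TRUE
  p2 <- pair_sessions(m0, m1, voxel_size = vx)
  expect_identical(p2$appearance, m1)
  expect_identical(p2$disappearance, m0)
  expect_error(pair_sessions(m0, array(FALSE, c(5, 5, 3)), voxel_size = vx),
               "grids")
})

test_that("translation registration recovers a constructed shift", {
  sc <- generate_vessel_scene(seed = 2, noise = FALSE)
  m0 <- sc$labels$t0
  m1 <- limbquant:::shift_arr(m0, c(3L, 0L, 0L), fill = FALSE) > 0
  p <- pair_sessions(m0, m1, registration = "translation",
                     voxel_size = sc$volume$voxel_size)
  expect_equal(p$shift, c(-3L, 0L, 0L))
  expect_false(any(p$appearance))
  expect_false(any(p$disappearance))
})

test_that("remodeling statistic equals hand counts on the toy fixture", {
  mm <- toy_masks_100_120_90()
  vx <- c(1, 1, 1)
  expect_equal(sum(mm$t0), 100L)
  expect_equal(sum(mm$t1), 120L)
  expect_equal(sum(mm$t0 & mm$t1), 90L)
  p <- pair_sessions(mm$t0, mm$t1, voxel_size = vx)
  rem <- suppressWarnings(remodeling_statistic(p, class_edges = 0.5))
  expect_equal(nrow(rem$records), 1L)
  expect_equal(rem$records$V_appear, 30)
  expect_equal(rem$records$V_disappear, 10)
  expect_equal(rem$records$delta_norm, 40 / 120)
  # signed variant
  rs <- suppressWarnings(remodeling_statistic(p, class_edges = 0.5,
                                              signed = TRUE))
  expect_equal(rs$records$delta_norm, 20 / 120)
})

test_that("identical sessions give zero volume change everywhere", {
  sc <- generate_vessel_scene(seed = 3, noise = FALSE)
  p <- pair_sessions(sc$labels$t0, sc$labels$t0,
                     voxel_size = sc$volume$voxel_size)
  rem <- remodeling_statistic(p, local_diameter(sc$labels$t0,
                                                sc$volume$voxel_size))
  expect_true(all(rem$records$delta_norm[!is.na(rem$records$class)] == 0))
})

test_that("remodeling matches a brute-force oracle on small random masks", {
  for (s in 1:5) {
    mm <- withr::with_seed(100 + s, {
      m0 <- array(runif(16 * 16 * 8) > 0.75, c(16, 16, 8))
      m1 <- array(runif(16 * 16 * 8) > 0.75, c(16, 16, 8))
      list(m0 = m0, m1 = m1)
    })
    vx <- c(1.5, 1.5, 2)
    p <- pair_sessions(mm$m0, mm$m1, voxel_size = vx)
    rem <- suppressWarnings(remodeling_statistic(p, class_edges = 0))
    bf <- brute_force_remodeling(mm$m0, mm$m1, vx)
    ok <- bf$V_t1 > 0
    expect_equal(rem$records$delta_norm[ok], bf$delta[ok])
    expect_equal(rem$records$V_appear, bf$V_appear)
    expect_equal(rem$records$V_disappear, bf$V_disappear)
    expect_equal(rem$n_fully_disappeared, sum(!ok))
  }
})

test_that("swapping sessions preserves the symmetric difference", {
  sc <- generate_vessel_scene(seed = 4, noise = FALSE)
  vx <- sc$volume$voxel_size
  p01 <- pair_sessions(sc$labels$t0, sc$labels$t1, voxel_size = vx)
  p10 <- pair_sessions(sc$labels$t1, sc$labels$t0, voxel_size = vx)
  r01 <- remodeling_statistic(p01, local_diameter(sc$labels$t1, vx))
  r10 <- remodeling_statistic(p10, local_diameter(sc$labels$t0, vx))
  expect_equal(r01$records$V_appear + r01$records$V_disappear,
               r10$records$V_appear + r10$records$V_disappear)
  # denominator switches to the other session's volume
  expect_equal(r10$records$V_t1,
               vapply(seq_len(nrow(r01$records)), function(i) {
                 r01$records$V_t1[i] - r01$records$V_appear[i] +
                   r01$records$V_disappear[i]
               }, numeric(1)))
})

test_that("delta_norm is invariant to uniform voxel rescaling", {
  mm <- toy_masks_100_120_90()
  p1 <- pair_sessions(mm$t0, mm$t1, voxel_size = c(1, 1, 1))
  p2 <- pair_sessions(mm$t0, mm$t1, voxel_size = c(3, 3, 3))
  r1 <- suppressWarnings(remodeling_statistic(p1, class_edges = 0.5))
  r2 <- suppressWarnings(remodeling_statistic(p2, class_edges = 1.5))
  expect_equal(r1$records$delta_norm, r2$records$delta_norm)
})

test_that("components with median diameter below the first edge are excluded", {
  d <- c(30, 30, 10)
  vx <- c(1, 1, 1)
  m0 <- array(FALSE, d)
  m0[3:4, 3:20, 5] <- TRUE # ~2 um wide ribbon, below the 5 um class edge
  m0 <- m0 | sphere_mask(d, vx, c(20, 15, 5), 4.2)
  p <- pair_sessions(m0, m0, voxel_size = vx)
  rem <- suppressWarnings(
    remodeling_statistic(p, local_diameter(m0, vx), class_edges = c(5, 15, 35)))
  expect_gte(rem$n_below_min_diameter, 1L)
})

test_that("class comparison detects separated classes and honors the null", {
  recs <- withr::with_seed(42, data.frame(
    class = rep(c("small", "mid", "large"), each = 20),
    delta_norm = c(rnorm(20, 0.4, 0.05), rnorm(20, 0.15, 0.05),
                   rnorm(20, 0.05, 0.05))))
  cmp <- compare_classes(recs)
  expect_lt(cmp$p_value, 0.001)
  expect_true(all(dim(cmp$pairwise) == c(2, 2)))
  # identical groups: F ~ 0, p ~ 1
  v <- c(0.1, 0.2, 0.3, 0.4)
  recs2 <- data.frame(class = rep(c("small", "mid"), each = 4),
                      delta_norm = c(v, v))
  cmp2 <- compare_classes(recs2)
  expect_lt(cmp2$F, 1e-10)
  expect_gt(cmp2$p_value, 0.999)
  # classes with < 2 records are dropped with a warning
  recs3 <- rbind(recs2, data.frame(class = "large", delta_norm = 0.5))
  expect_warning(compare_classes(recs3), "fewer than 2")
  expect_error(suppressWarnings(
    compare_classes(data.frame(class = "small", delta_norm = c(1, 2)))),
    "two classes")
})

test_that("power: well-separated classes reject in nearly all replicates", {
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    recs <- withr::with_seed(2000 + s, data.frame(
      class = rep(c("small", "mid", "large"), each = 20),
      delta_norm = c(rnorm(20, 0.4, 0.05), rnorm(20, 0.15, 0.05),
                     rnorm(20, 0.05, 0.05))))
    if (compare_classes(recs)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
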