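# Filters, surface segmentation, vessel mask construction and spot detection.

test_that("smoothing preserves constants and total intensity", {
  vs <- c(2, 1, 1)
  const <- array(7, c(10, 12, 12))
  expect_equal(smooth_channel(const, 4, vs), const)

  x <- array(0, c(10, 12, 12))
  x[5, 6, 6] <- 100
  sm <- smooth_channel(x, 4, vs)
  expect_equal(sum(sm), 100)           # reflecting boundary conserves mass
  expect_lt(max(sm), 100)              # peak spreads
  expect_equal(which.max(sm), which.max(x))
})

test_that("per-axis smoothing sigma scales with the voxel-size ratio", {
  # blur a 1D impulse along each axis and compare with a directly built kernel
  vs <- c(4, 1, 2)
  detail <- 8
  x <- array(0, c(31, 31, 31))
  x[16, 16, 16] <- 1
  sm <- smooth_channel(x, detail, vs)
  for (axis in 1:3) {
    sigma_vox <- (detail / 2) / vs[axis]
    r <- ceiling(3.5 * sigma_vox)
    k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
    k <- k / sum(k)
    profile <- switch(axis, sm[(16 - r):(16 + r), 16, 16],
                      sm[16, (16 - r):(16 + r), 16],
                      sm[16, 16, (16 - r):(16 + r)])
    expect_equal(profile / max(profile), k / max(k), tolerance = 1e-10)
  }
})

test_that("smoothing warns and skips axes coarser than the detail", {
  x <- array(runif(6 * 8 * 8), c(6, 8, 8))
  expect_warning(sm <- smooth_channel(x, 2, c(8, 1, 1)), "axis z")
  expect_equal(apply(sm, 1, sum), apply(x, 1, sum), tolerance = 1e-12)  # z untouched
})

test_that("top-hat removes flat background and keeps compact blobs", {
  vs <- c(2, 1, 1)
  x <- array(50, c(12, 40, 40))  # flat background
  blob <- array(extravas:::cpp_sphere_union(c(12L, 40L, 40L), vs,
                                            matrix(c(12, 20, 20), 1), c(4, 4, 4)),
                dim = c(12, 40, 40))
  x <- x + 100 * blob
  th <- subtract_background(x, 20, vs)
  expect_lt(max(th[!blob]), 1)            # background gone
  expect_gte(max(th), 0.8 * 100)          # blob peak retained
  expect_true(all(th >= 0))

  expect_equal(subtract_background(array(0, c(6, 10, 10)), 20, vs),
               array(0, c(6, 10, 10)))
  y <- array(runif(6 * 10 * 10, 0, 10), c(6, 10, 10))
  expect_true(all(subtract_background(y, 6, vs) >= 0))
  expect_warning(out <- subtract_background(y, 0.5, vs), "smaller than one voxel")
  expect_identical(out, y)
})

test_that("two separated spheres segment into two objects with analytic volumes", {
  vs <- c(2, 1, 1)
  shape <- c(24L, 48L, 48L)
  centers <- rbind(c(20, 14, 14), c(28, 34, 34))
  ch <- array(100 * extravas:::cpp_sphere_union(shape, vs, centers, c(6, 6, 6)),
              dim = shape)
  surf <- segment_surfaces(ch, vs, list(method = "manual", value = 50))
  expect_equal(nrow(surf$objects), 2L)
  analytic <- 4 / 3 * pi * 6^3
  expect_true(all(abs(surf$objects$volume_um3 - analytic) / analytic < 0.15))
  # centroids sit at the sphere centers
  got <- as.matrix(surf$objects[, c("centroid_z_um", "centroid_y_um", "centroid_x_um")])
  expect_equal(got[order(got[, 2]), ], centers, tolerance = 0.5, ignore_attr = TRUE)
})

test_that("the size filter drops sub-threshold components", {
  vs <- c(1, 1, 1)
  ch <- array(0, c(8, 8, 8))
  ch[2, 2, 2] <- 10            # single-voxel speck
  surf <- segment_surfaces(ch, vs, list(method = "manual", value = 5),
                           min_object_voxels = 3L)
  expect_equal(nrow(surf$objects), 0L)
  expect_true(all(surf$labels == 0L))
})

test_that("segmentation is deterministic and conserves foreground volume", {
  set.seed(31)
  vs <- c(2, 1, 1)
  ch <- array(runif(10 * 20 * 20, 0, 100), c(10, 20, 20))
  a <- segment_surfaces(ch, vs, min_object_voxels = 1L)
  b <- segment_surfaces(ch, vs, min_object_voxels = 1L)
  expect_identical(a$labels, b$labels)
  expect_identical(a$objects, b$objects)
  expect_equal(sum(a$objects$volume_um3),
               sum(ch > a$threshold) * prod(vs))
})

test_that("raising a manual threshold never grows the foreground", {
  set.seed(32)
  ch <- array(runif(8 * 16 * 16, 0, 100), c(8, 16, 16))
  vols <- vapply(c(20, 40, 60, 80), function(thr) {
    sum(segment_surfaces(ch, c(1, 1, 1), list(method = "manual", value = thr),
                         min_object_voxels = 1L)$objects$volume_um3)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("a manual threshold outside the intensity range errors", {
  ch <- array(runif(4 * 8 * 8, 0, 10), c(4, 8, 8))
  expect_error(segment_surfaces(ch, c(1, 1, 1), list(method = "manual", value = 99)),
               "outside the intensity range")
})

test_that("an empty foreground yields an empty surface set, not an error", {
  ch <- array(0, c(4, 8, 8))
  surf <- segment_surfaces(ch, c(1, 1, 1))
  expect_equal(nrow(surf$objects), 0L)
})

test_that("vessel mask filling turns a hollow shell into a solid tube", {
  vs <- c(2, 1, 1)
  shape <- c(20L, 40L, 40L)
  line <- rbind(c(-10, 20, 20), c(100, 20, 20))
  solid <- rasterize_tubes(line, 10, shape, vs)
  inner <- rasterize_tubes(line, 6, shape, vs)
  shell <- solid & !inner
  ch <- array(100 * shell, dim = shape)
  surf <- segment_surfaces(ch, vs, list(method = "manual", value = 50))
  vm <- build_vessel_mask(surf, closing_radius_um = 2)
  # lumen filled: the filled mask recovers (at least) the solid tube
  expect_true(all(vm$mask[solid]))
  expect_gte(vm$total_volume_um3, sum(shell) * prod(vs))

  # a solid input stays essentially unchanged (closing acts only at margins)
  ch2 <- array(100 * solid, dim = shape)
  surf2 <- segment_surfaces(ch2, vs, list(method = "manual", value = 50))
  vm2 <- build_vessel_mask(surf2, closing_radius_um = 2)
  expect_true(all(vm2$mask[solid]))
  expect_lt(sum(vm2$mask & !solid) / sum(solid), 0.1)
})

test_that("a lone nucleus is detected within one voxel of its center", {
  vs <- c(8, 1.14, 1.14)
  shape <- c(12L, 64L, 64L)
  center <- matrix(c(40, 36.5, 30.2), 1)
  ch <- array(200 * extravas:::cpp_sphere_union(shape, vs, center, c(4, 2.5, 2.5)),
              dim = shape)
  sp <- detect_spots(ch, vs, 5, 10)
  expect_equal(nrow(sp), 1L)
  expect_true(all(abs(c(sp$center_z_um, sp$center_y_um, sp$center_x_um) - center) <= vs))
})

test_that("two nuclei two diameters apart yield two spots", {
  vs <- c(8, 1.14, 1.14)
  shape <- c(12L, 64L, 64L)
  centers <- rbind(c(40, 30, 30), c(40, 30, 40))  # 10 um apart in x
  ch <- array(200 * extravas:::cpp_sphere_union(shape, vs, centers, c(4, 2.5, 2.5)),
              dim = shape)
  sp <- detect_spots(ch, vs, 5, 10)
  expect_equal(nrow(sp), 2L)
  expect_true(all(sp$quality >= 10))
})
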