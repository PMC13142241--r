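# Anisotropic distance mapping, per-cell assignment, profiles and escape
# distances.

test_that("anisotropic distances obey the Pythagorean cases", {
  vs <- c(8, 1, 1)
  mask <- array(FALSE, c(6, 8, 8))
  mask[1, 1, 1] <- TRUE
  dm <- distance_map_outside(mask, vs)
  expect_equal(dm$values[2, 1, 1], 8)     # one z step
  expect_equal(dm$values[1, 4, 5], 5)     # 3-4-5 triangle in-plane
  expect_equal(dm$values[1, 1, 1], 0)
})

test_that("a full mask maps to all zeros and an empty mask errors", {
  full <- array(TRUE, c(4, 5, 5))
  expect_true(all(distance_map_outside(full, c(8, 1, 1))$values == 0))
  expect_error(distance_map_outside(array(FALSE, c(4, 5, 5)), c(8, 1, 1)),
               "empty vessel mask")
})

test_that("the distance transform matches brute force on random masks", {
  set.seed(51)
  vs <- c(8, 1, 1)
  for (i in 1:15) {
    mask <- array(runif(16^3) < runif(1, 0.005, 0.08), c(16, 16, 16))
    if (!any(mask)) mask[sample(16, 1), sample(16, 1), sample(16, 1)] <- TRUE
    dm <- distance_map_outside(mask, vs)
    expect_lt(max(abs(dm$values - bf_distance_map(mask, vs))), 1e-6)
  }
})

test_that("the distance map is 1-Lipschitz in physical units", {
  set.seed(52)
  vs <- c(4, 1.5, 1)
  mask <- array(runif(12^3) < 0.03, c(12, 12, 12))
  mask[6, 6, 6] <- TRUE
  v <- distance_map_outside(mask, vs)$values
  # axis-neighbour differences never exceed the voxel pitch
  expect_lte(max(abs(apply(v, c(2, 3), diff))), vs[1] + 1e-9)
  expect_lte(max(abs(apply(v, c(1, 3), diff))), vs[2] + 1e-9)
  expect_lte(max(abs(apply(v, c(1, 2), diff))), vs[3] + 1e-9)
})

test_that("assignment samples the nearest voxel and splits compartments", {
  vs <- c(1, 1, 1)
  mask <- array(FALSE, c(10, 10, 12))
  mask[, , 1:2] <- TRUE              # flat vascular slab
  dm <- distance_map_outside(mask, vs)
  pop <- tibble::tibble(
    cell_id = 1:3,
    center_z_um = c(5, 5, 5), center_y_um = c(5, 5, 5),
    center_x_um = c(1, 6, 50),       # in-slab, 5 voxels off the face, out of bounds
    population = "effector"
  )
  expect_warning(out <- assign_distances(pop, dm, mask), "unassigned")
  expect_equal(out$compartment, c("intravascular", "extravascular", "unassigned"))
  expect_equal(out$distance_um[1:2], c(0, 5))
  expect_true(is.na(out$distance_um[3]))
})

test_that("profiles bin extravascular cells into half-open bins", {
  pop <- tibble::tibble(
    cell_id = 1:5,
    compartment = c("extravascular", "extravascular", "extravascular",
                    "intravascular", "intravascular"),
    distance_um = c(1, 1, 3, 0, 0),
    population = "effector"
  )
  prof <- bin_distances(pop, bin_width_um = 2)
  expect_equal(prof$count, c(2L, 1L))
  expect_equal(prof$percent, c(200 / 3, 100 / 3))
  expect_equal(prof$bin_lo_um, c(0, 2))
  expect_equal(sum(prof$count), 3L)
  expect_equal(attr(prof, "n_intravascular"), 2L)
  expect_equal(prof$cumulative_percent[nrow(prof)], 100)
  expect_true(all(diff(prof$cumulative_percent) >= 0))

  # a boundary distance falls in the upper bin
  prof2 <- bin_distances(dplyr::mutate(pop, distance_um = c(2, 1, 3, 0, 0)), 2)
  expect_equal(prof2$count, c(1L, 2L))

  # order invariance
  prof3 <- bin_distances(pop[sample(5), ], 2)
  expect_equal(prof3$count, prof$count)
})

test_that("an empty population produces an empty flagged profile", {
  pop <- tibble::tibble(cell_id = integer(0), compartment = character(0),
                        distance_um = numeric(0), population = character(0))
  prof <- bin_distances(pop, 10)
  expect_equal(nrow(prof), 0L)
  expect_true(attr(prof, "empty"))
})

test_that("escape distance is the empirical inverse-CDF quantile", {
  expect_equal(escape_distance(1:100, 0.95), 95)
  expect_equal(escape_distance(rep(7.5, 20), 0.5), 7.5)
  expect_equal(escape_distance(rep(7.5, 20), 0.99), 7.5)
  expect_error(escape_distance(numeric(0)), "empty")

  # sorted-scan oracle on random multisets
  set.seed(53)
  for (i in 1:20) {
    x <- round(runif(sample(5:80, 1), 0, 200), 1)
    q <- runif(1, 0.05, 0.99)
    xs <- sort(x)
    oracle <- xs[which(seq_along(xs) / length(xs) >= q)[1]]
    expect_equal(escape_distance(x, q), oracle)
  }
})

test_that("escape distance is non-decreasing in the quantile", {
  set.seed(54)
  x <- rexp(200, 1 / 30)
  qs <- seq(0.1, 1, by = 0.1)
  vals <- vapply(qs, function(q) escape_distance(x, q), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("the binned escape distance brackets the raw one from above", {
  set.seed(55)
  pop <- tibble::tibble(
    cell_id = 1:150, compartment = "extravascular",
    distance_um = rexp(150, 1 / 25), population = "p"
  )
  prof <- bin_distances(pop, 10)
  raw <- escape_distance(pop, 0.95)
  binned <- escape_distance_binned(prof, 0.95)
  expect_gte(binned, raw)
  expect_lte(binned - raw, 10)
})
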