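# Voxel masking, compartment volumes, the extravasation fraction and counts.

test_that("masking partitions a channel exactly", {
  set.seed(61)
  d <- c(8L, 16L, 16L)
  ch <- array(runif(prod(d), 0, 255), d)
  mask <- array(runif(prod(d)) < 0.3, d)
  parts <- mask_population_channel(ch, mask)
  expect_identical(parts$inside + parts$outside, ch)   # bitwise reconstruction
  expect_true(all(parts$inside[!mask] == 0))
  expect_true(all(parts$outside[mask] == 0))

  empty <- array(FALSE, d)
  p0 <- mask_population_channel(ch, empty)
  expect_true(all(p0$inside == 0))
  expect_identical(p0$outside, ch)

  full <- array(TRUE, d)
  p1 <- mask_population_channel(ch, full)
  expect_true(all(p1$outside == 0))
  expect_identical(p1$inside, ch)

  expect_error(mask_population_channel(ch, array(TRUE, c(8, 16, 15))), "shapes differ")
})

test_that("a sphere outside the mask lands entirely in V_out at its analytic volume", {
  vs <- c(2, 1, 1)
  d <- c(24L, 40L, 40L)
  ch <- array(100 * extravas:::cpp_sphere_union(d, vs, matrix(c(24, 20, 20), 1),
                                                c(6, 6, 6)), dim = d)
  mask <- array(FALSE, d)
  mask[1:2, , ] <- TRUE   # slab far from the sphere
  vols <- population_volumes(mask_population_channel(ch, mask), vs, 50)
  expect_equal(vols[["V_in_um3"]], 0)
  analytic <- 4 / 3 * pi * 6^3
  expect_lt(abs(vols[["V_out_um3"]] - analytic) / analytic, 0.15)
})

test_that("a sphere bisected by a flat mask face splits its volume evenly", {
  vs <- c(1, 1, 1)
  d <- c(40L, 40L, 40L)
  ch <- array(100 * extravas:::cpp_sphere_union(d, vs, matrix(c(19.5, 20, 20), 1),
                                                c(8, 8, 8)), dim = d)
  mask <- array(FALSE, d)
  mask[1:20, , ] <- TRUE   # face between voxel rows 20 and 21, at z = 19.5
  vols <- population_volumes(mask_population_channel(ch, mask), vs, 50,
                             min_object_voxels = 1L)
  expect_lt(abs(vols[["V_in_um3"]] - vols[["V_out_um3"]]) /
              max(vols[["V_in_um3"]], vols[["V_out_um3"]]), 0.10)
})

test_that("with an absolute threshold the split volumes conserve the total", {
  set.seed(62)
  vs <- c(2, 1, 1)
  d <- c(10L, 24L, 24L)
  ch <- array(runif(prod(d), 0, 100), d)
  mask <- array(runif(prod(d)) < 0.4, d)
  thr <- 60
  vols <- population_volumes(mask_population_channel(ch, mask), vs, thr,
                             min_object_voxels = 1L)
  total <- sum(segment_surfaces(ch, vs, list(method = "manual", value = thr),
                                min_object_voxels = 1L)$objects$volume_um3)
  expect_equal(unname(vols[["V_in_um3"]] + vols[["V_out_um3"]]), total)
})

test_that("the extravasation fraction follows its defining formula", {
  expect_equal(extravasation_fraction(100, 100), 50)
  expect_equal(extravasation_fraction(0, 42), 100)
  expect_equal(extravasation_fraction(42, 0), 0)
  expect_error(extravasation_fraction(0, 0), "undefined")
  # scale invariance
  set.seed(63)
  for (i in 1:10) {
    vi <- runif(1, 1, 1e5); vo <- runif(1, 1, 1e5); k <- runif(1, 1e-3, 1e3)
    expect_equal(extravasation_fraction(vi, vo),
                 extravasation_fraction(k * vi, k * vo))
  }
  expect_true(all(extravasation_fraction(runif(5, 0, 10), runif(5, 0, 10)) <= 100))
})

test_that("compartment counts partition the assigned population", {
  pop <- tibble::tibble(
    cell_id = 1:6,
    compartment = c(rep("intravascular", 4), "extravascular", "unassigned")
  )
  expect_message(cnt <- count_extravasated(pop), "1 unassigned")
  expect_equal(cnt[["n_extravasated"]], 1L)
  expect_equal(cnt[["n_intravascular"]], 4L)
  expect_equal(sum(cnt), 5L)

  all_in <- tibble::tibble(cell_id = 1:7, compartment = rep("intravascular", 7))
  expect_equal(unname(count_extravasated(all_in)), c(0L, 7L))
})

test_that("counts recover ground truth exactly on noise-free truth centers", {
  cfg <- small_sim_config(seed = 64L,
                          noise_model = list(poisson_gain = 0, gaussian_sd = 0))
  net <- generate_vessel_network(cfg)
  truth <- place_cells(cfg, net$vessel_mask_true)
  dm <- distance_map_outside(net$vessel_mask_true, cfg$voxel_size_um)
  got <- assign_distances(truth$cells, dm, net$vessel_mask_true)
  expect_equal(got$compartment, truth$cells$compartment)
  cnt <- count_extravasated(got)
  expect_equal(cnt[["n_extravasated"]],
               sum(truth$cells$compartment == "extravascular"))
})
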