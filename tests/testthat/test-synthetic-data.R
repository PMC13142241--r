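# Generator: vessel geometry, cell placement statistics, rendering, and the
# determinism/closure invariants that make the simulation usable as ground
# truth.

test_that("a straight axis-aligned tube reproduces the analytic cylinder volume", {
  shape <- c(24L, 64L, 64L)
  vs <- c(8, 1, 1)
  center <- rbind(c(-20, 32, 32), c(220, 32, 32))  # spans the full z extent
  mask <- rasterize_tubes(center, radius_um = 10, shape, vs)
  vol <- sum(mask) * prod(vs)
  analytic <- pi * 10^2 * (shape[1] * vs[1])
  expect_lt(abs(vol - analytic) / analytic, 0.10)
  # every z-plane carries the same disk
  expect_true(all(apply(mask, 1, sum) == sum(mask[1, , ])))
})

test_that("zero vessels give an empty mask and a zero channel", {
  cfg <- small_sim_config(n_vessels = 0L)
  net <- generate_vessel_network(cfg)
  expect_false(any(net$vessel_mask_true))
  expect_true(all(net$vessel_channel == 0))
})

test_that("a vessel radius exceeding the field of view is rejected", {
  cfg <- small_sim_config(vessel_radius_um = c(mean = 80, sd = 0))
  expect_error(generate_vessel_network(cfg), "field of view")
})

test_that("the generate -> place -> render chain is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5L)
  a <- simulate_tumor_volume(cfg)
  b <- simulate_tumor_volume(cfg)
  expect_identical(a$truth$vessel_mask_true, b$truth$vessel_mask_true)
  expect_identical(a$truth$cells, b$truth$cells)
  for (nm in names(a$stack$channels)) {
    expect_identical(a$stack$channels[[nm]], b$stack$channels[[nm]])
  }
})

test_that("vessel mask occupies a minority of the volume", {
  net <- generate_vessel_network(simulation_config(seed = 2L))
  occ <- mean(net$vessel_mask_true)
  expect_gt(occ, 0)
  expect_lt(occ, 0.5)
})

test_that("a zero extravascular fraction places every cell in a vessel at distance 0", {
  cfg <- small_sim_config(extravascular_fraction_true = 0)
  net <- generate_vessel_network(cfg)
  truth <- place_cells(cfg, net$vessel_mask_true)
  expect_equal(nrow(truth$cells), cfg$n_cells)
  expect_true(all(truth$cells$compartment == "intravascular"))
  expect_true(all(truth$cells$distance_true_um == 0))
})

test_that("extravascular distances follow the exponential decay law", {
  # all-extravascular placement at decay length 20 um; the empirical mean must
  # land within 3 standard errors of 20 (mild truncation by the field size)
  cfg <- simulation_config(seed = 21L, n_cells = 2000L,
                           extravascular_fraction_true = 1, decay_length_um = 20)
  net <- generate_vessel_network(cfg)
  truth <- place_cells(cfg, net$vessel_mask_true)
  expect_true(all(truth$cells$compartment == "extravascular"))
  expect_true(all(truth$cells$distance_true_um > 0))
  expect_lt(abs(mean(truth$cells$distance_true_um) - 20), 3 * 20 / sqrt(2000))
})

test_that("intravascular centers lie in the mask and extravascular centers outside", {
  cfg <- small_sim_config(seed = 3L)
  net <- generate_vessel_network(cfg)
  truth <- place_cells(cfg, net$vessel_mask_true)
  d <- dim(net$vessel_mask_true)
  vox <- round(sweep(cells_to_matrix(truth$cells), 2, cfg$voxel_size_um, `/`)) + 1
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
  inside <- net$vessel_mask_true[lin]
  expect_true(all(inside[truth$cells$compartment == "intravascular"]))
  expect_true(all(!inside[truth$cells$compartment == "extravascular"]))
  expect_true(all(truth$cells$distance_true_um >= 0))
  expect_true(all((truth$cells$distance_true_um == 0) ==
                    (truth$cells$compartment == "intravascular")))
})

test_that("raising the extravascular fraction never lowers the extravascular count", {
  counts <- vapply(c(0.2, 0.5, 0.8), function(f) {
    cfg <- small_sim_config(seed = 9L, extravascular_fraction_true = f)
    net <- generate_vessel_network(cfg)
    truth <- place_cells(cfg, net$vessel_mask_true)
    sum(truth$cells$compartment == "extravascular")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the truth fraction closes with the extravasation formula", {
  cfg <- small_sim_config(seed = 7L)
  net <- generate_vessel_network(cfg)
  truth <- place_cells(cfg, net$vessel_mask_true)
  expect_equal(
    extravasation_fraction(truth$volume_in_true_um3, truth$volume_out_true_um3),
    truth$fraction_true_pct
  )
})

test_that("noiseless rendering peaks at a lone cell center and is reproducible", {
  cfg <- simulation_config(shape_voxels = c(9L, 33L, 33L), voxel_size_um = c(4, 1, 1),
                           n_vessels = 0L, n_cells = 0L, background_level = 0,
                           noise_model = list(poisson_gain = 0, gaussian_sd = 0),
                           psf_sigma_um = c(2, 1, 1), seed = 1L)
  truth <- structure(list(
    vessel_mask_true = array(FALSE, cfg$shape_voxels),
    cells = tibble::tibble(cell_id = 1L, center_z_um = 16, center_y_um = 16,
                           center_x_um = 16, compartment = "extravascular",
                           distance_true_um = 10),
    volume_in_true_um3 = 0, volume_out_true_um3 = 1,
    fraction_true_pct = 100, config = cfg
  ), class = "ground_truth")
  stack <- render_volume(truth, cfg)
  nuc <- stack$channels$nucleus
  peak_vox <- arrayInd(which.max(nuc), dim(nuc))
  expect_equal(as.vector((peak_vox - 1) * cfg$voxel_size_um), c(16, 16, 16))
  # no RNG is consumed without noise: renders are identical
  expect_identical(stack$channels$nucleus, render_volume(truth, cfg)$channels$nucleus)
})

test_that("the realized SNR of a rendered volume matches its definition", {
  cfg <- small_sim_config(seed = 13L,
                          noise_model = list(poisson_gain = 0, gaussian_sd = 40))
  noiseless <- small_sim_config(seed = 13L,
                                noise_model = list(poisson_gain = 0, gaussian_sd = 0))
  sim_n <- simulate_tumor_volume(cfg)
  sim_0 <- simulate_tumor_volume(noiseless)
  peak <- max(sim_0$stack$channels$effector) - cfg$background_level
  snr <- peak / cfg$noise_model$gaussian_sd
  expect_equal(snr, peak / 40)
  # away from the zero-clamp (bright voxels), the noisy render is the clean
  # render plus zero-mean read noise at the configured sd
  bright <- sim_0$stack$channels$effector > 3 * 40
  resid <- (sim_n$stack$channels$effector - sim_0$stack$channels$effector)[bright]
  expect_gt(sum(bright), 1000)
  expect_lt(abs(mean(resid)), 40 / sqrt(sum(bright)) * 4)
  expect_lt(abs(sd(resid) - 40), 2)
})
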