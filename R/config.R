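#' Configuration for the synthetic cleared-tumor volume generator
#'
#' Defines the acquisition geometry and biological structure of a simulated
#' multi-channel z-stack: tube-like vasculature, nuclei rendered as ~5 um
#' blobs, and an effector-cell population split between an intravascular and
#' an extravascular compartment whose density decays exponentially with
#' distance from the vessel wall.
#'
#' The default geometry is a downscaled tile of a typical cleared-tumor
#' confocal acquisition (1024 x 1024 XY frames over ~300 um depth at an 8 um
#' z-step): 256 x 256 XY at the same pixel pitch and 24 z-planes. The full
#' acquisition size runs through the identical code path.
#'
#' @param shape_voxels Integer (z, y, x) voxel counts.
#' @param voxel_size_um Physical voxel size (z, y, x), micrometers.
#' @param n_vessels Number of vessel tubes to grow.
#' @param vessel_radius_um Mean and sd of the per-vessel radius, micrometers.
#' @param n_cells Total number of effector cells.
#' @param extravascular_fraction_true Fraction of cells placed outside the
#'   vasculature, in `[0, 1]`.
#' @param decay_length_um Scale of the exponential distance decay used to
#'   place extravascular cells, micrometers.
#' @param cell_radius_um Radius of the rendered whole-cell sphere, micrometers.
#' @param nucleus_radius_um Radius of the rendered nucleus sphere, micrometers.
#' @param psf_sigma_um Gaussian PSF sigma per axis (z, y, x), micrometers.
#' @param background_level Constant background intensity added to every channel.
#' @param noise_model List with `poisson_gain` (photons per intensity unit;
#'   0 disables shot noise) and `gaussian_sd` (additive read noise sd;
#'   0 disables).
#' @param seed Integer seed; the generate/place/render chain is fully
#'   deterministic given the seed.
#' @param cell_placement `"perivascular"` (the default: intravascular cells
#'   uniform in the mask, extravascular cells with exponential distance decay)
#'   or `"uniform"` (cells uniform over the whole volume regardless of
#'   `extravascular_fraction_true`; compartments and distances still recorded
#'   from the mask) -- the layout used for detector benchmarks.
#' @param channel_amplitude Intensity of rendered cell/nucleus spheres before
#'   optics and noise.
#' @param vessel_amplitude Intensity of the rendered vessel tube.
#' @param step_length_um Centerline step of the vessel random walk, micrometers.
#' @param tortuosity Sd of the per-step direction perturbation; 0 gives
#'   straight tubes.
#' @return A `simulation_config` list.
#' @seealso [simulate_tumor_volume()], [generate_vessel_network()],
#'   [place_cells()], [render_volume()]
#' @export
simulation_config <- function(shape_voxels = c(24L, 256L, 256L),
                              voxel_size_um = c(8, 1.14, 1.14),
                              n_vessels = 6L,
                              vessel_radius_um = c(mean = 12, sd = 2),
                              n_cells = 800L,
                              extravascular_fraction_true = 0.7,
                              decay_length_um = 30,
                              cell_radius_um = 5,
                              nucleus_radius_um = 2.5,
                              psf_sigma_um = c(3, 1, 1),
                              background_level = 10,
                              noise_model = list(poisson_gain = 1, gaussian_sd = 2),
                              seed = 1L,
                              channel_amplitude = 200,
                              vessel_amplitude = 150,
                              step_length_um = 15,
                              tortuosity = 0.35,
                              cell_placement = c("perivascular", "uniform")) {
  cell_placement <- match.arg(cell_placement)
  if (length(shape_voxels) != 3L || any(shape_voxels < 1)) {
    abort("`shape_voxels` must be three positive voxel counts (z, y, x)")
  }
  check_voxel_size(voxel_size_um)
  if (extravascular_fraction_true < 0 || extravascular_fraction_true > 1) {
    abort("`extravascular_fraction_true` must lie in [0, 1]")
  }
  pos <- c(decay_length_um = decay_length_um, cell_radius_um = cell_radius_um,
           nucleus_radius_um = nucleus_radius_um, step_length_um = step_length_um)
  if (any(pos <= 0)) {
    abort(sprintf("physical sizes must be strictly positive (%s)",
                  paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (vessel_radius_um[[1]] <= 0) abort("`vessel_radius_um` mean must be positive")
  if (n_cells < 0 || n_vessels < 0) abort("counts must be non-negative")
  structure(list(
    shape_voxels = as.integer(shape_voxels),
    voxel_size_um = as.numeric(voxel_size_um),
    n_vessels = as.integer(n_vessels),
    vessel_radius_um = c(mean = unname(vessel_radius_um[[1]]),
                         sd = if (length(vessel_radius_um) > 1) unname(vessel_radius_um[[2]]) else 0),
    n_cells = as.integer(n_cells),
    extravascular_fraction_true = extravascular_fraction_true,
    decay_length_um = decay_length_um,
    cell_radius_um = cell_radius_um,
    nucleus_radius_um = nucleus_radius_um,
    psf_sigma_um = as.numeric(psf_sigma_um),
    background_level = background_level,
    noise_model = noise_model,
    seed = as.integer(seed),
    channel_amplitude = channel_amplitude,
    vessel_amplitude = vessel_amplitude,
    step_length_um = step_length_um,
    tortuosity = tortuosity,
    cell_placement = cell_placement
  ), class = "simulation_config")
}

#' Analysis parameters for the quantification pipeline
#'
#' Holds every tunable of the surface/spot workflow with the defaults used for
#' the cleared-tumor acquisitions: 2.0 um surface smoothing detail, 5 um
#' estimated nucleus spot diameter, a spot quality cutoff of 10, a 5 um
#' spot-to-surface proximity threshold, and the cumulative 95% escape-distance
#' quantile. The spot quality scale here is the normalized
#' Laplacian-of-Gaussian response amplitude, a reproducible stand-in for the
#' undocumented quality score of interactive software; the numeric cutoff is
#' kept at 10 but its calibration is detector-specific.
#'
#' @param smoothing_detail_um Surface smoothing detail (Gaussian sigma =
#'   detail / 2 per axis), micrometers.
#' @param background_sphere_um Diameter of the ellipsoidal top-hat structuring
#'   element used for background subtraction, micrometers. Must exceed the
#'   widest structure to be retained (here the vessel diameter), otherwise the
#'   top-hat removes it.
#' @param vessel_threshold List `list(method = "otsu")` or
#'   `list(method = "manual", value = <absolute intensity>)` for the vessel
#'   channel.
#' @param population_threshold Same structure, for quantified cell channels.
#' @param spot_diameter_um Estimated XY nucleus diameter for spot detection.
#' @param spot_quality_min Minimum spot quality (normalized LoG amplitude).
#' @param proximity_um Spot-to-surface association threshold (closed bound).
#' @param bin_width_um Width of distance histogram bins, micrometers.
#' @param cumulative_quantile Quantile defining the escape distance.
#' @param min_object_voxels Minimum connected-component size kept as a surface
#'   object.
#' @param vessel_channel,nucleus_channel Channel names in the input stack.
#' @param quantified_channels Channels to quantify; default: every channel
#'   that is neither the vessel nor the nucleus channel.
#' @param seed Integer seed recorded in reports (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(smoothing_detail_um = 2.0,
                            background_sphere_um = 40,
                            vessel_threshold = list(method = "otsu"),
                            population_threshold = list(method = "otsu"),
                            spot_diameter_um = 5,
                            spot_quality_min = 10,
                            proximity_um = 5,
                            bin_width_um = 10,
                            cumulative_quantile = 0.95,
                            min_object_voxels = 5L,
                            vessel_channel = "vessel",
                            nucleus_channel = "nucleus",
                            quantified_channels = NULL,
                            seed = 1L) {
  pos <- c(smoothing_detail_um = smoothing_detail_um,
           background_sphere_um = background_sphere_um,
           spot_diameter_um = spot_diameter_um, bin_width_um = bin_width_um)
  if (any(pos <= 0)) {
    abort(sprintf("physical parameters must be positive (%s)",
                  paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (proximity_um < 0) abort("`proximity_um` must be >= 0")
  if (cumulative_quantile <= 0 || cumulative_quantile >= 1) {
    abort("`cumulative_quantile` must lie strictly between 0 and 1")
  }
  for (thr in list(vessel_threshold, population_threshold)) {
    if (!is.list(thr) || !thr$method %in% c("otsu", "manual")) {
      abort("thresholds must be list(method = \"otsu\") or list(method = \"manual\", value = ...)")
    }
    if (thr$method == "manual" && is.null(thr$value)) {
      abort("manual thresholds need a `value`")
    }
  }
  structure(list(
    smoothing_detail_um = smoothing_detail_um,
    background_sphere_um = background_sphere_um,
    vessel_threshold = vessel_threshold,
    population_threshold = population_threshold,
    spot_diameter_um = spot_diameter_um,
    spot_quality_min = spot_quality_min,
    proximity_um = proximity_um,
    bin_width_um = bin_width_um,
    cumulative_quantile = cumulative_quantile,
    min_object_voxels = as.integer(min_object_voxels),
    vessel_channel = vessel_channel,
    nucleus_channel = nucleus_channel,
    quantified_channels = quantified_channels,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  volume: %s voxels at (%.2f, %.2f, %.2f) um -> (%.0f, %.0f, %.0f) um\n",
              paste(x$shape_voxels, collapse = " x "),
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              x$shape_voxels[1] * x$voxel_size_um[1],
              x$shape_voxels[2] * x$voxel_size_um[2],
              x$shape_voxels[3] * x$voxel_size_um[3]))
  cat(sprintf("  vessels: %d (radius %.1f +/- %.1f um)\n",
              x$n_vessels, x$vessel_radius_um[["mean"]], x$vessel_radius_um[["sd"]]))
  cat(sprintf("  cells: %d, extravascular fraction %.2f, decay %.0f um\n",
              x$n_cells, x$extravascular_fraction_true, x$decay_length_um))
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  smoothing %.1f um | background sphere %.1f um | spots %.1f um (quality >= %g)\n",
              x$smoothing_detail_um, x$background_sphere_um,
              x$spot_diameter_um, x$spot_quality_min))
  cat(sprintf("  proximity %.1f um | bins %.1f um | escape quantile %.2f\n",
              x$proximity_um, x$bin_width_um, x$cumulative_quantile))
  invisible(x)
}
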