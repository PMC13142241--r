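# Volume-based extravasation analysis: voxel masking against the vessel mask,
# re-segmentation of the inside/outside channels, and the extravasation
# fraction and counts.

#' Split a cell channel into intravascular and extravascular signal
#'
#' Voxel masking against the vessel mask: the inside channel keeps the
#' original intensities on vascular voxels and is zero elsewhere; the outside
#' channel is the exact complement. The two reconstruct the input bitwise.
#'
#' @param channel 3D numeric array of a cell population.
#' @param mask A `vessel_mask` or logical array of matching shape.
#' @return List with `inside` and `outside` arrays.
#' @export
mask_population_channel <- function(channel, mask) {
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  check_volume(channel, "channel")
  if (!identical(dim(channel), dim(mask))) {
    abort("channel and vessel mask shapes differ")
  }
  inside <- channel
  inside[!mask] <- 0
  outside <- channel
  outside[mask] <- 0
  list(inside = inside, outside = outside)
}

#' Segmented population volumes inside and outside the vasculature
#'
#' Re-segments the masked channels independently at a common absolute
#' threshold (the procedure applied to each compartment after voxel masking)
#' and sums the object volumes. Using one absolute threshold for both
#' compartments makes the in/out volumes sum to the unmasked segmented volume.
#'
#' @param masked List with `inside`/`outside` from [mask_population_channel()].
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @param threshold Absolute intensity threshold shared by both compartments.
#' @param min_object_voxels Smallest component kept.
#' @return Named numeric: `V_in_um3`, `V_out_um3`.
#' @export
population_volumes <- function(masked, voxel_size_um, threshold,
                               min_object_voxels = 5L) {
  v_in <- segment_surfaces_absolute(masked$inside, voxel_size_um, threshold,
                                    min_object_voxels)
  v_out <- segment_surfaces_absolute(masked$outside, voxel_size_um, threshold,
                                     min_object_voxels)
  c(V_in_um3 = sum(v_in$objects$volume_um3),
    V_out_um3 = sum(v_out$objects$volume_um3))
}

#' Relative extravasation fraction
#'
#' `100 * V_out / (V_in + V_out)`: the percentage of the segmented population
#' volume lying outside the vessel mask.
#'
#' @param V_in_um3,V_out_um3 Non-negative volumes, micrometers^3.
#' @return Percentage in `[0, 100]`.
#' @export
extravasation_fraction <- function(V_in_um3, V_out_um3) {
  if (any(V_in_um3 < 0) || any(V_out_um3 < 0)) abort("volumes must be non-negative")
  total <- V_in_um3 + V_out_um3
  if (any(total <= 0)) {
    abort("extravasation fraction is undefined when the total population volume is zero")
  }
  100 * V_out_um3 / total
}

#' Count cells by vascular compartment
#'
#' @param population Cell tibble with a `compartment` column (from
#'   [assign_distances()]). Unassigned cells are excluded with a message.
#' @return Named integer: `n_extravasated`, `n_intravascular`.
#' @export
count_extravasated <- function(population) {
  if (!"compartment" %in% names(population)) {
    abort("`population` has no `compartment` column; run assign_distances() first")
  }
  n_un <- sum(population$compartment == "unassigned" | is.na(population$compartment))
  if (n_un > 0) {
    inform(sprintf("%d unassigned cell(s) excluded from compartment counts", n_un))
  }
  c(n_extravasated = sum(population$compartment == "extravascular", na.rm = TRUE),
    n_intravascular = sum(population$compartment == "intravascular", na.rm = TRUE))
}
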