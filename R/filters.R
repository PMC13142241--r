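# Pre-segmentation intensity filters: anisotropy-aware Gaussian smoothing and
# morphological top-hat background subtraction.

smoothing_sigma_vox <- function(smoothing_detail_um, voxel_size_um, warn_axes = TRUE) {
  sigma_um <- rep(smoothing_detail_um / 2, 3)
  sigma_vox <- sigma_um / voxel_size_um
  too_fine <- smoothing_detail_um < voxel_size_um
  if (any(too_fine)) {
    sigma_vox[too_fine] <- 0
    if (warn_axes) {
      warn(sprintf(
        "smoothing detail %.2f um is below the voxel size on axis %s; no smoothing applied there",
        smoothing_detail_um,
        paste(c("z", "y", "x")[too_fine], collapse = ", ")))
    }
  }
  sigma_vox
}

#' Surface-detail Gaussian smoothing of a channel
#'
#' Anisotropic Gaussian smoothing with physical sigma `smoothing_detail_um/2`
#' per axis, converted to voxels per axis, with reflecting boundaries (so the
#' mean intensity is preserved). Axes whose voxel pitch exceeds the detail are
#' left untouched, with a warning.
#'
#' @param channel 3D numeric array.
#' @param smoothing_detail_um Surface detail, micrometers.
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @return Smoothed array of identical shape.
#' @export
smooth_channel <- function(channel, smoothing_detail_um, voxel_size_um) {
  check_volume(channel, "channel")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (smoothing_detail_um <= 0) abort("`smoothing_detail_um` must be positive")
  sigma_vox <- smoothing_sigma_vox(smoothing_detail_um, voxel_size_um)
  array(cpp_gauss_blur(as.numeric(channel), dim(channel), sigma_vox), dim = dim(channel))
}

#' Morphological background subtraction (white top-hat)
#'
#' Subtracts the grey-scale opening of the channel under an
#' anisotropy-corrected ellipsoidal structuring element of the given physical
#' diameter, removing any background structure wider than the sphere while
#' retaining compact bright objects. The output is non-negative.
#'
#' @param channel 3D numeric array.
#' @param background_sphere_um Structuring-element diameter, micrometers.
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @return Background-corrected array.
#' @export
subtract_background <- function(channel, background_sphere_um, voxel_size_um) {
  check_volume(channel, "channel")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (background_sphere_um <= 0) abort("`background_sphere_um` must be positive")
  if (background_sphere_um / 2 < min(voxel_size_um)) {
    warn(sprintf("background sphere %.2f um is smaller than one voxel; channel returned unchanged",
                 background_sphere_um))
    return(channel)
  }
  d <- dim(channel)
  r <- background_sphere_um / 2
  eroded <- cpp_morph_ellipsoid(as.numeric(channel), d, voxel_size_um, r, FALSE)
  opened <- cpp_morph_ellipsoid(eroded, d, voxel_size_um, r, TRUE)
  array(pmax(as.numeric(channel) - opened, 0), dim = d)
}
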