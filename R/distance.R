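# Distance-to-vessel mapping and the distance-based summaries: per-cell
# distances, binned penetration profiles, and quantile escape distances.

#' Anisotropic Euclidean distance map outside the vessel mask
#'
#' Exact Euclidean distance transform of the complement of the vessel mask
#' with per-axis physical sampling: every voxel carries its minimum distance
#' in micrometers to the nearest vascular voxel; voxels inside the mask are 0.
#'
#' @param mask A `vessel_mask` from [build_vessel_mask()], or a logical array
#'   (then `voxel_size_um` is required).
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @return A `distance_map`: numeric array `values` plus geometry.
#' @export
distance_map_outside <- function(mask, voxel_size_um = NULL) {
  if (inherits(mask, "vessel_mask")) {
    voxel_size_um <- mask$voxel_size_um
    mask <- mask$mask
  }
  check_volume(mask, "mask")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (!any(mask)) abort("empty vessel mask: no reference surface for distances")
  vals <- cpp_edt(as.logical(mask), dim(mask), voxel_size_um)
  structure(list(values = array(vals, dim = dim(mask)),
                 voxel_size_um = voxel_size_um),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %s voxels, range 0 - %.1f um\n",
              paste(dim(x$values), collapse = " x "), max(x$values)))
  invisible(x)
}

#' Assign per-cell distances and compartments from a distance map
#'
#' Each cell samples the distance map at the voxel nearest its center; a cell
#' whose voxel lies inside the vessel mask is `intravascular` with distance 0,
#' otherwise `extravascular` with the sampled distance. Out-of-bounds centers
#' are flagged `unassigned` with a warning.
#'
#' @param population Cell tibble (from [spots_near_surfaces()] or any tibble
#'   with `center_z_um`, `center_y_um`, `center_x_um`).
#' @param dmap A `distance_map` from [distance_map_outside()].
#' @param mask The matching `vessel_mask` (or logical array).
#' @return The population tibble with `distance_um` and `compartment` columns.
#' @export
assign_distances <- function(population, dmap, mask) {
  stopifnot(inherits(dmap, "distance_map"))
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  d <- dim(dmap$values)
  if (nrow(population) == 0) {
    population$distance_um <- numeric(0)
    population$compartment <- character(0)
    return(population)
  }
  centers <- as.matrix(population[, c("center_z_um", "center_y_um", "center_x_um")])
  vox <- um_to_index(centers, dmap$voxel_size_um)
  inb <- index_in_bounds(vox, d)
  if (any(!inb)) {
    warn(sprintf("%d cell center(s) outside the volume were flagged unassigned", sum(!inb)))
  }
  vox[, 1] <- pmin(pmax(vox[, 1], 1L), d[1])
  vox[, 2] <- pmin(pmax(vox[, 2], 1L), d[2])
  vox[, 3] <- pmin(pmax(vox[, 3], 1L), d[3])
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
  dist <- dmap$values[lin]
  inside <- mask[lin]
  population$distance_um <- ifelse(inb, ifelse(inside, 0, dist), NA_real_)
  population$compartment <- ifelse(!inb, "unassigned",
                                   ifelse(inside, "intravascular", "extravascular"))
  population
}

#' Distance-binned penetration profile
#'
#' Histograms the extravascular cell distances into half-open bins
#' `[k*w, (k+1)*w)` and accumulates per-bin percentages into a cumulative
#' distribution; intravascular cells are carried as profile metadata, not
#' binned.
#'
#' @param population Cell tibble with `distance_um` and `compartment`.
#' @param bin_width_um Bin width, micrometers.
#' @param population_name Profile label; defaults to the population column.
#' @return A `penetration_profile` tibble: `bin_lo_um`, `bin_hi_um`, `count`,
#'   `percent`, `cumulative_percent`, with attributes `n_intravascular`,
#'   `bin_width_um` and `population_name`.
#' @export
bin_distances <- function(population, bin_width_um = 10,
                          population_name = NULL) {
  if (bin_width_um <= 0) abort("`bin_width_um` must be positive")
  population_name <- population_name %||%
    (if ("population" %in% names(population) && nrow(population) > 0)
      population$population[1] else "population")
  ex <- population[!is.na(population$compartment) &
                     population$compartment == "extravascular", , drop = FALSE]
  n_in <- sum(population$compartment == "intravascular", na.rm = TRUE)
  if (nrow(ex) == 0) {
    prof <- tibble::tibble(bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                           count = integer(0), percent = numeric(0),
                           cumulative_percent = numeric(0))
    return(new_penetration_profile(prof, n_in, bin_width_um, population_name, empty = TRUE))
  }
  k <- floor(ex$distance_um / bin_width_um)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  percent <- 100 * counts / sum(counts)
  prof <- tibble::tibble(
    bin_lo_um = (0:kmax) * bin_width_um,
    bin_hi_um = (1:(kmax + 1)) * bin_width_um,
    count = counts,
    percent = percent,
    cumulative_percent = cumsum(percent)
  )
  new_penetration_profile(prof, n_in, bin_width_um, population_name, empty = FALSE)
}

new_penetration_profile <- function(prof, n_intravascular, bin_width_um,
                                    population_name, empty) {
  structure(prof,
            n_intravascular = n_intravascular,
            bin_width_um = bin_width_um,
            population_name = population_name,
            empty = empty,
            class = c("penetration_profile", class(prof)))
}

#' Escape distance at a cumulative quantile
#'
#' The smallest observed distance `d` such that at least `quantile` of the
#' extravascular cells lie within `d` -- an empirical (inverse-CDF, type 1)
#' quantile of the raw distances. With the default 0.95 this is the cumulative
#' 95% escape distance.
#'
#' @param x Numeric distances, or a cell tibble with `distance_um` and
#'   `compartment` (extravascular cells are used).
#' @param quantile Cumulative fraction in (0, 1].
#' @return Escape distance, micrometers.
#' @export
escape_distance <- function(x, quantile = 0.95) {
  if (is.data.frame(x)) {
    x <- x$distance_um[!is.na(x$compartment) & x$compartment == "extravascular"]
  }
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("escape distance is undefined for an empty population")
  if (quantile <= 0 || quantile > 1) abort("`quantile` must lie in (0, 1]")
  xs <- sort(x)
  xs[ceiling(quantile * length(xs))]
}

#' Escape distance read off a binned profile
#'
#' Bin-resolution counterpart of [escape_distance()] for parity with plotted
#' cumulative profiles: the upper edge of the first bin whose cumulative
#' percentage reaches the quantile.
#'
#' @param profile A `penetration_profile`.
#' @param quantile Cumulative fraction in (0, 1].
#' @return Distance, micrometers.
#' @export
escape_distance_binned <- function(profile, quantile = 0.95) {
  stopifnot(inherits(profile, "penetration_profile"))
  if (nrow(profile) == 0) abort("escape distance is undefined for an empty profile")
  i <- which(profile$cumulative_percent >= 100 * quantile - 1e-9)[1]
  profile$bin_hi_um[i]
}
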