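# Penetration/cytotoxicity depth endpoints and cross-region aggregation.
# The same operation yields the cell penetration metrics (CPDmax/CPD50/CPA50)
# on an effector population and the cell death metrics (CDDmax/CDD50/CDA50)
# on an apoptotic population; there is no separate code path.

#' Penetration depth and amount metrics for one population
#'
#' `cpd_max_um` is the maximum extravascular cell distance, `cpd50_um` is
#' structurally half of it, and `cpa50` counts extravascular cells with
#' `0 < distance <= cpd50_um` (closed upper bound; boundary ties count).
#' Applied to an apoptotic (e.g. TUNEL-positive) population these are the
#' CDDmax/CDD50/CDA50 endpoints.
#'
#' @param population Cell tibble with `distance_um` and `compartment`.
#' @param population_name Label for the output row.
#' @return One-row tibble: `population`, `n_extravascular`, `cpd_max_um`,
#'   `cpd50_um`, `cpa50`.
#' @export
penetration_metrics <- function(population, population_name = NULL) {
  population_name <- population_name %||%
    (if ("population" %in% names(population) && nrow(population) > 0)
      population$population[1] else "population")
  ex <- population$distance_um[!is.na(population$compartment) &
                                 population$compartment == "extravascular"]
  if (length(ex) == 0) {
    abort("penetration metrics are undefined without extravascular cells")
  }
  cpd_max <- max(ex)
  cpd50 <- cpd_max / 2
  tibble::tibble(
    population = population_name,
    n_extravascular = length(ex),
    cpd_max_um = cpd_max,
    cpd50_um = cpd50,
    cpa50 = sum(ex > 0 & ex <= cpd50)
  )
}

#' Aggregate a metric across imaged regions
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of one
#' endpoint measured in several tumor regions, the form in which grouped
#' results are reported (mean +/- SD). Rounding is left to report time.
#'
#' @param values Numeric vector, one value per region.
#' @param metric_name Endpoint name.
#' @param units Unit string carried into reports.
#' @return One-row tibble: `metric_name`, `n_regions`, `mean`, `sd` (NA for a
#'   single region), `units`.
#' @export
aggregate_regions <- function(values, metric_name = "metric", units = "") {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no finite region values to aggregate")
  tibble::tibble(
    metric_name = metric_name,
    n_regions = length(values),
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else NA_real_,
    units = units
  )
}

#' Fold change between two group values
#'
#' @param value_a Numerator (e.g. the engineered-cell endpoint).
#' @param value_b Denominator; must be positive.
#' @return Ratio `value_a / value_b`, reported to one decimal.
#' @export
fold_change <- function(value_a, value_b) {
  if (any(value_b <= 0)) abort("fold change needs a positive denominator")
  round(value_a / value_b, 1)
}
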