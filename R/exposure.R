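#' Groundwater-consuming population raster
#'
#' Combines gridded rural and urban population with per-country rates of
#' domestic use of untreated groundwater:
#' `rural_pop * rural_fraction + urban_pop * urban_fraction`, the fractions
#' looked up by the cell's country id.
#'
#' @param rural,urban population `gw_raster`s on one grid.
#' @param usage data.frame with columns `country_id`, `rural_fraction`,
#'   `urban_fraction` (fractions in \[0, 1\]).
#' @param countries `gw_raster` of integer country ids on the same grid.
#' @return `gw_raster` of groundwater-consuming population.
#' @export
groundwater_population <- function(rural, urban, usage, countries) {
  stopifnot(same_grid(rural, urban), same_grid(rural, countries),
            all(c("country_id", "rural_fraction", "urban_fraction") %in% names(usage)))
  if (any(usage$rural_fraction < 0 | usage$rural_fraction > 1 |
          usage$urban_fraction < 0 | usage$urban_fraction > 1))
    stop("usage fractions must lie in [0, 1]")
  ids <- as.vector(countries$values)
  pop <- as.vector(rural$values) + as.vector(urban$values)
  need <- unique(ids[!is.na(ids) & pop > 0])
  missing_ids <- setdiff(need, usage$country_id)
  if (length(missing_ids))
    stop("no usage entry for country id(s): ",
         paste(sort(missing_ids), collapse = ", "))
  m <- match(ids, usage$country_id)
  rf <- usage$rural_fraction[m]; uf <- usage$urban_fraction[m]
  rf[is.na(rf)] <- 0; uf[is.na(uf)] <- 0
  v <- as.vector(rural$values) * rf + as.vector(urban$values) * uf
  gw_raster(matrix(v, nrow(rural$values), ncol(rural$values)),
            xmin = rural$xmin, ymin = rural$ymin, cellsize = rural$cellsize)
}

new_exposure_estimate <- function(method, cutoff, cells, consuming, map) {
  uncovered <- sum(as.vector(consuming$values)[is.na(map$values)], na.rm = TRUE)
  structure(list(method = method, cutoff = cutoff,
                 cells = cells,  # per-cell exposed persons (gw_raster)
                 total = sum(cells$values, na.rm = TRUE),
                 uncovered_population = uncovered),
            class = "exposure_estimate")
}

#' @export
print.exposure_estimate <- function(x, ...) {
  cat(sprintf("<exposure_estimate> method = %s%s, total = %.1f persons\n",
              x$method,
              if (is.na(x$cutoff)) "" else sprintf(" (cutoff %g)", x$cutoff),
              x$total))
  invisible(x)
}

check_exposure_inputs <- function(consuming, map) {
  stopifnot(inherits(consuming, "gw_raster"), inherits(map, "gw_raster"))
  if (!same_grid(consuming, map)) stop("population and hazard grids are misaligned")
  p <- map$values
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("hazard probabilities outside [0, 1]")
  invisible(TRUE)
}

#' High (probability-weighted) exposure estimate
#'
#' Every cell contributes its consuming population multiplied by the
#' modeled exceedance probability — a cell of 100 people at probability
#' 0.47 counts 47 persons. Nodata probability cells contribute zero and
#' are reported as uncovered population.
#'
#' @param consuming `gw_raster` from [groundwater_population()].
#' @param map hazard probability `gw_raster` on the same grid.
#' @return an `exposure_estimate` (method `"high"`).
#' @export
exposed_high <- function(consuming, map) {
  check_exposure_inputs(consuming, map)
  v <- consuming$values * map$values
  v[is.na(map$values)] <- 0
  cells <- gw_raster(v, xmin = map$xmin, ymin = map$ymin,
                     cellsize = map$cellsize)
  new_exposure_estimate("high", NA_real_, cells, consuming, map)
}

#' Low (cutoff-count) exposure estimate
#'
#' Counts the full consuming population of cells whose probability strictly
#' exceeds the cutoff (default 0.5, the sensitivity-specificity crossover
#' of a balanced model), without probability weighting.
#'
#' @inheritParams exposed_high
#' @param cutoff probability cutoff (default 0.5).
#' @return an `exposure_estimate` (method `"low"`).
#' @export
exposed_low <- function(consuming, map, cutoff = 0.5) {
  check_exposure_inputs(consuming, map)
  v <- consuming$values * (!is.na(map$values) & map$values > cutoff)
  cells <- gw_raster(v, xmin = map$xmin, ymin = map$ymin,
                     cellsize = map$cellsize)
  new_exposure_estimate("low", cutoff, cells, consuming, map)
}

#' Hybrid exposure estimate
#'
#' Probability-weighted count restricted to cells whose probability
#' strictly exceeds half the sensitivity-specificity crossover (0.25 for a
#' crossover of 0.5): low-probability cells are excluded, and the rest are
#' weighted by their probability. Always at most the high estimate.
#'
#' @inheritParams exposed_high
#' @param cutoff probability floor (default 0.25 = crossover/2).
#' @return an `exposure_estimate` (method `"hybrid"`).
#' @export
exposed_hybrid <- function(consuming, map, cutoff = 0.25) {
  check_exposure_inputs(consuming, map)
  v <- consuming$values * map$values *
    (!is.na(map$values) & map$values > cutoff)
  v[is.na(v)] <- 0
  cells <- gw_raster(v, xmin = map$xmin, ymin = map$ymin,
                     cellsize = map$cellsize)
  new_exposure_estimate("hybrid", cutoff, cells, consuming, map)
}

zonal_sum <- function(values, ids) {
  s <- tapply(as.vector(values), as.vector(ids), sum, na.rm = TRUE)
  stats::setNames(as.numeric(s), names(s))
}

#' Aggregate exposure estimates by country and continent
#'
#' Zonal sums of the three estimators' per-cell exposed persons over the
#' country raster, ranked descending by the hybrid estimate with the
#' (low, high) range alongside, plus continent totals and the share of each
#' continent's population affected.
#'
#' @param high,low,hybrid `exposure_estimate`s on one grid.
#' @param countries `gw_raster` of integer country ids.
#' @param continents data.frame with `country_id`, `continent`.
#' @param population optional total-population `gw_raster` for the
#'   percentage columns (`NA` percentages if omitted).
#' @return list with `country_table` (ranked), `continent_table`, `totals`.
#' @export
aggregate_exposure <- function(high, low, hybrid, countries, continents,
                               population = NULL) {
  stopifnot(inherits(high, "exposure_estimate"),
            inherits(low, "exposure_estimate"),
            inherits(hybrid, "exposure_estimate"),
            same_grid(high$cells, countries))
  ids <- countries$values
  ct <- data.frame(country_id = as.integer(names(zonal_sum(hybrid$cells$values, ids))))
  ct$hybrid <- zonal_sum(hybrid$cells$values, ids)
  ct$low <- zonal_sum(low$cells$values, ids)[as.character(ct$country_id)]
  ct$high <- zonal_sum(high$cells$values, ids)[as.character(ct$country_id)]
  if (!is.null(population)) {
    ct$population <- zonal_sum(population$values, ids)[as.character(ct$country_id)]
    ct$percent_affected <- 100 * ct$hybrid / ct$population
  } else {
    ct$population <- NA_real_
    ct$percent_affected <- NA_real_
  }
  ct$continent <- continents$continent[match(ct$country_id, continents$country_id)]
  ct <- ct[order(-ct$hybrid), , drop = FALSE]
  ct$rank <- seq_len(nrow(ct))
  rownames(ct) <- NULL
  agg <- function(col) tapply(ct[[col]], ct$continent, sum)
  cont <- data.frame(continent = names(agg("hybrid")),
                     hybrid = as.numeric(agg("hybrid")),
                     low = as.numeric(agg("low")),
                     high = as.numeric(agg("high")),
                     population = as.numeric(agg("population")))
  cont$percent_affected <- 100 * cont$hybrid / cont$population
  rownames(cont) <- NULL
  totals <- c(hybrid = sum(ct$hybrid), low = sum(ct$low), high = sum(ct$high))
  list(country_table = ct, continent_table = cont, totals = totals)
}
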