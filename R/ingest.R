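#' Deduplicate replicate well measurements
#'
#' Wells and springs often carry several measurements; before labeling, the
#' replicates of a well are collapsed to their arithmetic mean (averaging
#' always happens on the concentration scale, before binarization — the two
#' operations do not commute). Depth and any in-situ hydrochemistry columns
#' are averaged over their non-missing values. Rows with negative
#' concentrations are rejected with a warning.
#'
#' @param raw data.frame with at least `well_id` and `concentration`;
#'   `lon`/`lat` (taken from the first row per well — replicates share
#'   coordinates) and any additional numeric columns are averaged.
#' @return data.frame with one row per `well_id`; the number of rejected
#'   rows is attached as attribute `"n_rejected"`.
#' @export
dedupe_wells <- function(raw) {
  stopifnot(is.data.frame(raw),
            all(c("well_id", "concentration") %in% names(raw)))
  bad <- !is.na(raw$concentration) & raw$concentration < 0
  if (any(bad)) {
    warning(sprintf("rejecting %d row(s) with negative concentration", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  num_cols <- setdiff(names(raw)[vapply(raw, is.numeric, TRUE)],
                      c("lon", "lat"))
  first_cols <- setdiff(names(raw), num_cols)
  ord <- !duplicated(raw$well_id)
  out <- raw[ord, first_cols, drop = FALSE]
  for (cl in num_cols) {
    m <- tapply(raw[[cl]], raw$well_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    out[[cl]] <- as.numeric(m[match(out$well_id, names(m))])
  }
  out <- out[, names(raw), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Binarize concentrations against the guideline threshold
#'
#' Exceedance is strict: a measurement exactly at the guideline is labeled
#' 0 (the prevalence convention is the share of measurements *above*
#' 1.5 mg/L).
#'
#' @param concentration numeric vector (mg/L, non-negative).
#' @param threshold guideline concentration (default 1.5 mg/L, the WHO
#'   drinking-water guideline for fluoride).
#' @return integer 0/1 vector (`NA` in, `NA` out).
#' @export
binarize <- function(concentration, threshold = 1.5) {
  stopifnot(all(concentration >= 0, na.rm = TRUE))
  as.integer(concentration > threshold)
}

#' Extract covariate values at well locations
#'
#' Looks up every band of the stack at each point's containing cell (each
#' band at its own native resolution — block replication onto a finer grid
#' would return identical values). Points outside the grid extent, and
#' points hitting a missing cell in any band, are dropped with a message.
#'
#' @param points data.frame with `lon`, `lat` and any label/metadata
#'   columns to carry through.
#' @param stack a [covariate_stack()].
#' @return `points` restricted to usable rows, with one numeric column
#'   appended per band; counts of dropped points are attached as
#'   attributes `"n_outside"` and `"n_nodata"`.
#' @export
extract_covariates <- function(points, stack) {
  stopifnot(is.data.frame(points), all(c("lon", "lat") %in% names(points)),
            inherits(stack, "covariate_stack"))
  vals <- lapply(stack$bands, raster_lookup, x = points$lon, y = points$lat)
  idx <- cell_index(stack$bands[[1]], points$lon, points$lat)
  outside <- is.na(idx$row)
  if (all(outside)) stop("all points fall outside the raster extent")
  vm <- do.call(cbind, vals)
  nodata <- !outside & apply(is.na(vm), 1, any)
  keep <- !outside & !nodata
  if (any(!keep)) {
    message(sprintf("dropped %d point(s) outside the extent and %d with missing covariates",
                    sum(outside), sum(nodata)))
  }
  out <- cbind(points[keep, , drop = FALSE],
               as.data.frame(vm[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_outside") <- sum(outside)
  attr(out, "n_nodata") <- sum(nodata)
  out
}
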