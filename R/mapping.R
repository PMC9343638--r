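#' Harmonize a covariate stack onto its finest grid
#'
#' Coarse bands (whose cell size is an integer multiple of the finest) are
#' block-replicated (nearest-neighbour) onto the fine grid; values are
#' unchanged, so the value set of every band is preserved exactly. Bands
#' already at the finest resolution pass through untouched.
#'
#' @param stack a [covariate_stack()].
#' @return a `covariate_stack` in which every band shares the finest grid.
#' @export
harmonize_stack <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  cs <- stack_cellsizes(stack)
  fine <- min(cs)
  bands <- lapply(stack$bands, function(b) {
    ratio <- b$cellsize / fine
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("coarse cell size is not an integer multiple of the finest")
    ratio <- as.integer(round(ratio))
    if (ratio == 1L) return(b)
    v <- kronecker(b$values, matrix(1, ratio, ratio))
    gw_raster(v, xmin = b$xmin, ymin = b$ymin, cellsize = fine)
  })
  covariate_stack(bands, unname(stack$kind))
}

#' Apply a fitted model across a covariate stack
#'
#' Produces the hazard map: the per-cell probability that groundwater
#' exceeds the guideline, computed by evaluating the forest on every cell
#' of the harmonized stack. Cells with a missing value in any selected band
#' propagate to nodata. Evaluation is chunked so the vote matrix stays
#' bounded in memory.
#'
#' @param model a `balanced_forest`.
#' @param stack a [covariate_stack()] containing all selected feature bands.
#' @param chunk_size cells evaluated per block.
#' @return a `gw_raster` of probabilities on the finest grid, with the
#'   nodata cell count attached as attribute `"n_nodata"`.
#' @export
predict_map <- function(model, stack, chunk_size = 50000L) {
  stopifnot(inherits(model, "balanced_forest"),
            inherits(stack, "covariate_stack"))
  missing_bands <- setdiff(model$features, names(stack$bands))
  if (length(missing_bands))
    stop("stack lacks feature band(s): ", paste(missing_bands, collapse = ", "))
  hs <- harmonize_stack(stack)
  g <- hs$bands[[model$features[1]]]
  cells <- data.frame(lapply(hs$bands[model$features],
                             function(b) as.vector(b$values)))
  names(cells) <- model$features
  ok <- !apply(is.na(cells), 1, any)
  prob <- rep(NA_real_, nrow(cells))
  if (any(ok)) {
    prob[ok] <- predict(model, cells[ok, , drop = FALSE], type = "prob",
                        chunk_size = chunk_size)
  }
  out <- gw_raster(matrix(prob, nrow(g$values), ncol(g$values)),
                   xmin = g$xmin, ymin = g$ymin, cellsize = g$cellsize)
  attr(out, "n_nodata") <- sum(!ok)
  out
}

#' Areal fraction above a probability cutoff
#'
#' Fraction of the (optionally masked, optionally area-weighted) region in
#' which the modeled probability strictly exceeds the cutoff — e.g. the
#' share of a continent with a greater than 50% probability of exceedance.
#'
#' @param map probability `gw_raster`.
#' @param mask optional logical/0-1 `gw_raster` on the same grid selecting
#'   the region (`NULL` = whole grid).
#' @param cutoff probability cutoff (default 0.5; strict comparison).
#' @param cell_areas optional `gw_raster` of per-cell areas for
#'   latitude-corrected weighting; `NULL` weights all cells equally.
#' @return fraction in \[0, 1\], over non-nodata region cells.
#' @export
area_fraction_above <- function(map, mask = NULL, cutoff = 0.5,
                                cell_areas = NULL) {
  stopifnot(inherits(map, "gw_raster"))
  p <- as.vector(map$values)
  sel <- !is.na(p)
  if (!is.null(mask)) {
    stopifnot(same_grid(map, mask))
    sel <- sel & !is.na(mask$values) & as.vector(mask$values) > 0
  }
  if (!any(sel)) stop("empty region")
  w <- if (is.null(cell_areas)) rep(1, length(p)) else {
    stopifnot(same_grid(map, cell_areas))
    as.vector(cell_areas$values)
  }
  sum(w[sel] * (p[sel] > cutoff)) / sum(w[sel])
}
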