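#' Planar grid raster
#'
#' A minimal in-memory raster: a numeric matrix on a regular planar grid.
#' Row 1 is the northernmost row (the usual raster convention); cell centres
#' are at `xmin + (col - 0.5) * cellsize` and `ymin + (nrow - row + 0.5) *
#' cellsize`. Missing cells are `NA`.
#'
#' @param values numeric matrix (rows x cols), row 1 = top.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize side length of a (square) cell, in map units.
#' @return an object of class `gw_raster`.
#' @export
gw_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values), cellsize > 0)
  storage.mode(values) <- "double"
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "gw_raster")
}

#' @export
print.gw_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gw_raster> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              d[1], d[2], x$cellsize, x$xmin, x$ymin))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.gw_raster <- function(x) dim(x$values)

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$cellsize
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' Do two rasters share the same grid?
#' @param a,b `gw_raster` objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

#' Map point coordinates to raster row/column indices
#'
#' Cells are half-open intervals `[x0, x1)` on both axes; points lying
#' exactly on the maximum x or y boundary map to the last cell. Points
#' outside the extent get `NA` indices.
#'
#' @param r a `gw_raster`.
#' @param x,y point coordinates.
#' @return data.frame with integer columns `row`, `col` (`NA` = outside).
#' @export
cell_index <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row_from_bottom <- floor((y - r$ymin) / r$cellsize) + 1L
  # max-boundary points belong to the last cell
  col[x == raster_xmax(r)] <- nc
  row_from_bottom[y == raster_ymax(r)] <- nr
  row <- nr - row_from_bottom + 1L
  out <- col < 1L | col > nc | row < 1L | row > nr
  col[out] <- NA_integer_; row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Look up raster values at point coordinates
#' @inheritParams cell_index
#' @return numeric vector (`NA` for points outside the extent).
#' @export
raster_lookup <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  v <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  v[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  v
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced grid format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from north to south).
#'
#' @param r a `gw_raster`.
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "gw_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", format(r$xmin, digits = 15)),
           paste("yllcorner", format(r$ymin, digits = 15)),
           paste("cellsize", format(r$cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return a `gw_raster` with nodata cells as `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals["nrows"], ncol(m) == vals["ncols"])
  m[m == vals[["nodata_value"]]] <- NA_real_
  gw_raster(m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]])
}

#' Assemble a covariate stack
#'
#' Bands may sit at different (integer-multiple) resolutions but must cover
#' the same extent; [harmonize_stack()] puts them all on the finest grid.
#'
#' @param bands named list of `gw_raster` objects.
#' @param kind character vector, `"continuous"` or `"categorical"` per band
#'   (recycled if length 1).
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(bands, kind = "continuous") {
  stopifnot(is.list(bands), length(bands) >= 1,
            !is.null(names(bands)), all(nzchar(names(bands))))
  kind <- rep_len(kind, length(bands))
  stopifnot(all(kind %in% c("continuous", "categorical")))
  ext <- function(r) c(r$xmin, r$ymin, raster_xmax(r), raster_ymax(r))
  e0 <- ext(bands[[1]])
  for (b in bands) {
    if (!isTRUE(all.equal(ext(b), e0)))
      stop("all bands must share one extent")
  }
  structure(list(bands = bands, kind = stats::setNames(kind, names(bands))),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d bands\n", length(x$bands)))
  for (nm in names(x$bands)) {
    d <- dim(x$bands[[nm]]$values)
    cat(sprintf("  %s (%s): %d x %d, cellsize %g\n", nm, x$kind[nm],
                d[1], d[2], x$bands[[nm]]$cellsize))
  }
  invisible(x)
}

stack_cellsizes <- function(stack)
  vapply(stack$bands, function(b) b$cellsize, 0)
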