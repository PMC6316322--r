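# Georeferenced raster grid: construction, ESRI ASCII I/O, cell indexing.

#' Construct a raster grid
#'
#' A `gn_grid` is a single georeferenced raster layer: a numeric matrix whose
#' first row is the northernmost row, plus the six-field ESRI ASCII header.
#' Coordinates are treated as planar; no reprojection is performed.
#'
#' @param values Numeric matrix, `nrows x ncols`, row 1 = northernmost row.
#'   `NA` entries are treated as nodata.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner of the
#'   lower-left cell.
#' @param cellsize Cell edge length (map units, e.g. degrees); must be > 0.
#' @param nodata_value Value used to serialize nodata cells (default -9999).
#' @return An object of class `gn_grid`.
#' @export
gn_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                    nodata_value = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (cellsize <= 0) stop("`cellsize` must be > 0")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values other than NA are not allowed in a grid")
  g <- structure(
    list(ncols = ncol(values), nrows = nrow(values),
         xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
         cellsize = as.numeric(cellsize),
         nodata_value = as.numeric(nodata_value),
         values = values),
    class = "gn_grid")
  g
}

#' @export
print.gn_grid <- function(x, ...) {
  nval <- sum(!is.na(x$values))
  cat(sprintf("<gn_grid> %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner))
  cat(sprintf("  valid cells: %d / %d", nval, x$nrows * x$ncols))
  if (nval > 0)
    cat(sprintf("; range [%g, %g]", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.gn_grid <- function(x, ...) x$values

#' @rdname gn_grid
#' @param x Object to test.
#' @export
is_gn_grid <- function(x) inherits(x, "gn_grid")

grid_header <- function(g)
  list(ncols = g$ncols, nrows = g$nrows, xllcorner = g$xllcorner,
       yllcorner = g$yllcorner, cellsize = g$cellsize)

same_header <- function(a, b, tol = 1e-9) {
  ha <- grid_header(a); hb <- grid_header(b)
  mism <- character(0)
  for (f in names(ha))
    if (abs(ha[[f]] - hb[[f]]) > tol * max(1, abs(ha[[f]]))) mism <- c(mism, f)
  mism
}

#' Read an ESRI ASCII grid
#'
#' Accepts both the `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` header
#' dialects; center-registered origins are normalized to the corner convention
#' by subtracting half a cell. Cells equal to the declared `NODATA_value`
#' become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [gn_grid].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7) stop("malformed ASCII grid (fewer than 6 header lines + data): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed header line %d: '%s'", i, lines[i]))
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop(sprintf("malformed header line %d (non-numeric value): '%s'", i, lines[i]))
    hdr[[key]] <- val
  }
  need_xy <- function(corner, center, size) {
    if (!is.null(hdr[[corner]])) return(hdr[[corner]])
    if (!is.null(hdr[[center]])) return(hdr[[center]] - size / 2)
    stop("header missing ", corner, " / ", center)
  }
  for (k in c("ncols", "nrows", "cellsize", "nodata_value"))
    if (is.null(hdr[[k]])) stop("header missing field: ", k)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cellsize <- hdr$cellsize
  if (is.na(ncols) || ncols <= 0 || is.na(nrows) || nrows <= 0)
    stop("malformed header: ncols/nrows must be positive integers")
  if (cellsize <= 0) stop("malformed header: cellsize must be > 0")
  xll <- need_xy("xllcorner", "xllcenter", cellsize)
  yll <- need_xy("yllcorner", "yllcenter", cellsize)
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))))
  if (anyNA(vals)) stop("non-numeric cell value in ", path)
  if (length(vals) != nrows * ncols)
    stop(sprintf("dimension error: header declares %d x %d = %d cells but file has %d",
                 nrows, ncols, nrows * ncols, length(vals)))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  gn_grid(m, xll, yll, cellsize, hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Always writes the corner-registered dialect. Values are printed with 17
#' significant digits, enough to round-trip IEEE doubles exactly; `NA` cells
#' are written as the grid's `nodata_value`.
#'
#' @param grid A [gn_grid].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(is_gn_grid(grid))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", fmt(grid$xllcorner)),
    paste("yllcorner", fmt(grid$yllcorner)),
    paste("cellsize", fmt(grid$cellsize)),
    paste("NODATA_value", fmt(grid$nodata_value))), con)
  m <- grid$values
  m[is.na(m)] <- grid$nodata_value
  writeLines(apply(m, 1, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Locate the cells containing points
#'
#' Cells are half-open intervals `[origin, origin + cellsize)`: a point on the
#' top or left edge of the grid belongs to row/column 1, a point on the bottom
#' or right boundary is out of extent.
#'
#' @param grid A [gn_grid] (or anything with the same header fields).
#' @param lon,lat Numeric vectors of point coordinates.
#' @return A data.frame with integer columns `row`, `col` (NA when the point
#'   is outside the extent) and `cell`, the 1-based linear cell index
#'   `(row - 1) * ncols + col`.
#' @export
cell_index <- function(grid, lon, lat) {
  ytop <- grid$yllcorner + grid$nrows * grid$cellsize
  row <- floor((ytop - lat) / grid$cellsize) + 1
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1
  # points exactly on the top/left edge belong to row/col 1
  row[lat == ytop] <- 1
  col[lon == grid$xllcorner] <- 1
  bad <- row < 1 | row > grid$nrows | col < 1 | col > grid$ncols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1) * grid$ncols + col))
}

# Center coordinates of linear cell indices.
cell_center <- function(grid, cell) {
  row <- (cell - 1) %/% grid$ncols + 1
  col <- (cell - 1) %% grid$ncols + 1
  ytop <- grid$yllcorner + grid$nrows * grid$cellsize
  data.frame(lon = grid$xllcorner + (col - 0.5) * grid$cellsize,
             lat = ytop - (row - 0.5) * grid$cellsize)
}

# Value at linear cell indices.
cell_value <- function(grid, cell) {
  row <- (cell - 1) %/% grid$ncols + 1
  col <- (cell - 1) %% grid$ncols + 1
  grid$values[cbind(row, col)]
}
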