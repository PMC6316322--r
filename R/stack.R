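# Aligned multi-layer raster stacks and value extraction.

# Canonical vocabulary for monthly overwintering-season climate layers.
CLIMATE_VARIABLES <- c("solar_radiation", "vapor_pressure", "precipitation",
                       "wind_speed", "tmean", "tmin", "tmax")
OVERWINTER_MONTHS <- c("Oct", "Nov", "Dec", "Jan", "Feb")

#' Compose / parse a layer name
#'
#' Layers are named `<variable>_<month>`, e.g. `"tmin_Jan"`, with variables
#' drawn from the seven monthly climate variables (solar radiation, water
#' vapor pressure, total precipitation, wind speed, mean/min/max temperature)
#' and months from the five-month overwintering season (October-February).
#'
#' @param variable Climate variable name (see `CLIMATE_VARIABLES`).
#' @param month Three-letter month (see `OVERWINTER_MONTHS`).
#' @return `layer_name()`: a character name. `parse_layer_name()`: a
#'   data.frame with columns `variable` and `month`.
#' @export
layer_name <- function(variable, month) {
  if (!all(variable %in% CLIMATE_VARIABLES))
    stop("unknown climate variable: ", paste(setdiff(variable, CLIMATE_VARIABLES), collapse = ", "))
  if (!all(month %in% OVERWINTER_MONTHS))
    stop("unknown overwintering month: ", paste(setdiff(month, OVERWINTER_MONTHS), collapse = ", "))
  paste(variable, month, sep = "_")
}

#' @rdname layer_name
#' @param name Character vector of layer names.
#' @export
parse_layer_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([A-Za-z]{3})$", name))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) stop("not a <variable>_<month> layer name: ", paste(name[bad], collapse = ", "))
  data.frame(variable = vapply(m, `[`, "", 2), month = vapply(m, `[`, "", 3),
             row.names = name)
}

#' Build an aligned layer stack
#'
#' A `gn_stack` is an ordered, named collection of [gn_grid] layers sharing
#' one header. The valid-cell mask is the intersection of the layers'
#' non-nodata cells: a cell missing in any layer is excluded from background
#' sampling, correlation, and projection.
#'
#' @param layers Named list of [gn_grid] objects.
#' @return An object of class `gn_stack` with elements `layers`, `mask`
#'   (logical matrix of jointly valid cells) and `valid_cells` (linear cell
#'   indices of mask == TRUE).
#' @export
gn_stack <- function(layers) {
  if (length(layers) == 0) stop("empty layer stack")
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers)))
    stop("layers must have unique non-empty names")
  stopifnot(all(vapply(layers, is_gn_grid, TRUE)))
  ref <- layers[[1]]
  for (nm in names(layers)[-1]) {
    mism <- same_header(ref, layers[[nm]])
    if (length(mism))
      stop(sprintf("alignment error: layer '%s' differs from '%s' in: %s",
                   nm, names(layers)[1], paste(mism, collapse = ", ")))
  }
  mask <- Reduce(`&`, lapply(layers, function(g) !is.na(g$values)))
  vc <- which(t(mask))  # linear index (row-1)*ncols + col
  structure(list(layers = layers, mask = mask, valid_cells = as.integer(vc)),
            class = "gn_stack")
}

#' @export
print.gn_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<gn_stack> %d layers, %d x %d cells, %d jointly valid\n",
              length(x$layers), g$nrows, g$ncols, length(x$valid_cells)))
  cat("  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.gn_stack <- function(x) length(x$layers)

#' @export
names.gn_stack <- function(x) names(x$layers)

#' @export
`[.gn_stack` <- function(x, i) gn_stack(x$layers[i])

stack_header <- function(stack) grid_header(stack$layers[[1]])

#' Load a stack of ESRI ASCII grids from disk
#'
#' @param paths Named character vector: `layer name -> file path`.
#' @return A [gn_stack].
#' @export
load_stack <- function(paths) {
  if (is.null(names(paths))) stop("`paths` must be a named vector (layer name -> path)")
  gn_stack(lapply(paths, read_ascii_grid))
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' @param stack A [gn_stack].
#' @param dir Output directory (created if absent); files are `<name>.asc`.
#' @return Invisibly, the written paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (i in seq_along(paths)) write_ascii_grid(stack$layers[[i]], paths[i])
  invisible(setNames(paths, names(stack$layers)))
}

# Matrix (valid cells x layers) of layer values at the stack's valid cells,
# or at an arbitrary vector of linear cell indices.
stack_values <- function(stack, cells = stack$valid_cells) {
  out <- vapply(stack$layers, function(g) cell_value(g, cells),
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  out
}

#' Extract layer values at point locations
#'
#' Returns the value of the cell containing each point (cell-center
#' registration, half-open cells). Points on jointly-nodata cells yield `NA`
#' rows and are flagged; points outside the extent are an error.
#'
#' @param stack A [gn_stack].
#' @param lon,lat Point coordinates.
#' @return A numeric matrix (points x layers) with attribute `"nodata"`, a
#'   logical vector marking points that fell on invalid cells.
#' @export
extract_values <- function(stack, lon, lat) {
  g <- stack$layers[[1]]
  idx <- cell_index(g, lon, lat)
  if (anyNA(idx$cell))
    stop("point(s) outside extent at index: ",
         paste(which(is.na(idx$cell)), collapse = ", "))
  out <- stack_values(stack, idx$cell)
  nodata <- !stack$mask[cbind(idx$row, idx$col)]
  out[nodata, ] <- NA_real_
  attr(out, "nodata") <- nodata
  rownames(out) <- NULL
  out
}
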