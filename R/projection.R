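# Model transfer onto altered layer stacks, with clamping and
# distribution-shift diagnostics.

#' Project a fitted model onto a layer stack
#'
#' Rebuilds the model's features on the target stack using the training-time
#' scaling ranges. With `clamp = TRUE` (the default, the customary transfer
#' convention) feature transforms falling outside their training range are
#' pinned to it, and the number of clamped entries is recorded. The raw
#' distribution is renormalized over the target stack's valid cells, while
#' the logistic transform reuses the training entropy `H` (set
#' `recompute_entropy = TRUE` to use the target-background entropy instead,
#' for sensitivity checks). Projecting onto the training stack reproduces the
#' training surface.
#'
#' @param model A `maxent_model`.
#' @param stack A [gn_stack] supplying every layer the model references.
#' @param clamp Clamp features to their training ranges (default TRUE).
#' @param recompute_entropy Use the entropy of the projected distribution in
#'   the logistic transform (default FALSE).
#' @return A `probability_surface`: a [gn_grid] of logistic outputs with
#'   provenance attributes (`clamped`, counts of clamped feature values;
#'   `model_beta`; `recompute_entropy`).
#' @export
project_model <- function(model, stack, clamp = TRUE,
                          recompute_entropy = FALSE) {
  missing_layers <- setdiff(model$layers, names(stack$layers))
  if (length(missing_layers))
    stop("projection stack is missing required layer(s): ",
         paste(missing_layers, collapse = ", "))
  cells <- stack$valid_cells
  V <- stack_values(stack, cells)  # cells x layers (raw values)
  meta <- model$meta
  n_clamped <- 0L
  eta <- numeric(length(cells))
  for (i in seq_len(nrow(meta))) {
    mr <- meta[i, ]
    raw <- switch(mr$class,
      linear = V[, mr$parent1],
      quadratic = V[, mr$parent1]^2,
      product = V[, mr$parent1] * V[, mr$parent2],
      stop("unknown feature class: ", mr$class))
    if (clamp) {
      out_of_range <- raw < mr$lo | raw > mr$hi
      n_clamped <- n_clamped + sum(out_of_range)
      raw <- pmin(pmax(raw, mr$lo), mr$hi)
    }
    f <- (raw - mr$lo) / (mr$hi - mr$lo)
    eta <- eta + model$lambdas[i] * f
  }
  lnZ <- logsumexp(eta)
  q <- exp(eta - lnZ)
  H <- if (recompute_entropy) -sum(q * log(q)) else model$entropy
  eHq <- exp(H) * q
  p <- eHq / (1 + eHq)
  g <- stack$layers[[1]]
  m <- matrix(NA_real_, g$nrows, g$ncols)
  row <- (cells - 1) %/% g$ncols + 1
  col <- (cells - 1) %% g$ncols + 1
  m[cbind(row, col)] <- p
  surf <- gn_grid(m, g$xllcorner, g$yllcorner, g$cellsize, g$nodata_value)
  class(surf) <- c("probability_surface", class(surf))
  attr(surf, "clamped") <- n_clamped
  attr(surf, "model_beta") <- model$beta
  attr(surf, "recompute_entropy") <- recompute_entropy
  surf
}

#' @export
predict.maxent_model <- function(object, stack, clamp = TRUE,
                                 recompute_entropy = FALSE, ...)
  project_model(object, stack, clamp = clamp,
                recompute_entropy = recompute_entropy)

#' @export
print.probability_surface <- function(x, ...) {
  cat("<probability_surface> ")
  NextMethod()
  cat(sprintf("  clamped feature values: %d\n", attr(x, "clamped") %||% 0L))
  invisible(x)
}

#' Plot a probability surface
#' @param x A `probability_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.probability_surface <- function(x, ...) {
  m <- x$values
  graphics::image(x = x$xllcorner + (seq_len(x$ncols) - 0.5) * x$cellsize,
                  y = x$yllcorner + (seq_len(x$nrows) - 0.5) * x$cellsize,
                  z = t(m[x$nrows:1, , drop = FALSE]),
                  xlab = "lon", ylab = "lat", ...)
  invisible(x)
}

#' Cells above probability thresholds
#'
#' @param surface A `probability_surface`.
#' @param thresholds Numeric thresholds in `[0, 1]`.
#' @return Named integer vector: count of valid cells with `p >= threshold`.
#' @export
area_above_threshold <- function(surface, thresholds) {
  p <- surface$values[!is.na(surface$values)]
  setNames(vapply(thresholds, function(t) sum(p >= t), integer(1)),
           as.character(thresholds))
}

#' Correlation between a probability surface and elevation
#'
#' Pearson correlation over cells valid in both grids; the headline
#' diagnostic for elevation-tracking distribution shifts under warming.
#'
#' @param surface A `probability_surface`.
#' @param elevation A [gn_grid], aligned with the surface.
#' @return Pearson r.
#' @export
elevation_correlation <- function(surface, elevation) {
  mism <- same_header(surface, elevation)
  if (length(mism))
    stop("alignment error between surface and elevation: ",
         paste(mism, collapse = ", "))
  ok <- !is.na(surface$values) & !is.na(elevation$values)
  if (sum(ok) < 2) stop("fewer than 2 shared valid cells")
  cor(surface$values[ok], elevation$values[ok])
}

#' Cellwise difference of two aligned surfaces
#'
#' @param current,future Aligned `probability_surface` objects.
#' @return A [gn_grid] of `future - current`; nodata propagates.
#' @export
difference_map <- function(current, future) {
  mism <- same_header(current, future)
  if (length(mism))
    stop("alignment error between surfaces: ", paste(mism, collapse = ", "))
  gn_grid(future$values - current$values, current$xllcorner,
          current$yllcorner, current$cellsize, current$nodata_value)
}

#' Distribution-shift report between two surfaces
#'
#' Summarizes how a projected surface differs from the current one: cell
#' counts above each threshold, elevation correlations, and the difference
#' map's mean/min/max.
#'
#' @param current,future Aligned `probability_surface` objects.
#' @param elevation Aligned elevation [gn_grid].
#' @param thresholds Probability thresholds (default `seq(0.1, 0.9, 0.1)`).
#' @return A list of class `shift_report`.
#' @export
shift_report <- function(current, future, elevation,
                         thresholds = seq(0.1, 0.9, by = 0.1)) {
  d <- difference_map(current, future)
  dv <- d$values[!is.na(d$values)]
  structure(list(
    thresholds = thresholds,
    area_current = area_above_threshold(current, thresholds),
    area_future = area_above_threshold(future, thresholds),
    elev_r_current = elevation_correlation(current, elevation),
    elev_r_future = elevation_correlation(future, elevation),
    diff_mean = mean(dv), diff_min = min(dv), diff_max = max(dv)),
    class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report>\n")
  cat(sprintf("  elevation correlation: current %.3f -> future %.3f\n",
              x$elev_r_current, x$elev_r_future))
  cat(sprintf("  difference (future - current): mean %.4f, range [%.4f, %.4f]\n",
              x$diff_mean, x$diff_min, x$diff_max))
  df <- data.frame(threshold = x$thresholds,
                   cells_current = as.integer(x$area_current),
                   cells_future = as.integer(x$area_future))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Crop a surface to a rectangular sub-extent
#'
#' Post-processing crop (never a refit): cells outside the window become
#' nodata, mirroring the practice of modelling over a broad background and
#' clipping the reporting region from the result.
#'
#' @param surface A `probability_surface` or [gn_grid].
#' @param xmin,xmax,ymin,ymax Window bounds in map units.
#' @return A grid of identical extent with outside cells set to nodata.
#' @export
crop_surface <- function(surface, xmin, xmax, ymin, ymax) {
  g <- surface
  cx <- g$xllcorner + (seq_len(g$ncols) - 0.5) * g$cellsize
  cy <- g$yllcorner + g$nrows * g$cellsize - (seq_len(g$nrows) - 0.5) * g$cellsize
  keep <- outer(cy >= ymin & cy <= ymax, cx >= xmin & cx <= xmax, `&`)
  m <- g$values
  m[!keep] <- NA_real_
  out <- gn_grid(m, g$xllcorner, g$yllcorner, g$cellsize, g$nodata_value)
  class(out) <- class(surface)
  attr(out, "clamped") <- attr(surface, "clamped")
  attr(out, "model_beta") <- attr(surface, "model_beta")
  out
}
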