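# Feature construction for the maximum-entropy model: linear, quadratic and
# pairwise-product transforms of the layers, affinely rescaled to [0,1] over
# the training background.

#' Choose background cells for model training
#'
#' All jointly valid cells are used when there are at most `max_background`;
#' otherwise a seeded uniform sample of `max_background` valid cells is drawn.
#' Presence cells are always included in the background.
#'
#' @param stack A [gn_stack].
#' @param presence_cells Linear cell indices of presences.
#' @param max_background Background-size ceiling (default 10000).
#' @param seed Integer seed for the background sample.
#' @return Sorted integer vector of background cell indices.
#' @export
choose_background <- function(stack, presence_cells = integer(0),
                              max_background = 10000, seed = 1) {
  vc <- stack$valid_cells
  if (!all(presence_cells %in% vc))
    stop("presence cell(s) outside the stack's valid mask")
  if (length(vc) <= max_background) return(sort(vc))
  bg <- with_seed(substream_seed(seed, "background"),
                  sample(vc, max_background))
  sort(unique(c(bg, presence_cells)))
}

#' Build the model feature space
#'
#' Constructs the design matrix over background cells and the presence
#' feature matrix. Feature classes: `linear` (the layer itself), `quadratic`
#' (its square), `product` (pairwise products of distinct layers). Each
#' feature column is an affine rescale of its raw transform to `[0,1]` over
#' the background; the raw min/max are recorded per feature and later serve
#' as clamp ranges during projection. Layers constant over the background are
#' dropped with a warning.
#'
#' @param stack A [gn_stack].
#' @param presence_cells Linear indices of presence cells (must be valid).
#' @param classes Subset of `c("linear", "quadratic", "product")`.
#' @param background_cells Optional explicit background; defaults to
#'   [choose_background()].
#' @param max_background,seed Passed to [choose_background()].
#' @return An object of class `maxent_features`: `design` (background x
#'   features, in `[0,1]`), `pres` (presences x features), `meta` (per-feature
#'   class, parents, raw lo/hi), `layers`, `background_cells`,
#'   `presence_cells`.
#' @export
build_features <- function(stack, presence_cells,
                           classes = c("linear", "quadratic", "product"),
                           background_cells = NULL, max_background = 10000,
                           seed = 1) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (length(presence_cells) < 1) stop("at least one presence cell is required")
  if (is.null(background_cells))
    background_cells <- choose_background(stack, presence_cells,
                                          max_background, seed)
  B <- stack_values(stack, background_cells)
  P <- stack_values(stack, presence_cells)
  if (anyNA(B) || anyNA(P)) stop("background or presence cells include nodata")

  keep <- apply(B, 2, function(v) diff(range(v)) > 0)
  if (any(!keep))
    warning("dropping constant layer(s) over background: ",
            paste(colnames(B)[!keep], collapse = ", "))
  if (!any(keep)) stop("no non-constant layers available")
  B <- B[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  layers <- colnames(B)

  cols_bg <- list(); cols_pr <- list()
  meta <- list()
  add <- function(raw_bg, raw_pr, name, class, p1, p2 = NA_character_) {
    lo <- min(raw_bg); hi <- max(raw_bg)
    if (hi - lo <= 0) return(invisible(NULL))  # degenerate transform
    i <- length(cols_bg) + 1L
    cols_bg[[i]] <<- (raw_bg - lo) / (hi - lo)
    cols_pr[[i]] <<- (raw_pr - lo) / (hi - lo)
    meta[[i]] <<- data.frame(feature = name, class = class, parent1 = p1,
                             parent2 = p2, lo = lo, hi = hi,
                             stringsAsFactors = FALSE)
    invisible(NULL)
  }
  if ("linear" %in% classes)
    for (l in layers) add(B[, l], P[, l], l, "linear", l)
  if ("quadratic" %in% classes)
    for (l in layers) add(B[, l]^2, P[, l]^2, paste0(l, "^2"), "quadratic", l)
  if ("product" %in% classes && length(layers) >= 2) {
    prs <- utils::combn(layers, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      add(B[, a] * B[, b], P[, a] * P[, b], paste0(a, ":", b), "product", a, b)
    }
  }
  meta <- do.call(rbind, meta)
  design <- do.call(cbind, cols_bg)
  pres <- do.call(cbind, cols_pr)
  colnames(design) <- colnames(pres) <- meta$feature
  structure(list(design = design, pres = pres, meta = meta, layers = layers,
                 background_cells = background_cells,
                 presence_cells = presence_cells, classes = classes),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("<maxent_features> %d features over %d layers; %d background cells, %d presences\n",
              nrow(x$meta), length(x$layers), nrow(x$design), nrow(x$pres)))
  print(table(x$meta$class))
  invisible(x)
}
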