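# The maximum-entropy presence-only model: fitting, outputs, contributions.

#' Fit an L1-regularized maximum-entropy model
#'
#' Estimates the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over
#' background cells that maximizes the penalized presence log-likelihood
#' `mean_presence(lambda . f) - ln Z(lambda) - sum_j beta * s_j * |lambda_j|`,
#' with per-feature penalty scale `s_j = sd(f_j over presences) / sqrt(m)`.
#' Fitting is cyclic coordinate descent with exact one-dimensional
#' soft-threshold solves; convergence is declared when a full sweep improves
#' the penalized objective by less than `tol`. The fit is deterministic given
#' its inputs.
#'
#' @param features A [build_features()] object.
#' @param beta Positive regularization multiplier applied to every `s_j`.
#' @param presence_idx Optional integer rows of `features$pres` to train on
#'   (used by replicate resampling); defaults to all presences.
#' @param lambda_init Optional warm-start coefficients.
#' @param max_sweeps,tol Optimizer controls (defaults 10000 sweeps, 1e-8).
#' @param seed Integer seed recorded on the model (randomness enters only
#'   through background choice, done in [build_features()]).
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(features, beta = 1, presence_idx = NULL,
                       lambda_init = NULL, max_sweeps = 10000, tol = 1e-8,
                       seed = 1) {
  stopifnot(inherits(features, "maxent_features"))
  if (beta < 0) stop("beta must be >= 0")
  pres <- features$pres
  if (!is.null(presence_idx)) pres <- pres[presence_idx, , drop = FALSE]
  m <- nrow(pres)
  if (m < 1) stop("at least one presence is required")
  fbar <- colMeans(pres)
  s <- if (m > 1) apply(pres, 2, sd) / sqrt(m) else rep(0, ncol(pres))
  if (is.null(lambda_init)) lambda_init <- rep(0, ncol(pres))
  fit <- maxent_cd_fit(features$design, fbar, s, beta,
                       as.numeric(lambda_init), as.integer(max_sweeps), tol)
  if (!fit$converged) {
    cond <- simpleError(sprintf(
      "maxent fit did not converge in %d sweeps (last objective %.10g)",
      max_sweeps, fit$objective))
    cond$objective <- fit$objective
    cond$lambda <- fit$lambda
    stop(cond)
  }
  lambda <- setNames(fit$lambda, features$meta$feature)
  eta <- as.numeric(features$design %*% lambda)
  lnZ <- fit$log_normalizer
  q <- exp(eta - lnZ)
  H <- -sum(q * log(q))
  structure(list(
    lambdas = lambda,
    beta = beta,
    penalty_scales = setNames(s, features$meta$feature),
    log_normalizer = lnZ,
    entropy = H,
    meta = features$meta,
    layers = features$layers,
    classes = features$classes,
    n_presence = m,
    presence_cells = if (is.null(presence_idx)) features$presence_cells
                     else features$presence_cells[presence_idx],
    background_cells = features$background_cells,
    presence_fbar = fbar,
    gains = setNames(fit$gains, features$meta$feature),
    objective = fit$objective,
    sweeps = fit$sweeps,
    seed = seed,
    q_background = q), class = "maxent_model")
}

#' Raw (Gibbs) output of a fitted model
#'
#' The raw output is the fitted probability distribution over background
#' cells; it is strictly positive and sums to 1 over the full background.
#'
#' @param model A `maxent_model`.
#' @param cells Linear cell indices (must be background cells); default all
#'   background cells.
#' @return Numeric vector of raw probabilities.
#' @export
raw_output <- function(model, cells = NULL) {
  if (is.null(cells)) return(model$q_background)
  pos <- match(cells, model$background_cells)
  if (anyNA(pos))
    stop("cell(s) outside the model background at index: ",
         paste(which(is.na(pos)), collapse = ", "))
  model$q_background[pos]
}

#' Logistic output of a fitted model
#'
#' The logistic transform `p = e^H q / (1 + e^H q)` of the raw output, with
#' `H` the entropy of the fitted distribution; a null (uniform) model maps to
#' 0.5 everywhere.
#'
#' @inheritParams raw_output
#' @return Numeric vector of values in (0,1).
#' @export
logistic_output <- function(model, cells = NULL) {
  q <- raw_output(model, cells)
  eHq <- exp(model$entropy) * q
  eHq / (1 + eHq)
}

#' Presence log-likelihood of a fitted model
#'
#' Sum over presences of `ln q(x)` with `q` the raw output normalized over
#' the background; this is the likelihood convention used for AICc scoring.
#'
#' @param model A `maxent_model`.
#' @param presence_cells Cells to score; default the model's training
#'   presences.
#' @return A single number (always negative for more than one background
#'   cell).
#' @export
log_likelihood <- function(model, presence_cells = model$presence_cells) {
  sum(log(raw_output(model, presence_cells)))
}

#' Percent contribution of each layer
#'
#' Training-path attribution: the positive penalized-objective gains recorded
#' at each coordinate update are summed over the features belonging to each
#' layer (gains of a product feature are split equally between its two parent
#' layers) and normalized to 100. A model that achieved no gain yields an
#' undefined table, flagged via the `"undefined"` attribute.
#'
#' @param model A `maxent_model`.
#' @return Named numeric vector (one entry per layer, summing to 100), with
#'   attribute `undefined`.
#' @export
percent_contribution <- function(model) {
  gains <- model$gains
  per_layer <- setNames(numeric(length(model$layers)), model$layers)
  for (i in seq_along(gains)) {
    g <- gains[i]
    if (g <= 0) next
    p1 <- model$meta$parent1[i]; p2 <- model$meta$parent2[i]
    if (is.na(p2)) per_layer[p1] <- per_layer[p1] + g
    else {
      per_layer[p1] <- per_layer[p1] + g / 2
      per_layer[p2] <- per_layer[p2] + g / 2
    }
  }
  tot <- sum(per_layer)
  if (tot <= 0) {
    out <- setNames(rep(NA_real_, length(per_layer)), names(per_layer))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- 100 * per_layer / tot
  attr(out, "undefined") <- FALSE
  out
}

# ---- high-level fitting interface ------------------------------------------

#' Fit a climatic-niche model to grove occurrences
#'
#' High-level interface: reduces raw occurrence records to presences
#' (centroid per grove, optional per-cell thinning, clip to the stack),
#' builds the feature space, and fits the maximum-entropy model.
#'
#' @param stack A [gn_stack] of climate layers.
#' @param occurrences Raw occurrence data.frame (`grove_id, lon, lat[,
#'   occupied]`) or an `occurrence_set`.
#' @param beta Regularization multiplier (default 1, the customary default).
#' @param classes Feature classes (see [build_features()]).
#' @param dedupe_cells Thin presences to one per raster cell (default TRUE).
#' @param max_background,seed See [choose_background()].
#' @return A `maxent_model` carrying, additionally, the training stack header
#'   and occurrence provenance.
#' @export
maxent_sdm <- function(stack, occurrences, beta = 1,
                       classes = c("linear", "quadratic", "product"),
                       dedupe_cells = TRUE, max_background = 10000,
                       seed = 1) {
  occ <- if (inherits(occurrences, "occurrence_set") && !is.null(occurrences$cells))
    occurrences else prepare_presences(
      if (inherits(occurrences, "occurrence_set")) occurrences$records else occurrences,
      stack, dedupe_cells = dedupe_cells)
  if (length(occ$cells) == 0) stop("no presence records remain after reduction")
  feats <- build_features(stack, occ$cells, classes = classes,
                          max_background = max_background, seed = seed)
  model <- fit_maxent(feats, beta = beta, seed = seed)
  model$header <- stack_header(stack)
  model$provenance <- occ$provenance
  model
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.maxent_model <- function(x, ...) {
  k <- sum(abs(x$lambdas) > 1e-12)
  cat(sprintf("<maxent_model> beta = %g; %d/%d non-zero coefficients; %d layers\n",
              x$beta, k, length(x$lambdas), length(x$layers)))
  cat(sprintf("  presences: %d; background cells: %d\n", x$n_presence,
              length(x$background_cells)))
  cat(sprintf("  entropy H = %.4f; penalized objective = %.6f (%d sweeps)\n",
              x$entropy, x$objective, x$sweeps))
  invisible(x)
}

#' @export
summary.maxent_model <- function(object, ...) {
  pc <- percent_contribution(object)
  out <- list(model = object, contributions = sort(pc, decreasing = TRUE),
              k = sum(abs(object$lambdas) > 1e-12),
              logLik = log_likelihood(object))
  class(out) <- "summary.maxent_model"
  out
}

#' @export
print.summary.maxent_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  presence log-likelihood: %.4f\n", x$logLik))
  cat("  percent contribution by layer:\n")
  pc <- x$contributions
  for (nm in names(pc)) cat(sprintf("    %-24s %6.2f\n", nm, pc[[nm]]))
  invisible(x)
}

#' @export
coef.maxent_model <- function(object, ...) object$lambdas

#' @export
logLik.maxent_model <- function(object, ...) {
  ll <- log_likelihood(object)
  attr(ll, "df") <- sum(abs(object$lambdas) > 1e-12)
  attr(ll, "nobs") <- object$n_presence
  class(ll) <- "logLik"
  ll
}

#' Simulate presence cells from a fitted model
#'
#' Draws cells from the fitted raw distribution over the background, the
#' generative interpretation of the maximum-entropy model.
#'
#' @param object A `maxent_model`.
#' @param nsim Number of presences per replicate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Integer vector of linear cell indices.
#' @export
simulate.maxent_model <- function(object, nsim = object$n_presence,
                                  seed = 1, ...) {
  with_seed(substream_seed(seed, "simulate"),
            sample(object$background_cells, nsim, replace = TRUE,
                   prob = object$q_background))
}

#' Response curves of a fitted model
#'
#' Plots, for each layer, the logistic output along that layer's observed
#' background range with all other layers held at their background mean.
#'
#' @param x A `maxent_model`.
#' @param layers Layers to plot (default all).
#' @param n Number of evaluation points per curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maxent_model <- function(x, layers = x$layers, n = 100, ...) {
  oldpar <- graphics::par(mfrow = grDevices::n2mfrow(length(layers)),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  # mean scaled feature values over the background as the conditioning point
  for (l in layers) {
    grid01 <- seq(0, 1, length.out = n)
    eta <- numeric(n)
    for (i in seq_len(nrow(x$meta))) {
      mrow <- x$meta[i, ]
      f <- if (identical(mrow$parent1, l) && is.na(mrow$parent2)) {
        if (mrow$class == "linear") grid01
        else grid01^2  # quadratic of the scaled value; display-only proxy
      } else 0.5
      eta <- eta + x$lambdas[i] * f
    }
    q <- exp(eta - logsumexp(eta))
    eHq <- exp(x$entropy) * q * length(x$background_cells) / n
    lr <- x$meta[x$meta$feature == l, , drop = FALSE]
    xv <- if (nrow(lr)) seq(lr$lo, lr$hi, length.out = n) else grid01
    graphics::plot(xv, eHq / (1 + eHq), type = "l", xlab = l,
                   ylab = "logistic output", main = l, ...)
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes everything needed to reproduce outputs bit-identically: feature
#' metadata, coefficients, penalty scales, entropy, log-normalizer, clamp
#' ranges, background cells, and the seed.
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  obj <- model[c("beta", "log_normalizer", "entropy", "layers", "classes",
                 "n_presence", "presence_cells", "background_cells",
                 "objective", "sweeps", "seed")]
  # named vectors as objects so the names survive the JSON round-trip
  obj$lambdas <- as.list(model$lambdas)
  obj$penalty_scales <- as.list(model$penalty_scales)
  obj$gains <- as.list(model$gains)
  obj$meta <- model$meta
  obj$header <- model$header
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path JSON path written by [write_model_json()].
#' @return A `maxent_model` (without the cached background distribution's
#'   source design matrix; outputs are reconstructed from the stored pieces).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("lambdas", "penalty_scales", "gains"))
    obj[[nm]] <- setNames(as.numeric(obj[[nm]]), names(obj[[nm]]))
  class(obj) <- "maxent_model"
  obj
}
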