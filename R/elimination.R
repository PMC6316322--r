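# Collinearity-driven variable elimination: pairwise layer correlation and
# the two iterative "top variable" procedures.

#' Pairwise Pearson correlation between layers
#'
#' Computed once over the stack's jointly valid cells and looked up
#' thereafter: pairwise correlations do not change as layers are removed.
#' Constant layers get correlation 0 against everything (with a warning).
#'
#' @param stack A [gn_stack].
#' @return A symmetric correlation matrix with unit diagonal and attribute
#'   `n_cells`.
#' @export
pairwise_correlation <- function(stack) {
  V <- stack_values(stack)
  if (nrow(V) < 2) stop("fewer than 2 valid cells; correlation undefined")
  const <- apply(V, 2, function(v) diff(range(v)) == 0)
  r <- suppressWarnings(cor(V))
  if (any(const)) {
    warning("constant layer(s) treated as uncorrelated: ",
            paste(colnames(V)[const], collapse = ", "))
    r[const, ] <- 0; r[, const] <- 0
  }
  diag(r) <- 1
  attr(r, "n_cells") <- nrow(V)
  r
}

# Shared engine for both elimination procedures.
eliminate_engine <- function(stack, presence_cells, beta, threshold_r,
                             threshold_pc, drop_low_contribution,
                             classes, max_background, seed) {
  corr <- pairwise_correlation(stack)
  remaining <- names(stack$layers)
  retained <- character(0)
  steps <- list()
  cycle <- 0L
  while (length(remaining) > 0) {
    cycle <- cycle + 1L
    feats <- build_features(stack[remaining], presence_cells,
                            classes = classes,
                            max_background = max_background, seed = seed)
    model <- fit_maxent(feats, beta = beta, seed = seed)
    pc <- percent_contribution(model)
    # contributions for layers dropped as constant in build_features are 0;
    # a fully-shrunk model (no gain) is treated as all-zero contributions and
    # resolved by the lexicographic tie-break
    pc_full <- setNames(rep(0, length(remaining)), remaining)
    if (!isTRUE(attr(pc, "undefined"))) pc_full[names(pc)] <- pc
    elim_low <- character(0)
    if (drop_low_contribution) {
      elim_low <- names(pc_full)[pc_full < threshold_pc]
      # never eliminate the would-be top variable on the low-contribution rule
      elim_low <- setdiff(elim_low, names(pc_full)[pc_full == max(pc_full)])
    }
    cand <- setdiff(remaining, elim_low)
    top <- sort(cand[pc_full[cand] == max(pc_full[cand])])[1]  # lexicographic tie-break
    rest <- setdiff(cand, top)
    elim_corr <- rest[abs(corr[rest, top]) >= threshold_r]
    steps[[cycle]] <- list(cycle = cycle, beta = beta,
                           remaining = remaining,
                           contributions = pc_full,
                           eliminated_low_contribution = elim_low,
                           top = top,
                           eliminated_correlated = elim_corr)
    retained <- c(retained, top)
    remaining <- setdiff(rest, elim_corr)
  }
  trace <- structure(list(steps = steps, retained = retained,
                          threshold_r = threshold_r,
                          threshold_pc = if (drop_low_contribution) threshold_pc else NA_real_,
                          method = if (drop_low_contribution)
                            "top_variable_uncorrelated" else "uncorrelated",
                          correlation = corr),
                     class = "elimination_trace")
  list(retained = retained, trace = trace)
}

#' "Top variable uncorrelated" elimination
#'
#' Iterative cycle on the remaining layers: (1) fit the model at `beta`;
#' (2) eliminate layers contributing less than `threshold_pc` percent;
#' (3) promote the highest-contribution layer to the top-variable list
#' (ties to the lexicographically smallest name); (4) eliminate remaining
#' layers whose absolute correlation with the new top variable is at least
#' `threshold_r`; repeat until every layer is eliminated or promoted. The
#' retained set is the top-variable list.
#'
#' @param stack A [gn_stack].
#' @param presence_cells Linear presence cell indices.
#' @param beta Regularization multiplier for the cycle's fits.
#' @param threshold_r Correlation threshold (default 0.7, absolute value).
#' @param threshold_pc Percent-contribution threshold (default 5).
#' @param classes,max_background,seed Passed to [build_features()] /
#'   [fit_maxent()].
#' @return A list: `retained` (character, in promotion order) and `trace`
#'   (an `elimination_trace`).
#' @export
eliminate_top_variable_uncorrelated <- function(stack, presence_cells, beta,
    threshold_r = 0.7, threshold_pc = 5,
    classes = c("linear", "quadratic", "product"),
    max_background = 10000, seed = 1)
  eliminate_engine(stack, presence_cells, beta, threshold_r, threshold_pc,
                   drop_low_contribution = TRUE, classes, max_background, seed)

#' "Uncorrelated" elimination (relaxed)
#'
#' Same cycle as [eliminate_top_variable_uncorrelated()] but without the
#' percent-contribution rule: low-contribution layers are kept as long as
#' their correlation with every promoted top variable stays below the
#' threshold, avoiding over-elimination and under-parameterization.
#'
#' @inheritParams eliminate_top_variable_uncorrelated
#' @return As [eliminate_top_variable_uncorrelated()].
#' @export
eliminate_uncorrelated <- function(stack, presence_cells, beta,
    threshold_r = 0.7, classes = c("linear", "quadratic", "product"),
    max_background = 10000, seed = 1)
  eliminate_engine(stack, presence_cells, beta, threshold_r, threshold_pc = 0,
                   drop_low_contribution = FALSE, classes, max_background, seed)

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> method '%s', %d cycle(s); retained: %s\n",
              x$method, length(x$steps), paste(x$retained, collapse = ", ")))
  for (s in x$steps) {
    cat(sprintf("  cycle %d (beta %g): top = %s", s$cycle, s$beta, s$top))
    if (length(s$eliminated_low_contribution))
      cat("; low-contribution: ",
          paste(s$eliminated_low_contribution, collapse = ", "), sep = "")
    if (length(s$eliminated_correlated))
      cat("; correlated: ", paste(s$eliminated_correlated, collapse = ", "), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Replay an elimination trace
#'
#' Reconstructs the retained set and per-cycle remaining sets from the
#' recorded contributions and decisions alone, verifying the trace is a
#' complete audit record of the procedure.
#'
#' @param trace An `elimination_trace`.
#' @return Character vector of retained layers, in promotion order.
#' @export
replay_trace <- function(trace) {
  retained <- character(0)
  for (s in trace$steps) {
    remaining <- s$remaining
    if (length(retained)) {
      # remaining must equal previous remaining minus assignments
      prev <- trace$steps[[s$cycle - 1]]
      expect <- setdiff(prev$remaining,
                        c(prev$eliminated_low_contribution, prev$top,
                          prev$eliminated_correlated))
      if (!setequal(expect, remaining))
        stop("trace replay mismatch at cycle ", s$cycle)
    }
    cand <- setdiff(remaining, s$eliminated_low_contribution)
    top <- sort(cand[s$contributions[cand] == max(s$contributions[cand])])[1]
    if (!identical(top, s$top)) stop("trace replay: top mismatch at cycle ", s$cycle)
    retained <- c(retained, top)
  }
  if (!identical(retained, trace$retained)) stop("trace replay: retained set mismatch")
  retained
}

#' Serialize an elimination trace to JSON
#' @param trace An `elimination_trace`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_json <- function(trace, path) {
  obj <- unclass(trace)
  obj$correlation <- as.data.frame(trace$correlation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
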