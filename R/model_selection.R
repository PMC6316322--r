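# AICc scoring and the three-stage regularization (beta) optimization
# protocol: coarse integer sweep with replicates, 0.1-step bracketing around
# the coarse optimum, and a final 0.1-2.0 scan.

#' Small-sample corrected AIC
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1)`, with `k` the number of non-zero
#' model coefficients and `n` the number of presences. Undefined (NA) when
#' `n - k - 1 <= 0`.
#'
#' @param lnL Presence log-likelihood.
#' @param k Number of non-zero coefficients.
#' @param n Number of presences.
#' @return Numeric; `NA` when the small-sample correction is undefined.
#' @export
aicc <- function(lnL, k, n) {
  stopifnot(k >= 0, n >= 1)
  ifelse(n - k - 1 <= 0, NA_real_, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
}

#' Number of model parameters for AICc
#'
#' Counts coefficients with `|lambda| > 1e-12`; L1 regularization zeroes
#' coefficients exactly, so this is the effective parameter count.
#'
#' @param model A `maxent_model`.
#' @return Integer.
#' @export
count_parameters <- function(model) sum(abs(model$lambdas) > 1e-12)

replicate_indices <- function(m, replicate, seed,
                              mode = c("bootstrap", "subsample", "identical")) {
  mode <- match.arg(mode)
  switch(mode,
    bootstrap = with_seed(substream_seed(seed, paste0("replicate-", replicate)),
                          sample.int(m, m, replace = TRUE)),
    subsample = with_seed(substream_seed(seed, paste0("replicate-", replicate)),
                          sort(sample.int(m, max(1L, floor(0.75 * m))))),
    identical = seq_len(m))
}

#' Scan regularization multipliers by replicate-averaged AICc
#'
#' For each `beta`, refits the model on `replicates` seeded resamples of the
#' presences (bootstrap by default), scores each fit by AICc
#' (`k` = non-zero coefficients, `lnL` on the replicate's presences), and
#' averages over replicates. The best beta minimizes the mean AICc; ties are
#' broken toward the smaller beta. Every fit is cold-started, so the record
#' for a given (beta, replicate) pair is identical across scans sharing the
#' same seed, whatever other betas the scan covers.
#'
#' @param features A [build_features()] object.
#' @param betas Numeric vector of multipliers to scan.
#' @param replicates Number of resampling replicates (default 10).
#' @param mode Resampling mode: `"bootstrap"` (default), `"subsample"` (75%),
#'   or `"identical"` (no resampling; replicates are degenerate).
#' @param seed Integer seed driving the replicate resamples.
#' @return An object of class `beta_scan`: `$table` (beta, replicate, k, lnL,
#'   n, aicc), `$mean_aicc` (named by beta), `$best_beta`.
#' @export
beta_scan <- function(features, betas, replicates = 10,
                      mode = c("bootstrap", "subsample", "identical"),
                      seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "maxent_features"))
  if (nrow(features$pres) < 2) stop("at least 2 presences are required for a beta scan")
  betas <- sort(unique(round(betas, 10)))
  if (any(betas <= 0)) stop("betas must be positive")
  rows <- vector("list", length(betas) * replicates)
  ri <- 0L
  # canonicalize presence order (by cell index) so the scan is invariant to
  # the ordering of the input records
  ord <- order(features$presence_cells)
  for (r in seq_len(replicates)) {
    idx <- ord[replicate_indices(nrow(features$pres), r, seed, mode)]
    for (b in betas) {
      # every fit cold-starts so a beta's record is identical across scans
      # that share the replicate seed, whatever else the scan covers
      fit <- fit_maxent(features, beta = b, presence_idx = idx, seed = seed)
      k <- count_parameters(fit)
      lnL <- log_likelihood(fit)
      n <- fit$n_presence
      ri <- ri + 1L
      rows[[ri]] <- data.frame(beta = b, replicate = r, k = k, lnL = lnL,
                               n = n, aicc = aicc(lnL, k, n))
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$beta, tab$replicate), ]
  rownames(tab) <- NULL
  mean_aicc <- tapply(tab$aicc, tab$beta, function(a)
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE))
  mean_aicc <- setNames(as.numeric(mean_aicc), names(mean_aicc))
  defined <- !is.na(mean_aicc)
  if (!any(defined)) stop("AICc undefined at every beta; selection impossible")
  cand <- as.numeric(names(mean_aicc))[defined]
  vals <- mean_aicc[defined]
  best <- min(cand[vals == min(vals)])
  structure(list(table = tab, mean_aicc = mean_aicc, best_beta = best,
                 replicates = replicates, mode = mode, seed = seed),
            class = "beta_scan")
}

#' @export
print.beta_scan <- function(x, ...) {
  cat(sprintf("<beta_scan> %d beta values x %d replicates (%s); best beta = %g\n",
              length(x$mean_aicc), x$replicates, x$mode, x$best_beta))
  df <- data.frame(beta = as.numeric(names(x$mean_aicc)),
                   mean_aicc = as.numeric(x$mean_aicc))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @describeIn beta_scan Coarse sweep over integer betas 1-7.
#' @export
coarse_beta_sweep <- function(features, betas = 1:7, replicates = 10,
                              mode = "bootstrap", seed = 1)
  beta_scan(features, betas, replicates, mode, seed)

#' Refine a coarse beta optimum on a 0.1 grid
#'
#' Scans every 0.1-step value between the coarse optimum's integer
#' neighbours (truncated below at 0.1), using the same replicate protocol and
#' seed, so the refined optimum's mean AICc can never exceed the coarse one.
#'
#' @param features A [build_features()] object.
#' @param scan A `beta_scan` from [coarse_beta_sweep()].
#' @param step Grid step (default 0.1).
#' @param replicates,mode,seed As in [beta_scan()].
#' @return A refined `beta_scan`.
#' @export
bracket_beta <- function(features, scan, step = 0.1, replicates = 10,
                         mode = "bootstrap", seed = 1) {
  stopifnot(inherits(scan, "beta_scan"))
  b0 <- scan$best_beta
  betas <- round(seq(b0 - 1, b0 + 1, by = step), 10)
  betas <- betas[betas > 0]
  beta_scan(features, betas, replicates, mode, seed)
}

#' Final beta scan over 0.1-2.0
#'
#' The final model's multiplier is chosen by the lowest replicate-averaged
#' AICc over the twenty values 0.1, 0.2, ..., 2.0.
#'
#' @inheritParams beta_scan
#' @param range Two-element range (default `c(0.1, 2.0)`), scanned in 0.1
#'   steps.
#' @return A `beta_scan`.
#' @export
final_beta_scan <- function(features, range = c(0.1, 2.0), replicates = 10,
                            mode = "bootstrap", seed = 1) {
  betas <- round(seq(range[1], range[2], by = 0.1), 10)
  beta_scan(features, betas, replicates, mode, seed)
}

#' Write a beta-scan table as CSV
#' @param scan A `beta_scan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_csv <- function(scan, path) {
  write.csv(scan$table, path, row.names = FALSE)
  invisible(path)
}
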