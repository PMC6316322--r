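# Internal helpers: seeded substreams, logging, numeric utilities.

#' Derive a deterministic child seed from a run seed and a stream name
#'
#' All randomness in the package flows from a single run seed through named
#' substreams (landscape, climate noise, grove sampling, replicate resampling)
#' so that changing one stage's draws never perturbs another's.
#'
#' @param seed Integer run seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h) %% (2^31 - 1))
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

log_msg <- function(..., verbose = getOption("groveniche.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf("[groveniche %s] ", format(Sys.time(), "%H:%M:%S")), ...)
  invisible(NULL)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
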