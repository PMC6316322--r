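# Shared fixtures and the independent brute-force optimizer used as the
# oracle for the coordinate-descent trainer.

# log(sum(exp(x))) without the package's internal helper
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Penalized maxent objective, written independently of the package internals.
maxent_objective <- function(lambda, X, fbar, s, beta)
  sum(lambda * fbar) - lse(as.numeric(X %*% lambda)) - beta * sum(s * abs(lambda))

# Brute-force oracle: nested grid refinement of the penalized objective over
# lambda (concave), for <= 3 features. Independent of the package trainer.
oracle_maxent <- function(X, fbar, s, beta, span = 10, refinements = 12) {
  J <- ncol(X)
  stopifnot(J <= 3)
  center <- rep(0, J)
  width <- span
  for (r in seq_len(refinements)) {
    g <- seq(-width, width, length.out = 9)
    pts <- as.matrix(expand.grid(rep(list(g), J)))
    vals <- apply(pts, 1, function(d)
      maxent_objective(center + d, X, fbar, s, beta))
    center <- center + pts[which.max(vals), ]
    width <- width / 4
  }
  center
}

# Softmax distribution over background cells for a coefficient vector.
oracle_q <- function(X, lambda) {
  eta <- as.numeric(X %*% lambda)
  exp(eta - lse(eta))
}

# A tiny deterministic stack: nl layers of seeded uniform values on an
# nr x nc grid (all cells valid).
tiny_stack <- function(nl = 2, nr = 5, nc = 5, seed = 1,
                       names = paste0("L", seq_len(nl))) {
  set.seed(seed)
  layers <- lapply(seq_len(nl), function(i)
    gn_grid(matrix(runif(nr * nc), nr, nc), 0, 0, 1))
  names(layers) <- names
  gn_stack(layers)
}

# A small synthetic study shared across expensive tests (built once per run).
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        seed = 42,
        landscape = landscape_spec(nrows = 50, ncols = 50),
        climate = default_climate_spec(variables = c("tmin", "precipitation"),
                                       months = c("Oct", "Dec", "Feb")),
        niche = niche_spec(active = c(tmin_Feb = 2.0, precipitation_Oct = 1.2),
                           n_groves = 150))
    }
    cache
  }
})
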