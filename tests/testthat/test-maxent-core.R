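# The maximum-entropy core: features, fitting, outputs, contributions.

test_that("feature construction counts classes and drops constant layers", {
  st <- tiny_stack(nl = 3, nr = 5, nc = 5, seed = 2)
  f_lin <- build_features(st, presence_cells = c(1L, 7L), classes = "linear")
  expect_equal(nrow(f_lin$meta), 3)
  f_all <- build_features(st, presence_cells = c(1L, 7L))
  expect_equal(nrow(f_all$meta), 3 + 3 + 3)  # linear + quadratic + products
  expect_true(all(f_all$design >= 0 & f_all$design <= 1))
  # per-column scaling attains both bounds over the background
  expect_equal(unname(apply(f_all$design, 2, min)), rep(0, 9))
  expect_equal(unname(apply(f_all$design, 2, max)), rep(1, 9))
  # constant layer dropped with warning
  stc <- gn_stack(c(st$layers, list(K = gn_grid(matrix(1, 5, 5), 0, 0, 1))))
  expect_warning(fc <- build_features(stc, c(1L, 7L), classes = "linear"),
                 "constant")
  expect_equal(nrow(fc$meta), 3)
})

test_that("one-feature fits reproduce the closed-form moment match", {
  # 2 background cells, f = (0, 1), presence mean 0.75, no penalty:
  # q = (0.25, 0.75), lambda = ln 3
  st <- gn_stack(list(a = gn_grid(matrix(c(0, 1), 1), 0, 0, 1)))
  f <- build_features(st, presence_cells = c(1L, 2L, 2L, 2L), classes = "linear")
  m <- fit_maxent(f, beta = 0)
  expect_equal(unname(m$lambdas), log(3), tolerance = 1e-7)
  expect_equal(unname(raw_output(m)), c(0.25, 0.75), tolerance = 1e-7)
  expect_equal(log_likelihood(m, c(2L, 2L, 1L)), 2 * log(0.75) + log(0.25),
               tolerance = 1e-7)
  expect_equal(count_parameters(m), 1)

  # penalty beyond the moment gap soft-thresholds to zero
  s <- m$penalty_scales
  gap <- abs(0.75 - 0.5)
  m0 <- fit_maxent(f, beta = (gap / s) * 1.5)
  expect_equal(unname(m0$lambdas), 0)
  # brute-force 1-D confirmation that 0 is optimal at that penalty
  lgrid <- seq(-3, 3, by = 0.001)
  ogrid <- vapply(lgrid, function(l)
    maxent_objective(l, f$design, colMeans(f$pres), s, (gap / s) * 1.5),
    numeric(1))
  expect_equal(lgrid[which.max(ogrid)], 0)
})

test_that("full shrinkage at huge beta yields the uniform null model", {
  st <- tiny_stack(nl = 2, nr = 6, nc = 6, seed = 3)
  f <- build_features(st, presence_cells = c(3L, 14L, 27L))
  m <- fit_maxent(f, beta = 1e6)
  expect_equal(unname(m$lambdas), rep(0, nrow(m$meta)))
  N <- length(m$background_cells)
  expect_equal(unname(raw_output(m)), rep(1 / N, N))
  # null-model conventions: logistic 0.5 everywhere, lnL = -m ln N
  expect_equal(unname(logistic_output(m)), rep(0.5, N))
  expect_equal(log_likelihood(m), -3 * log(N))
  expect_equal(m$entropy, log(N))
})

test_that("raw and logistic outputs follow the stated formulas", {
  # hand-computed 3-cell, 1-feature case: f = (0, 0.5, 1), lambda = 1
  eta <- c(0, 0.5, 1)
  q_hand <- exp(eta) / sum(exp(eta))
  expect_equal(q_hand, c(0.1863237, 0.3071959, 0.5064804), tolerance = 1e-6)
  H <- -sum(q_hand * log(q_hand))
  p_hand <- exp(H) * q_hand / (1 + exp(H) * q_hand)
  # the package path reproduces the arithmetic: build a 3-cell problem whose
  # fit is forced to lambda = 1 by moment-matching presences is fragile;
  # instead check the transform functions directly on a fitted model
  st <- gn_stack(list(a = gn_grid(matrix(c(0, 0.5, 1), 1), 0, 0, 1)))
  f <- build_features(st, presence_cells = c(2L, 3L, 3L), classes = "linear")
  m <- fit_maxent(f, beta = 0.1)
  q <- raw_output(m)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_true(all(q > 0))
  # logistic is the stated monotone transform of raw
  expect_equal(logistic_output(m),
               exp(m$entropy) * q / (1 + exp(m$entropy) * q))
  expect_equal(order(q), order(logistic_output(m)))
  expect_error(raw_output(m, cells = 999L), "outside the model background")
})

test_that("fits match the brute-force oracle on small seeded problems", {
  for (seed in 1:6) {
    set.seed(seed)
    nl <- sample(1:3, 1)
    st <- tiny_stack(nl = nl, nr = 6, nc = sample(4:10, 1), seed = seed + 100)
    ncell <- st$layers[[1]]$nrows * st$layers[[1]]$ncols
    pres <- sample(ncell, sample(3:8, 1))
    beta <- runif(1, 0.1, 2)
    f <- build_features(st, presence_cells = pres, classes = "linear")
    m <- fit_maxent(f, beta = beta)
    lam_star <- oracle_maxent(f$design, colMeans(f$pres),
                              m$penalty_scales, beta)
    q_star <- oracle_q(f$design, lam_star)
    expect_lt(max(abs(raw_output(m) - q_star)), 1e-4)
  }
})

test_that("KKT soft-moment bound holds at every fitted optimum", {
  for (seed in c(21, 22)) {
    st <- tiny_stack(nl = 4, nr = 8, nc = 8, seed = seed)
    set.seed(seed)
    pres <- sample(64, 10)
    f <- build_features(st, presence_cells = pres)
    m <- fit_maxent(f, beta = 0.8)
    Eq <- as.numeric(crossprod(f$design, raw_output(m)))
    fbar <- colMeans(f$pres)
    expect_true(all(abs(fbar - Eq) <= m$beta * m$penalty_scales + 1e-6))
  }
})

test_that("stronger regularization never increases the parameter count", {
  st <- tiny_stack(nl = 4, nr = 8, nc = 8, seed = 31)
  set.seed(31)
  f <- build_features(st, presence_cells = sample(64, 12))
  ks <- vapply(c(0.1, 0.5, 1, 2, 5), function(b)
    count_parameters(fit_maxent(f, beta = b)), integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_equal(ks, sort(ks, decreasing = TRUE))
})

test_that("fitting is deterministic: identical inputs give identical lambdas", {
  st <- tiny_stack(nl = 3, nr = 7, nc = 7, seed = 41)
  set.seed(41)
  pres <- sample(49, 9)
  f1 <- build_features(st, presence_cells = pres, seed = 7)
  f2 <- build_features(st, presence_cells = pres, seed = 7)
  m1 <- fit_maxent(f1, beta = 0.7, seed = 7)
  m2 <- fit_maxent(f2, beta = 0.7, seed = 7)
  expect_identical(m1$lambdas, m2$lambdas)
  expect_identical(m1$entropy, m2$entropy)
})

test_that("percent contribution sums to 100 and attributes gain to layers", {
  st <- tiny_stack(nl = 3, nr = 8, nc = 8, seed = 51)
  set.seed(51)
  f <- build_features(st, presence_cells = sample(64, 12))
  m <- fit_maxent(f, beta = 0.5)
  pc <- percent_contribution(m)
  expect_named(pc, names(st$layers))
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_true(all(pc >= 0))
  # single-layer model: all contribution on that layer
  f1 <- build_features(st[1], presence_cells = sample(64, 12))
  m1 <- fit_maxent(f1, beta = 0.2)
  pc1 <- percent_contribution(m1)
  expect_equal(as.numeric(pc1), 100)
  # fully shrunk model: undefined table, flagged
  mz <- fit_maxent(f, beta = 1e6)
  pcz <- percent_contribution(mz)
  expect_true(attr(pcz, "undefined"))
  expect_true(all(is.na(pcz)))
})

test_that("model JSON round-trips the coefficients and normalizers", {
  st <- tiny_stack(nl = 2, nr = 6, nc = 6, seed = 61)
  set.seed(61)
  f <- build_features(st, presence_cells = sample(36, 8))
  m <- fit_maxent(f, beta = 0.6)
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p)
  m2 <- read_model_json(p)
  expect_equal(m2$lambdas, m$lambdas)
  expect_equal(m2$entropy, m$entropy)
  expect_equal(m2$log_normalizer, m$log_normalizer)
  expect_equal(m2$meta$lo, m$meta$lo)
})
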