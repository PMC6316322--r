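# Synthetic study-system generator: landscape shape, climate coupling,
# niche suitability, grove sampling, and scenario deltas.

test_that("landscapes are deterministic under seed and coastal-low", {
  spec <- landscape_spec(nrows = 40, ncols = 40)
  e1 <- make_landscape(spec, seed = 11)
  e2 <- make_landscape(spec, seed = 11)
  e3 <- make_landscape(spec, seed = 12)
  expect_identical(e1$values, e2$values)
  expect_false(identical(e1$values, e3$values))
  expect_true(all(e1$values >= 0))
  # coast on the west: westernmost columns lower than easternmost on average
  expect_lt(mean(e1$values[, 1:5]), mean(e1$values[, 36:40]))
  # broad inland trend: column means correlate with distance from coast
  expect_gt(cor(colMeans(e1$values), seq_len(40)), 0.8)
})

test_that("zero-noise, zero-ridge landscapes are the exact ramp", {
  spec <- landscape_spec(nrows = 10, ncols = 8, n_ridges = 0, noise_amp = 0)
  e <- make_landscape(spec, seed = 1)
  ramp <- matrix((seq_len(8) - 0.5) / 8 * 1500, 10, 8, byrow = TRUE)
  expect_equal(e$values, ramp)
})

test_that("climate layers recover the prescribed lapse rate", {
  # the deterministic ramp and ridges are functions of coast distance alone,
  # so the lapse rate is identified by elevation variation orthogonal to the
  # coast axis; give the test landscape strong short-range relief noise
  spec <- landscape_spec(nrows = 100, ncols = 100,
                         noise_amp = 300, noise_len = 2)
  elev <- make_landscape(spec, seed = 21)
  cl <- default_climate_spec(variables = "tmin", months = c("Oct", "Jan"))
  d <- as.numeric(t(matrix((seq_len(100) - 0.5) / 100, 100, 100, byrow = TRUE)))
  z <- as.numeric(t(elev$values)) / 1000
  # noiseless: regression on elevation and coast distance is exact
  cl0 <- cl; cl0$noise_amp <- 0
  st0 <- derive_climate(elev, cl0, seed = 21)
  fit0 <- lm(as.numeric(stack_values(st0)[, "tmin_Jan"]) ~ z + d)
  expect_equal(unname(coef(fit0)[["z"]]), -6.5, tolerance = 1e-8)
  # with climate noise at the default amplitude the slope comes back within
  # ~2 standard errors of the truth
  st <- derive_climate(elev, cl, seed = 21)
  fit <- lm(as.numeric(stack_values(st)[, "tmin_Jan"]) ~ z + d)
  expect_lt(abs(coef(fit)[["z"]] - (-6.5)), 0.3)
})

test_that("months of one variable share noise; variables are independent", {
  spec <- landscape_spec(nrows = 40, ncols = 40)
  elev <- make_landscape(spec, seed = 31)
  cl <- default_climate_spec(variables = c("tmin", "precipitation"),
                             months = c("Oct", "Jan"))
  st <- derive_climate(elev, cl, seed = 31)
  # isolate the noise by subtracting the deterministic part
  noise_of <- function(layer, row) {
    d <- matrix((seq_len(40) - 0.5) / 40, 40, 40, byrow = TRUE)
    st$layers[[layer]]$values - row$base - row$elev_coeff * elev$values / 1000 -
      row$coast_coeff * d
  }
  cl_row <- function(layer) cl[cl$layer == layer, ]
  n_tmin_oct <- noise_of("tmin_Oct", cl_row("tmin_Oct"))
  n_tmin_jan <- noise_of("tmin_Jan", cl_row("tmin_Jan"))
  n_prec_oct <- noise_of("precipitation_Oct", cl_row("precipitation_Oct"))
  # shared_rho = 0.85 implies cross-month noise correlation near rho^2
  expect_gt(cor(c(n_tmin_oct), c(n_tmin_jan)), 0.5)
  expect_lt(abs(cor(c(n_tmin_oct), c(n_prec_oct))), 0.3)
  # determinism of the whole stack
  st2 <- derive_climate(elev, cl, seed = 31)
  expect_identical(stack_values(st), stack_values(st2))
})

test_that("true suitability is the logistic of the standardized niche", {
  st <- tiny_stack(nl = 2, nr = 6, nc = 6, seed = 41, names = c("a", "b"))
  spec <- niche_spec(active = c(a = 2, b = -1), intercept = 0.3, n_groves = 5)
  suit <- true_suitability(st, spec)
  za <- scale(as.numeric(st$layers$a$values))
  zb <- scale(as.numeric(st$layers$b$values))
  expect_equal(as.numeric(suit$values),
               as.numeric(plogis(0.3 + 2 * za - 1 * zb)))
  expect_true(all(suit$values > 0 & suit$values < 1))
  expect_error(true_suitability(st, niche_spec(active = c(zz = 1))),
               "lacks active")
})

test_that("grove sampling is seeded, bounded, and suitability-weighted", {
  st <- tiny_stack(nl = 1, nr = 20, nc = 20, seed = 51, names = "a")
  spec <- niche_spec(active = c(a = 3), n_groves = 40,
                     max_records_per_grove = 3, scatter_sd = 0.05)
  suit <- true_suitability(st, spec)
  r1 <- sample_groves(suit, spec, seed = 5)
  r2 <- sample_groves(suit, spec, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1$lon, sample_groves(suit, spec, seed = 6)$lon))
  # one grove id per center, 1..max records each
  counts <- table(r1$grove_id)
  expect_length(counts, 40)
  expect_true(all(counts >= 1 & counts <= 3))
  # scatter is truncated: every record within 2.5 sd of its grove center
  centers <- attr(r1, "centers")
  expect_length(centers, 40)
  ctr <- cell_center(suit, centers)
  idx <- as.integer(factor(r1$grove_id, levels = sprintf("G%04d", 1:40)))
  expect_true(all(abs(r1$lon - ctr$lon[idx]) <= 2.5 * 0.05 + 1e-12))
  expect_true(all(abs(r1$lat - ctr$lat[idx]) <= 2.5 * 0.05 + 1e-12))
  # weighting: sampled centers sit in above-average suitability
  expect_gt(mean(cell_value(suit, centers)), mean(suit$values))
  # oversampling more groves than valid cells is an error
  expect_error(sample_groves(suit, niche_spec(active = c(a = 1),
                                              n_groves = 500), 1),
               "exceeds")
})

test_that("scenario deltas apply value * mult + add per layer", {
  st <- tiny_stack(nl = 2, nr = 4, nc = 4, seed = 61,
                   names = c("tmin_Jan", "precipitation_Feb"))
  out <- apply_scenario(st, list(tmin_Jan = list(add = 2, mult = 1.1)))
  expect_equal(out$layers$tmin_Jan$values, st$layers$tmin_Jan$values * 1.1 + 2)
  # layers without a delta pass through unchanged
  expect_identical(out$layers$precipitation_Feb$values,
                   st$layers$precipitation_Feb$values)
  expect_warning(apply_scenario(st, list(nope = list(add = 1))), "unknown")
})

test_that("warming deltas target exactly the temperature layers", {
  st <- tiny_stack(nl = 4, nr = 3, nc = 3, seed = 71,
                   names = c("tmin_Jan", "tmax_Feb", "precipitation_Oct",
                             "wind_speed_Dec"))
  d <- warming_deltas(st, dT = 2)
  expect_setequal(names(d), c("tmin_Jan", "tmax_Feb"))
  expect_equal(d$tmin_Jan$add, 2)
  warmed <- apply_scenario(st, d)
  expect_equal(warmed$layers$tmin_Jan$values, st$layers$tmin_Jan$values + 2)
  expect_identical(warmed$layers$precipitation_Oct$values,
                   st$layers$precipitation_Oct$values)
})

test_that("simulate_study ties the pieces together deterministically", {
  sim <- shared_study()
  expect_length(sim$stack, 6)  # 2 variables x 3 months
  expect_equal(length(unique(sim$records$grove_id)), 150)
  expect_equal(same_header(sim$elevation, sim$stack$layers[[1]]), character(0))
  # rebuilt from the same seed: identical records and layer values
  sim2 <- simulate_study(42, sim$landscape, sim$climate, sim$niche)
  expect_identical(sim2$records, sim$records)
  expect_identical(stack_values(sim2$stack), stack_values(sim$stack))
  # records fall inside the grid extent
  ext_x <- sim$elevation$xllcorner + c(0, 50 * sim$elevation$cellsize)
  expect_true(all(sim$records$lon >= ext_x[1] & sim$records$lon <= ext_x[2]))
})
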