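# Model transfer onto altered stacks: clamping, renormalization, thresholds,
# elevation correlation, difference maps, and cropping.

# A small fitted model on a deterministic stack, reused across blocks.
projection_fixture <- function(seed = 7) {
  st <- tiny_stack(nl = 2, nr = 10, nc = 10, seed = seed,
                   names = c("tmin_Jan", "precipitation_Feb"))
  set.seed(seed)
  pres <- sort(sample(100, 18))
  f <- build_features(st, pres)
  list(stack = st, presences = pres,
       model = fit_maxent(f, beta = 1, seed = seed))
}

test_that("projection onto the training stack reproduces the training surface", {
  fx <- projection_fixture()
  surf <- project_model(fx$model, fx$stack)
  # every cell is valid, so surface cells align with the background cells
  expect_equal(as.numeric(t(surf$values))[fx$model$background_cells],
               unname(logistic_output(fx$model, fx$model$background_cells)))
  expect_equal(attr(surf, "clamped"), 0L)  # nothing out of training range
  expect_equal(attr(surf, "model_beta"), 1)
  expect_s3_class(surf, "probability_surface")
  # raw distribution renormalizes: logit-transformed p recovers q summing to 1
  p <- as.numeric(t(surf$values))
  q <- (p / (1 - p)) / exp(fx$model$entropy)
  expect_equal(sum(q), 1)
})

test_that("predict() is the projection interface", {
  fx <- projection_fixture()
  expect_equal(predict(fx$model, fx$stack)$values,
               project_model(fx$model, fx$stack)$values)
})

test_that("clamping pins out-of-range features to the training range", {
  # linear/quadratic model on positive layers: clamping a shifted layer is
  # then exactly equivalent to holding it at its training maximum
  st <- tiny_stack(nl = 2, nr = 10, nc = 10, seed = 7,
                   names = c("tmin_Jan", "precipitation_Feb"))
  set.seed(7)
  f <- build_features(st, sort(sample(100, 18)),
                      classes = c("linear", "quadratic"))
  model <- fit_maxent(f, beta = 1, seed = 7)
  shifted <- apply_scenario(st, list(tmin_Jan = list(add = 100)))
  clamped <- project_model(model, shifted, clamp = TRUE)
  free <- project_model(model, shifted, clamp = FALSE)
  expect_gt(attr(clamped, "clamped"), 0)
  expect_equal(attr(free, "clamped"), 0L)
  hi <- max(st$layers$tmin_Jan$values)
  pinned <- st
  pinned$layers$tmin_Jan$values[] <- hi
  expect_equal(clamped$values, project_model(model, pinned)$values)
  expect_false(isTRUE(all.equal(clamped$values, free$values)))
})

test_that("projection requires every model layer in the target stack", {
  fx <- projection_fixture()
  expect_error(project_model(fx$model, fx$stack["tmin_Jan"]),
               "missing required layer")
})

test_that("recompute_entropy switches the logistic scaling constant", {
  fx <- projection_fixture()
  shifted <- apply_scenario(fx$stack, list(tmin_Jan = list(mult = 0.2)))
  fixed_H <- project_model(fx$model, shifted)
  new_H <- project_model(fx$model, shifted, recompute_entropy = TRUE)
  expect_false(isTRUE(all.equal(fixed_H$values, new_H$values)))
  # same raw distribution underneath: odds ratios differ by a constant factor
  odds <- function(s) { p <- as.numeric(t(s$values)); p / (1 - p) }
  ratio <- odds(new_H) / odds(fixed_H)
  expect_equal(diff(range(ratio)), 0, tolerance = 1e-10)
})

test_that("area_above_threshold counts cells and is monotone", {
  g <- gn_grid(matrix(c(0.1, 0.4, 0.6, 0.9, NA, 0.5), 2, 3), 0, 0, 1)
  class(g) <- c("probability_surface", class(g))
  a <- area_above_threshold(g, c(0.05, 0.5, 0.7, 0.95))
  expect_equal(unname(a), c(5L, 3L, 1L, 0L))  # NA cells never counted
  expect_true(all(diff(a) <= 0))
})

test_that("elevation correlation matches cor() and enforces alignment", {
  suit <- gn_grid(matrix(seq(0.1, 0.9, length.out = 9), 3, 3), 0, 0, 1)
  class(suit) <- c("probability_surface", class(suit))
  elev <- gn_grid(matrix(1:9, 3, 3), 0, 0, 1)
  expect_equal(elevation_correlation(suit, elev), 1)
  neg <- gn_grid(-elev$values, 0, 0, 1)
  expect_equal(elevation_correlation(suit, neg), -1)
  # NA cells are dropped pairwise
  elev2 <- elev; elev2$values[1, 1] <- NA
  ok <- !is.na(elev2$values)
  expect_equal(elevation_correlation(suit, elev2),
               cor(suit$values[ok], elev$values[ok]))
  off <- gn_grid(matrix(1:9, 3, 3), 5, 0, 1)
  expect_error(elevation_correlation(suit, off), "alignment")
})

test_that("difference maps subtract cellwise and propagate nodata", {
  a <- gn_grid(matrix(c(0.2, 0.4, NA, 0.8), 2, 2), 0, 0, 1)
  b <- gn_grid(matrix(c(0.5, 0.3, 0.1, NA), 2, 2), 0, 0, 1)
  d <- difference_map(a, b)
  expect_equal(d$values, matrix(c(0.3, -0.1, NA, NA), 2, 2))
  expect_error(difference_map(a, gn_grid(matrix(0, 3, 3), 0, 0, 1)),
               "alignment")
})

test_that("shift reports summarize the difference and both correlations", {
  fx <- projection_fixture()
  current <- project_model(fx$model, fx$stack)
  future <- project_model(fx$model,
                          apply_scenario(fx$stack, list(tmin_Jan = list(add = 0.2))))
  elev <- gn_grid(matrix(seq(0, 500, length.out = 100), 10, 10), 0, 0, 1)
  rep <- shift_report(current, future, elev, thresholds = c(0.3, 0.6))
  expect_s3_class(rep, "shift_report")
  expect_equal(rep$diff_mean, mean(future$values - current$values))
  expect_equal(rep$area_current, area_above_threshold(current, c(0.3, 0.6)))
  expect_equal(rep$elev_r_future, elevation_correlation(future, elev))
  expect_output(print(rep), "elevation correlation")
})

test_that("cropping masks outside cells without refitting values", {
  fx <- projection_fixture()
  surf <- project_model(fx$model, fx$stack)
  cr <- crop_surface(surf, xmin = 2, xmax = 6, ymin = 3, ymax = 8)
  expect_equal(dim(cr$values), dim(surf$values))
  inside <- !is.na(cr$values)
  expect_true(any(inside) && any(!inside))
  expect_equal(cr$values[inside], surf$values[inside])
  # cell centers outside the window are nodata (row 1 is the north edge)
  expect_true(all(is.na(cr$values[, 1])))   # lon 0.5 < xmin
  expect_true(all(is.na(cr$values[1, ])))   # lat 9.5 > ymax
})
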