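# Seeded synthetic study-system generator: coastal landscape, monthly
# climate layers coupled to elevation (lapse-rate structure) and coast
# distance, a smooth "true" niche over a small layer subset, grove-clustered
# occurrence records, and future-scenario deltas.

#' Landscape specification
#'
#' Describes a rectangular coastal landscape: a monotone coastal-to-inland
#' elevation ramp, a few smoothed ridges running parallel to the coast, and
#' Gaussian-smoothed noise. Defaults give a 100 x 100 grid at 30 arc-second
#' resolution with up to ~1500 m of relief, loosely shaped like a coastal
#' California county.
#'
#' @param nrows,ncols Grid dimensions.
#' @param cellsize Cell size in degrees (default 1/120, i.e. 30 arc seconds).
#' @param xllcorner,yllcorner Grid origin.
#' @param coast_side Which edge is the coast: `"W"`, `"E"`, `"N"`, `"S"`.
#' @param max_inland_elev Ramp height at the inland edge (m).
#' @param n_ridges Number of coast-parallel ridges.
#' @param ridge_height,ridge_width Ridge amplitude (m) and Gaussian width
#'   (cells).
#' @param noise_amp,noise_len Amplitude (m) and correlation length (cells) of
#'   the smoothed elevation noise.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(nrows = 100, ncols = 100, cellsize = 1 / 120,
                           xllcorner = -120.5, yllcorner = 34.3,
                           coast_side = c("W", "E", "N", "S"),
                           max_inland_elev = 1500, n_ridges = 2,
                           ridge_height = 700, ridge_width = 6,
                           noise_amp = 60, noise_len = 4) {
  coast_side <- match.arg(coast_side)
  structure(as.list(environment()), class = "landscape_spec")
}

# Gaussian-kernel smoothing of a matrix (separable, reflected edges).
gaussian_smooth <- function(m, len) {
  if (len <= 0) return(m)
  half <- max(1L, ceiling(3 * len))
  k <- exp(-0.5 * ((-half:half) / len)^2)
  k <- k / sum(k)
  pad_smooth <- function(x) {  # smooth columns of matrix x
    n <- nrow(x)
    # reflected padding by index arithmetic, valid for any kernel half-width
    src <- (1 - half):(n + half)
    s <- (src - 1) %% (2 * n)
    idx <- ifelse(s < n, s + 1, 2 * n - s)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(pad_smooth(t(pad_smooth(m))))
}

# Fraction of the way inland from the coast, in [0, 1], per cell.
coast_distance_matrix <- function(nrows, ncols, coast_side) {
  colf <- (seq_len(ncols) - 0.5) / ncols
  rowf <- (seq_len(nrows) - 0.5) / nrows
  switch(coast_side,
    W = matrix(colf, nrows, ncols, byrow = TRUE),
    E = matrix(rev(colf), nrows, ncols, byrow = TRUE),
    N = matrix(rowf, nrows, ncols),
    S = matrix(rev(rowf), nrows, ncols))
}

#' Generate a synthetic elevation grid
#'
#' Deterministic under the seed: coastal ramp + coast-parallel Gaussian
#' ridges at seeded positions + Gaussian-smoothed white noise, truncated at
#' zero so elevation is non-negative and the coastal edge is on average the
#' lowest.
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed.
#' @return An elevation [gn_grid] (meters).
#' @export
make_landscape <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "landscape_spec"))
  d <- coast_distance_matrix(spec$nrows, spec$ncols, spec$coast_side)
  elev <- spec$max_inland_elev * d
  with_seed(substream_seed(seed, "landscape"), {
    if (spec$n_ridges > 0) {
      span <- switch(spec$coast_side, W = , E = spec$ncols, spec$nrows)
      pos <- sort(runif(spec$n_ridges, 0.25, 0.9))  # inland fractions
      for (p in pos)
        elev <- elev + spec$ridge_height *
          exp(-0.5 * ((d - p) * span / spec$ridge_width)^2)
    }
    noise <- gaussian_smooth(matrix(rnorm(spec$nrows * spec$ncols),
                                    spec$nrows, spec$ncols), spec$noise_len)
    # smoothing shrinks the variance; rescale to the requested amplitude
    noise <- noise / sd(noise) * spec$noise_amp
    elev <- pmax(elev + noise, 0)
  })
  gn_grid(elev, spec$xllcorner, spec$yllcorner, spec$cellsize)
}

#' Climate-layer specification table
#'
#' One row per (variable, month) layer: additive base value, elevation
#' coefficient (units per km of elevation — a lapse-rate analogue for the
#' temperature variables), coast-distance coefficient (units per full
#' coast-to-inland transect), noise amplitude, noise correlation length
#' (cells), and `shared_rho`, the weight on a per-variable shared noise field
#' that induces correlation among months of the same variable.
#'
#' @param variables Climate variables to include.
#' @param months Months to include.
#' @param shared_rho Cross-month noise-sharing weight in `[0, 1]`.
#' @return A data.frame of class `climate_spec` with one row per layer.
#' @export
default_climate_spec <- function(variables = CLIMATE_VARIABLES,
                                 months = OVERWINTER_MONTHS,
                                 shared_rho = 0.85) {
  base <- c(solar_radiation = 130, vapor_pressure = 1.1, precipitation = 60,
            wind_speed = 3.0, tmean = 14, tmin = 7, tmax = 21)
  elev_coeff <- c(solar_radiation = 6, vapor_pressure = -0.25,
                  precipitation = 25, wind_speed = 0.9,
                  tmean = -6.5, tmin = -6.5, tmax = -6.5)
  coast_coeff <- c(solar_radiation = 12, vapor_pressure = -0.35,
                   precipitation = 8, wind_speed = -1.2,
                   tmean = 2.5, tmin = -2.5, tmax = 5)
  noise_amp <- c(solar_radiation = 7, vapor_pressure = 0.06,
                 precipitation = 12, wind_speed = 0.35,
                 tmean = 0.9, tmin = 1.1, tmax = 1.1)
  month_offset <- list(
    solar_radiation = c(Oct = 25, Nov = 5, Dec = -10, Jan = -5, Feb = 10),
    vapor_pressure = c(Oct = 0.1, Nov = 0, Dec = -0.08, Jan = -0.1, Feb = -0.04),
    precipitation = c(Oct = -35, Nov = -10, Dec = 15, Jan = 25, Feb = 20),
    wind_speed = c(Oct = -0.3, Nov = -0.1, Dec = 0.1, Jan = 0.2, Feb = 0.3),
    tmean = c(Oct = 3, Nov = 1, Dec = -1.5, Jan = -2.5, Feb = -1.5),
    tmin = c(Oct = 3, Nov = 1, Dec = -1.5, Jan = -2.5, Feb = -1.5),
    tmax = c(Oct = 3.5, Nov = 1, Dec = -1.5, Jan = -2.5, Feb = -1))
  rows <- list()
  for (v in variables) for (mo in months)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = layer_name(v, mo), variable = v, month = mo,
      base = base[[v]] + month_offset[[v]][[mo]],
      elev_coeff = elev_coeff[[v]], coast_coeff = coast_coeff[[v]],
      noise_amp = noise_amp[[v]], noise_len = 4, shared_rho = shared_rho,
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("climate_spec", class(out))
  out
}

#' Derive a monthly climate stack from elevation
#'
#' Each layer is `base + elev_coeff * (elev / 1000) + coast_coeff *
#' coast_distance + noise`, where the noise of month `m` of variable `v` is
#' `amp * (rho * shared_v + sqrt(1 - rho^2) * own)`, both fields
#' Gaussian-smoothed seeded white noise. Deterministic under the seed; nodata
#' cells of the elevation grid propagate.
#'
#' @param elev Elevation [gn_grid] (meters).
#' @param spec A [default_climate_spec()]-style data.frame.
#' @param coast_side Coast edge used for the coast-distance field.
#' @param seed Integer seed.
#' @return A [gn_stack] with one layer per spec row.
#' @export
derive_climate <- function(elev, spec, coast_side = "W", seed = 1) {
  stopifnot(is_gn_grid(elev))
  d <- coast_distance_matrix(elev$nrows, elev$ncols, coast_side)
  layers <- list()
  shared <- list()
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    if (is.null(shared[[r$variable]]))
      shared[[r$variable]] <- with_seed(
        substream_seed(seed, paste0("climate-shared-", r$variable)), {
          f <- gaussian_smooth(matrix(rnorm(elev$nrows * elev$ncols),
                                      elev$nrows, elev$ncols), r$noise_len)
          f / sd(f)
        })
    own <- with_seed(substream_seed(seed, paste0("climate-own-", r$layer)), {
      f <- gaussian_smooth(matrix(rnorm(elev$nrows * elev$ncols),
                                  elev$nrows, elev$ncols), r$noise_len)
      f / sd(f)
    })
    noise <- r$noise_amp * (r$shared_rho * shared[[r$variable]] +
                            sqrt(1 - r$shared_rho^2) * own)
    vals <- r$base + r$elev_coeff * (elev$values / 1000) +
      r$coast_coeff * d + noise
    vals[is.na(elev$values)] <- NA_real_
    layers[[r$layer]] <- gn_grid(vals, elev$xllcorner, elev$yllcorner,
                                 elev$cellsize, elev$nodata_value)
  }
  gn_stack(layers)
}

#' Niche specification
#'
#' The "true" niche is `suitability = plogis(a + sum_i b_i z_i)` where the
#' `z_i` are the active layers standardized over valid cells. Grove centers
#' are drawn with probability proportional to suitability; each grove emits a
#' cluster of records scattered around its center.
#'
#' @param active Named numeric vector: active layer name -> coefficient `b`.
#' @param intercept Intercept `a` of the suitability logit.
#' @param n_groves Number of groves to sample.
#' @param max_records_per_grove Records per grove drawn uniformly from
#'   `1:max_records_per_grove`.
#' @param scatter_sd Within-grove scatter (map units; truncated normal,
#'   bounded at 2.5 sd).
#' @return A list of class `niche_spec`.
#' @export
niche_spec <- function(active = c(tmin_Jan = 2.0, precipitation_Feb = 1.2),
                       intercept = -0.5, n_groves = 200,
                       max_records_per_grove = 3, scatter_sd = 0.002) {
  stopifnot(length(active) >= 1, !is.null(names(active)))
  structure(as.list(environment()), class = "niche_spec")
}

#' True suitability surface of a niche
#'
#' @param stack A [gn_stack] containing the niche's active layers.
#' @param spec A [niche_spec()].
#' @return A suitability [gn_grid] with values in (0, 1) on valid cells.
#' @export
true_suitability <- function(stack, spec) {
  miss <- setdiff(names(spec$active), names(stack$layers))
  if (length(miss)) stop("stack lacks active niche layer(s): ",
                         paste(miss, collapse = ", "))
  g <- stack$layers[[1]]
  eta <- matrix(spec$intercept, g$nrows, g$ncols)
  for (nm in names(spec$active)) {
    v <- stack$layers[[nm]]$values
    mu <- mean(v[stack$mask]); sdv <- sd(v[stack$mask])
    eta <- eta + spec$active[[nm]] * (v - mu) / sdv
  }
  suit <- plogis(eta)
  suit[!stack$mask] <- NA_real_
  gn_grid(suit, g$xllcorner, g$yllcorner, g$cellsize, g$nodata_value)
}

# Truncated-normal draws bounded at +/- bound*sd (inverse-CDF method).
rtnorm <- function(n, sd, bound = 2.5) {
  u <- runif(n, stats::pnorm(-bound), stats::pnorm(bound))
  sd * stats::qnorm(u)
}

#' Sample grove-clustered occurrence records
#'
#' Grove centers are cells drawn without replacement with probability
#' proportional to suitability; each grove emits `1:max_records_per_grove`
#' records scattered around the cell center by a truncated normal, clamped
#' inside the grid extent. Deterministic under the seed.
#'
#' @param suitability A suitability [gn_grid] (values in `(0, 1)`, NA =
#'   invalid).
#' @param spec A [niche_spec()].
#' @param seed Integer seed.
#' @return A data.frame of raw records (`grove_id, lon, lat, occupied`) with
#'   attribute `"centers"`, the sampled center cell indices.
#' @export
sample_groves <- function(suitability, spec, seed = 1) {
  valid <- which(t(!is.na(suitability$values)))
  if (spec$n_groves > length(valid))
    stop("n_groves exceeds the number of valid cells")
  w <- cell_value(suitability, valid)
  with_seed(substream_seed(seed, "groves"), {
    centers <- valid[sample.int(length(valid), spec$n_groves, prob = w)]
    ctr <- cell_center(suitability, centers)
    nrec <- sample.int(spec$max_records_per_grove, spec$n_groves, replace = TRUE)
    rows <- vector("list", spec$n_groves)
    xmin <- suitability$xllcorner + 1e-9
    xmax <- suitability$xllcorner + suitability$ncols * suitability$cellsize - 1e-9
    ymin <- suitability$yllcorner + 1e-9
    ymax <- suitability$yllcorner + suitability$nrows * suitability$cellsize - 1e-9
    for (i in seq_len(spec$n_groves)) {
      k <- nrec[i]
      lon <- pmin(pmax(ctr$lon[i] + rtnorm(k, spec$scatter_sd), xmin), xmax)
      lat <- pmin(pmax(ctr$lat[i] + rtnorm(k, spec$scatter_sd), ymin), ymax)
      rows[[i]] <- data.frame(
        grove_id = sprintf("G%04d", i), lon = lon, lat = lat,
        occupied = TRUE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "centers") <- centers
    out
  })
}

#' Apply a future-climate scenario to a stack
#'
#' Per-layer linear forcing `value -> value * mult + add`, the standard way
#' a downscaled concentration-pathway scenario perturbs a baseline stack.
#' Layers without a delta are passed through unchanged (and logged); nodata
#' is untouched.
#'
#' @param stack A [gn_stack].
#' @param deltas Named list: layer name -> `list(add =, mult =)` (either
#'   element may be omitted; defaults 0 and 1).
#' @return A [gn_stack] with identical layout.
#' @export
apply_scenario <- function(stack, deltas) {
  out <- stack$layers
  missing_delta <- setdiff(names(out), names(deltas))
  if (length(missing_delta))
    log_msg("apply_scenario: no delta for layer(s) ",
            paste(missing_delta, collapse = ", "), "; left unchanged")
  unknown <- setdiff(names(deltas), names(out))
  if (length(unknown))
    warning("deltas reference unknown layer(s): ",
            paste(unknown, collapse = ", "))
  for (nm in intersect(names(deltas), names(out))) {
    d <- deltas[[nm]]
    add <- d$add %||% 0; mult <- d$mult %||% 1
    g <- out[[nm]]
    g$values <- g$values * mult + add
    out[[nm]] <- g
  }
  gn_stack(out)
}

#' Uniform warming deltas for the temperature layers
#'
#' @param stack A [gn_stack].
#' @param dT Additive warming (same units as the temperature layers).
#' @param variables Variables to warm (default the three temperature
#'   variables).
#' @return A delta list for [apply_scenario()].
#' @export
warming_deltas <- function(stack, dT,
                           variables = c("tmean", "tmin", "tmax")) {
  nm <- names(stack$layers)
  pv <- parse_layer_name(nm)
  sel <- nm[pv$variable %in% variables]
  setNames(lapply(sel, function(x) list(add = dT)), sel)
}

#' Simulate a complete synthetic study system
#'
#' Convenience wrapper tying the generator together: landscape, climate
#' stack, true niche suitability, and grove-clustered occurrence records,
#' all driven by one seed through named substreams.
#'
#' @param seed Integer run seed.
#' @param landscape A [landscape_spec()].
#' @param climate A climate spec data.frame (default
#'   `default_climate_spec()` restricted to `tmin` and `precipitation`,
#'   giving 10 layers).
#' @param niche A [niche_spec()].
#' @return A list: `elevation`, `stack`, `suitability`, `records`, plus the
#'   specs used.
#' @export
simulate_study <- function(seed = 1,
                           landscape = landscape_spec(),
                           climate = default_climate_spec(
                             variables = c("tmin", "precipitation")),
                           niche = niche_spec()) {
  elev <- make_landscape(landscape, seed)
  stack <- derive_climate(elev, climate, landscape$coast_side, seed)
  suit <- true_suitability(stack, niche)
  records <- sample_groves(suit, niche, seed)
  list(elevation = elev, stack = stack, suitability = suit,
       records = records, landscape = landscape, climate = climate,
       niche = niche, seed = seed)
}
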