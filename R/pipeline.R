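# Config-driven orchestration: occurrence reduction -> beta optimization ->
# variable elimination -> final fit -> current and projected surfaces ->
# shift diagnostics and reporting.

PIPELINE_CONFIG_KEYS <- c(
  "synthetic", "inputs", "scenario", "dedupe_cells", "elimination", "beta",
  "classes", "max_background", "thresholds", "clamp",
  "nontransfer_threshold", "label")

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected. Either `synthetic` (generator specs) or
#' `inputs` (paths to `.asc` layers, an occurrence CSV and an elevation grid)
#' must describe the data.
#'
#' @param config A named list (e.g. from [yaml::read_yaml()]), or a YAML/JSON
#'   file path.
#' @return The validated config list, classed `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    synthetic = NULL, inputs = NULL,
    scenario = list(warming_dT = 2.0),
    dedupe_cells = TRUE,
    elimination = "top_variable_uncorrelated",
    beta = list(coarse = 1:7, replicates = 10, mode = "bootstrap",
                final_range = c(0.1, 2.0), optimize = TRUE, fixed = 1.0),
    classes = c("linear", "quadratic", "product"),
    max_background = 10000,
    thresholds = seq(0.1, 0.9, by = 0.1),
    clamp = TRUE,
    nontransfer_threshold = 0.05,
    label = "run")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in setdiff(names(defaults$beta), names(config$beta)))
    config$beta[[nm]] <- defaults$beta[[nm]]
  if (!config$elimination %in% c("top_variable_uncorrelated", "uncorrelated", "none"))
    stop("elimination must be one of: top_variable_uncorrelated, uncorrelated, none")
  structure(config, class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

build_study_inputs <- function(config, seed) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    stack <- load_stack(unlist(inp$stack))
    records <- read_occurrences(inp$occurrences)
    elevation <- if (!is.null(inp$elevation)) read_ascii_grid(inp$elevation)
    return(list(stack = stack, records = records, elevation = elevation,
                suitability = NULL))
  }
  syn <- config$synthetic %||% list()
  ls_args <- syn$landscape %||% list()
  landscape <- do.call(landscape_spec, ls_args)
  cl_args <- syn$climate %||% list(variables = c("tmin", "precipitation"))
  climate <- do.call(default_climate_spec, cl_args)
  ni_args <- syn$niche %||% list()
  if (!is.null(ni_args$active)) ni_args$active <- unlist(ni_args$active)
  niche <- do.call(niche_spec, ni_args)
  sim <- simulate_study(seed, landscape, climate, niche)
  list(stack = sim$stack, records = sim$records, elevation = sim$elevation,
       suitability = sim$suitability, niche = niche)
}

scenario_deltas <- function(config, stack) {
  sc <- config$scenario
  if (is.null(sc)) return(NULL)
  if (!is.null(sc$deltas)) return(sc$deltas)
  if (!is.null(sc$warming_dT))
    return(warming_deltas(stack, sc$warming_dT,
                          variables = sc$variables %||% c("tmean", "tmin", "tmax")))
  NULL
}

#' Run the full modelling pipeline
#'
#' Executes, in order: data generation or loading, systematic occurrence
#' reduction, regularization optimization (coarse 1-7 sweep then 0.1
#' bracketing), variable elimination (per the configured method), a final
#' 0.1-2.0 beta scan on the retained layers, the final fit, the current
#' probability surface, the scenario-projected surface, and the shift
#' report. Idempotent under identical `(config, seed)`.
#'
#' @param config A [run_config()] (or list / file path coercible to one).
#' @param seed Integer run seed.
#' @param out_dir Optional output directory; when given, all artifacts
#'   (model JSON, `.asc` surfaces, AICc CSVs, trace JSON, report JSON and a
#'   markdown summary) are written there.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = run_config(), seed = 1, out_dir = NULL) {
  config <- run_config(unclass(config))
  t0 <- Sys.time()
  inputs <- pipeline_stage("data", build_study_inputs(config, seed))
  stack <- inputs$stack

  occ <- pipeline_stage("occurrences",
    prepare_presences(inputs$records, stack,
                      dedupe_cells = isTRUE(config$dedupe_cells)))
  log_msg(sprintf("occurrences: %d presences from %d raw records",
                  length(occ$cells), occ$provenance$n_raw))

  scans <- list()
  optimize <- isTRUE(config$beta$optimize) && config$elimination != "none"
  if (optimize) {
    feats_all <- pipeline_stage("features",
      build_features(stack, occ$cells, classes = config$classes,
                     max_background = config$max_background, seed = seed))
    coarse <- pipeline_stage("beta-coarse",
      beta_scan(feats_all, config$beta$coarse, config$beta$replicates,
                config$beta$mode, seed))
    refined <- pipeline_stage("beta-bracket",
      bracket_beta(feats_all, coarse, replicates = config$beta$replicates,
                   mode = config$beta$mode, seed = seed))
    base_beta <- refined$best_beta
    scans$coarse <- coarse; scans$bracket <- refined

    elim <- pipeline_stage("elimination", switch(config$elimination,
      top_variable_uncorrelated = eliminate_top_variable_uncorrelated(
        stack, occ$cells, base_beta, classes = config$classes,
        max_background = config$max_background, seed = seed),
      uncorrelated = eliminate_uncorrelated(
        stack, occ$cells, base_beta, classes = config$classes,
        max_background = config$max_background, seed = seed)))
    retained <- elim$retained

    feats_final <- pipeline_stage("features-final",
      build_features(stack[retained], occ$cells, classes = config$classes,
                     max_background = config$max_background, seed = seed))
    final <- pipeline_stage("beta-final",
      final_beta_scan(feats_final, config$beta$final_range,
                      config$beta$replicates, config$beta$mode, seed))
    final_beta <- final$best_beta
    scans$final <- final
  } else {
    base_beta <- final_beta <- config$beta$fixed
    elim <- NULL
    retained <- names(stack$layers)
    feats_final <- pipeline_stage("features-final",
      build_features(stack, occ$cells, classes = config$classes,
                     max_background = config$max_background, seed = seed))
  }

  model <- pipeline_stage("fit",
    fit_maxent(feats_final, beta = final_beta, seed = seed))
  model$header <- stack_header(stack)
  model$provenance <- occ$provenance

  current <- pipeline_stage("project-current",
    project_model(model, stack, clamp = isTRUE(config$clamp)))

  deltas <- scenario_deltas(config, stack)
  future <- shift <- NULL
  nontransferable <- NA
  if (!is.null(deltas)) {
    future_stack <- pipeline_stage("scenario", apply_scenario(stack, deltas))
    future <- pipeline_stage("project-future",
      project_model(model, future_stack, clamp = isTRUE(config$clamp)))
    mean_future_p <- mean(future$values, na.rm = TRUE)
    nontransferable <- mean_future_p < config$nontransfer_threshold
    if (!is.null(inputs$elevation))
      shift <- pipeline_stage("shift-report",
        shift_report(current, future, inputs$elevation,
                     thresholds = config$thresholds))
  }

  p_at_occ <- logistic_output(model, occ$cells)
  report <- structure(list(
    label = config$label, seed = seed, config = unclass(config),
    provenance = occ$provenance,
    presence_cells = occ$cells,
    base_beta = base_beta, final_beta = final_beta,
    retained_layers = retained,
    elimination = elim,
    scans = scans,
    contributions = percent_contribution(model),
    model = model,
    current = current, future = future,
    shift = shift,
    nontransferable = nontransferable,
    p_at_occurrences = range(p_at_occ),
    elevation = inputs$elevation,
    suitability = inputs$suitability,
    version = as.character(utils::packageVersion("groveniche")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> '%s' (seed %d, %.1f s)\n", x$label, x$seed,
              x$elapsed_s))
  cat(sprintf("  presences: %d; base beta %g; final beta %g\n",
              length(x$presence_cells), x$base_beta, x$final_beta))
  cat("  retained layers: ", paste(x$retained_layers, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  logistic output at occurrences: %.3f - %.3f\n",
              x$p_at_occurrences[1], x$p_at_occurrences[2]))
  if (!is.null(x$shift))
    cat(sprintf("  elevation correlation: current %.3f -> future %.3f\n",
                x$shift$elev_r_current, x$shift$elev_r_future))
  if (isTRUE(x$nontransferable))
    cat("  WARNING: projected surface is near-uniformly low (non-transferable model)\n")
  invisible(x)
}

#' Write a run report and its artifacts to a directory
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_json(report$model, file.path(dir, "model.json"))
  write_ascii_grid(report$current, file.path(dir, "surface_current.asc"))
  if (!is.null(report$future))
    write_ascii_grid(report$future, file.path(dir, "surface_future.asc"))
  for (nm in names(report$scans))
    write_scan_csv(report$scans[[nm]], file.path(dir, paste0("aicc_", nm, ".csv")))
  if (!is.null(report$elimination))
    write_trace_json(report$elimination$trace, file.path(dir, "elimination_trace.json"))
  summary_obj <- list(
    label = report$label, seed = report$seed, version = report$version,
    provenance = report$provenance,
    base_beta = report$base_beta, final_beta = report$final_beta,
    retained_layers = report$retained_layers,
    contributions = as.list(report$contributions),
    p_at_occurrences = report$p_at_occurrences,
    nontransferable = report$nontransferable,
    shift = if (!is.null(report$shift)) unclass(report$shift),
    config = report$config)
  jsonlite::write_json(summary_obj, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null")
  md <- c(
    sprintf("# Run report: %s", report$label),
    "",
    sprintf("- seed: %d", report$seed),
    sprintf("- presences: %d (raw records: %d)", length(report$presence_cells),
            report$provenance$n_raw),
    sprintf("- base beta: %g; final beta: %g", report$base_beta, report$final_beta),
    sprintf("- retained layers: %s", paste(report$retained_layers, collapse = ", ")),
    sprintf("- logistic output at occurrences: %.3f-%.3f",
            report$p_at_occurrences[1], report$p_at_occurrences[2]))
  if (!is.null(report$shift))
    md <- c(md, sprintf("- elevation correlation: current %.3f, future %.3f",
                        report$shift$elev_r_current, report$shift$elev_r_future))
  if (isTRUE(report$nontransferable))
    md <- c(md, "- **flag**: projected surface near-uniformly low (non-transferable model)")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Compare the current surfaces of several runs
#'
#' @param reports List of `run_report` objects sharing a current stack.
#' @return A list: `correlation` (pairwise Pearson matrix of current
#'   surfaces over shared valid cells) and `p_at_occurrences` (per-run
#'   min/max logistic output at that run's presences).
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  labels <- vapply(reports, function(r) r$label, "")
  surfs <- lapply(reports, function(r) r$current)
  for (i in seq_along(surfs)[-1]) {
    mism <- same_header(surfs[[1]], surfs[[i]])
    if (length(mism))
      stop("alignment error between run surfaces: ", paste(mism, collapse = ", "))
  }
  ok <- Reduce(`&`, lapply(surfs, function(s) !is.na(s$values)))
  M <- vapply(surfs, function(s) s$values[ok], numeric(sum(ok)))
  corr <- cor(M)
  dimnames(corr) <- list(labels, labels)
  pr <- t(vapply(reports, function(r) r$p_at_occurrences, numeric(2)))
  dimnames(pr) <- list(labels, c("min", "max"))
  list(correlation = corr, p_at_occurrences = pr)
}
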