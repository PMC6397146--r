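#' Pipeline configuration
#'
#' Builds (and validates lazily; see [validate_pipeline_config()]) the
#' configuration driving [run_pipeline()]. With `simulate = TRUE` the
#' pipeline generates its own synthetic inputs; otherwise paths to counts,
#' traits, sensor and/or series CSVs must be given.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param simulate Generate synthetic inputs (default `TRUE`).
#' @param counts,traits,sensor,series Input CSV paths (used when
#'   `simulate = FALSE`; `traits` optional, defaulting to the bundled
#'   synthetic table).
#' @param n_years Simulated span in years.
#' @param period,harmonics,trend,seasonal_tvp,level ASDHR stage parameters.
#' @param expected_index Reference expected index for the EQR stage.
#' @param window_days,min_coverage,log_vars Antecedent stage parameters.
#' @param axes,top_species Ordination stage parameters.
#' @param stages Character vector of stages to run, in dependency order,
#'   from `c("eqr", "asdhr", "antecedent", "ordination")`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, simulate = TRUE,
                            counts = NULL, traits = NULL, sensor = NULL,
                            series = NULL, n_years = 5.5,
                            period = 1, harmonics = 2, trend = "irw",
                            seasonal_tvp = "rw", level = 0.95,
                            expected_index = 25,
                            window_days = 21, min_coverage = 0.5,
                            log_vars = c("turbidity", "rainfall", "discharge"),
                            axes = 2, top_species = 10,
                            stages = c("eqr", "asdhr", "antecedent",
                                       "ordination")) {
  structure(list(seed = seed, simulate = simulate,
                 paths = list(counts = counts, traits = traits,
                              sensor = sensor, series = series),
                 n_years = n_years, period = period, harmonics = harmonics,
                 trend = trend, seasonal_tvp = seasonal_tvp, level = level,
                 expected_index = expected_index, window_days = window_days,
                 min_coverage = min_coverage, log_vars = log_vars,
                 axes = axes, top_species = top_species, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  cfg <- do.call(pipeline_config, y[intersect(names(y), known)])
  if (!is.null(y$paths)) cfg$paths[names(y$paths)] <- y$paths
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config A `"pipeline_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges and, when not simulating, that every referenced
#' input file exists. All problems are reported together, before any
#' computation starts.
#'
#' @param config A `"pipeline_config"`.
#' @return `config`, invisibly, or an error listing every problem.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  probs <- character(0)
  chk <- function(cond, msg) if (!cond) probs <<- c(probs, msg)
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  chk(config$period > 0, "period must be positive")
  chk(config$harmonics >= 1 && config$harmonics <= 6,
      "harmonics must be in 1..6")
  chk(config$level > 0 && config$level < 1, "level must be in (0,1)")
  chk(config$expected_index >= 0 && config$expected_index < 100,
      "expected_index must be in [0,100)")
  chk(config$window_days > 0, "window_days must be positive")
  chk(config$min_coverage >= 0 && config$min_coverage <= 1,
      "min_coverage must be in [0,1]")
  chk(all(config$stages %in% c("eqr", "asdhr", "antecedent", "ordination")),
      "unknown stage name")
  if (!isTRUE(config$simulate)) {
    need <- c(counts = "eqr", sensor = "antecedent")
    for (p in names(need))
      if (need[[p]] %in% config$stages)
        chk(!is.null(config$paths[[p]]) && file.exists(config$paths[[p]]),
            sprintf("input file for `%s` missing or not found", p))
  }
  if (!is.null(config$paths$traits))
    chk(file.exists(config$paths$traits), "traits file not found")
  if (length(probs))
    stop("pipeline configuration invalid:\n  - ",
         paste(probs, collapse = "\n  - "))
  invisible(config)
}

#' Run the analysis pipeline end-to-end
#'
#' Validates the configuration, then executes the requested stages in
#' dependency order: (optional) simulation of counts/sensor inputs, valve
#' counts -> EQR series, EQR series -> ASDHR seasonal decomposition, sensor
#' record -> antecedent environmental matrix, and species + environment ->
#' PCA ordination. Each stage writes its outputs under `out_dir`; a
#' machine-readable `summary.json` and a run log (with the config snapshot
#' hash and package version) complete the run. Warnings are logged with
#' stable greppable prefixes (`[warn]`). A failed stage aborts downstream
#' stages.
#'
#' @param config A `"pipeline_config"`, or a path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with the stage results and the summary.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snap <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, snap)
  log_path <- file.path(out_dir, "run.log")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf), add = TRUE)
  log_msg <- function(..., prefix = "[info]") {
    line <- paste(prefix, sprintf(...))
    writeLines(line, logf)
    if (!quiet) message(line)
  }
  log_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      log_msg("%s", conditionMessage(w), prefix = "[warn]")
      invokeRestart("muffleWarning")
    }, message = function(m) {
      log_msg("%s", sub("\n$", "", conditionMessage(m)), prefix = "[info]")
      invokeRestart("muffleMessage")
    })
  }
  log_msg("seasdhr %s | config hash %s | seed %d",
          as.character(utils::packageVersion("seasdhr")),
          unname(tools::md5sum(snap)), as.integer(config$seed))

  results <- list()
  summary <- list(seed = config$seed,
                  package_version = as.character(utils::packageVersion("seasdhr")),
                  config_hash = unname(tools::md5sum(snap)))

  traits <- if (!is.null(config$paths$traits))
    read_trait_table(config$paths$traits) else default_trait_table()

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    log_msg("simulating inputs (%.1f years, seed %d)", config$n_years,
            as.integer(config$seed))
    dates <- gen_sample_dates(config$n_years, config$seed)
    gc_ <- log_warnings(gen_counts(dates, seed = config$seed))
    counts <- gc_$counts
    write_counts_csv(counts, file.path(out_dir, "counts.csv"))
    write_truth_json(gc_$truth, file.path(out_dir, "truth_counts.json"))
    gs_ <- gen_sensor(min(dates) - config$window_days - 1, max(dates),
                      seed = config$seed)
    sensor <- gs_$sensor
    write_sensor_csv(sensor, file.path(out_dir, "sensor.csv"),
                     units_path = file.path(out_dir, "sensor_units.json"))
    write_truth_json(gs_$truth[setdiff(names(gs_$truth), "event_times")],
                     file.path(out_dir, "truth_sensor.json"))
  } else {
    counts <- if (!is.null(config$paths$counts)) read_counts_csv(config$paths$counts)
    sensor <- if (!is.null(config$paths$sensor)) read_sensor_csv(config$paths$sensor)
  }

  # --- eqr ----------------------------------------------------------------
  series <- NULL
  if ("eqr" %in% config$stages) {
    log_msg("stage eqr: %d samples, expected index %.1f",
            nrow(counts$counts), config$expected_index)
    er <- log_warnings(eqr_series(counts, traits, config$expected_index))
    utils::write.csv(er$table, file.path(out_dir, "eqr_table.csv"),
                     row.names = FALSE)
    write_series_csv(er$series, file.path(out_dir, "eqr_series.csv"))
    results$eqr <- er
    series <- er$series
    summary$status_counts <- as.list(table(er$table$status))
    summary$eqr_capped <- sum(er$table$capped)
  }
  if (is.null(series) && !is.null(config$paths$series))
    series <- read_series_csv(config$paths$series)

  # --- asdhr --------------------------------------------------------------
  if ("asdhr" %in% config$stages) {
    if (is.null(series)) stop("asdhr stage needs an EQR stage or a series file")
    log_msg("stage asdhr: n = %d, period %.3g yr, %d harmonic(s)",
            length(series$times), config$period, config$harmonics)
    fit <- log_warnings(asdhr(series, period = config$period,
                              harmonics = config$harmonics,
                              trend = config$trend,
                              seasonal = config$seasonal_tvp,
                              level = config$level))
    write_fit_csv(fit, file.path(out_dir, "asdhr_fit.csv"))
    fit_summary_json(fit, file.path(out_dir, "asdhr_summary.json"))
    results$asdhr <- fit
    summary$r_squared <- fit$r.squared
    summary$f_statistic <- unname(fit$fstatistic["value"])
    summary$f_pvalue <- fit$f.pvalue
    log_msg("stage asdhr: R-squared %.3f, F p-value %.3g", fit$r.squared,
            fit$f.pvalue)
  }

  # --- antecedent ---------------------------------------------------------
  env <- NULL
  if ("antecedent" %in% config$stages) {
    if (is.null(sensor)) stop("antecedent stage needs a sensor record")
    log_msg("stage antecedent: %d-day window, min coverage %.2f",
            config$window_days, config$min_coverage)
    env <- log_warnings(build_env_matrix(sensor, counts$dates,
                                         window_days = config$window_days,
                                         min_coverage = config$min_coverage,
                                         log_vars = config$log_vars))
    utils::write.csv(data.frame(date = rownames(env), env),
                     file.path(out_dir, "env.csv"), row.names = FALSE)
    results$antecedent <- env
  }

  # --- ordination ---------------------------------------------------------
  if ("ordination" %in% config$stages) {
    log_msg("stage ordination: %d axes, top %d species by fit",
            config$axes, config$top_species)
    sp <- log_transform(relative_abundance(counts) * 100)
    keep <- if (!is.null(env)) match(rownames(env), format(counts$dates))
            else seq_along(counts$dates)
    ord <- pca_species(sp[keep, , drop = FALSE], n_axes = config$axes,
                       top_species = config$top_species)
    utils::write.csv(data.frame(date = format(counts$dates[keep]),
                                ord$sample_scores),
                     file.path(out_dir, "sample_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(taxon = rownames(ord$species_scores),
                                ord$species_scores, fit = ord$species_fit),
                     file.path(out_dir, "species_scores.csv"), row.names = FALSE)
    summary$eig_frac <- ord$eig_frac[seq_len(ord$n_axes)]
    if (!is.null(env)) {
      arrows <- project_env(ord, env)
      utils::write.csv(data.frame(variable = rownames(arrows), arrows),
                       file.path(out_dir, "env_arrows.csv"), row.names = FALSE)
      results$env_arrows <- arrows
    }
    writeLines(jsonlite::toJSON(list(eig_frac = ord$eig_frac,
                                     top_species = ord$top_species),
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "ordination.json"))
    results$ordination <- ord
  }

  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "summary.json"))
  log_msg("pipeline complete: outputs in %s", out_dir)
  results$summary <- summary
  invisible(results)
}
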