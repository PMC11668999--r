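#' Pipeline run configuration
#'
#' Collects everything a full run needs: either the four input file paths
#' or a generator configuration for simulate mode, plus the analysis
#' settings. Defaults equal the study protocol: 15 m contact radius,
#' 4-decimal place discretization, at least 4 prompts per day, Friday-
#' Sunday weekend, 50% compliance cutoff.
#'
#' @param gps_path,ema_path,participants_path,pois_path Input files
#'   (ignored in simulate mode).
#' @param generator A [generator_config()] to simulate inputs from, or
#'   NULL to read files.
#' @param radius_m Trigger-point contact radius in metres.
#' @param decimals Discretization decimals.
#' @param min_prompts Prompt-count day-inclusion threshold.
#' @param min_compliance Participant compliance cutoff.
#' @param series Also fit the 1-6 prompt sensitivity series.
#' @param tz Timezone for day boundaries.
#' @param seed Seed for simulate mode.
#' @param out_dir Output directory (NULL = nothing written).
#' @return Object of class `run_config`.
#' @export
run_config <- function(gps_path = NULL, ema_path = NULL,
                       participants_path = NULL, pois_path = NULL,
                       generator = NULL, radius_m = 15, decimals = 4,
                       min_prompts = 4, min_compliance = 0.5,
                       series = FALSE, tz = "Europe/Berlin", seed = NULL,
                       out_dir = NULL) {
  stopifnot(radius_m > 0, decimals >= 0, min_prompts %in% 1:6,
            min_compliance >= 0, min_compliance <= 1)
  if (is.null(generator)) {
    for (p in c(gps_path, ema_path, participants_path, pois_path)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  }
  structure(
    list(
      gps_path = gps_path, ema_path = ema_path,
      participants_path = participants_path, pois_path = pois_path,
      generator = generator, radius_m = radius_m, decimals = decimals,
      min_prompts = min_prompts, min_compliance = min_compliance,
      series = series, tz = tz, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate inputs, validate,
#' geospatial day summaries, EMA scoring and day aggregation with the
#' day-shifted outcome, compliance and prompt-count filtering, model fit
#' (optionally the sensitivity series) — and returns a run report with
#' row counts and exclusions at every stage. When `out_dir` is set, all
#' intermediates and a JSON/Markdown report are written there.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: list with `counts`,
#'   `compliance`, `day_table`, `model_table`, `fit`, `null_comparison`,
#'   `r2`, `series` (or NULL), `config`, `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$generator)) {
    study <- simulate_study(config$generator, seed = config$seed)
    gps <- study$gps
    ema <- study$prompts
    participants <- study$participants
    pois <- study$pois
  } else {
    validate_inputs(config$gps_path, config$ema_path,
                    config$participants_path, config$pois_path)
    gps <- read_gps_csv(config$gps_path)
    ema <- read_ema_csv(config$ema_path)
    participants <- read_participants_csv(config$participants_path)
    pois <- read_poi_geojson(config$pois_path)
  }

  geo <- geo_day_summaries(gps, pois, radius_m = config$radius_m,
                           decimals = config$decimals, tz = config$tz)
  day_table <- build_day_table(ema, geo, participants)
  compliance <- compliance_report(ema, participants)
  in_ids <- compliance$participant_id[compliance$included]
  modeled <- day_table[day_table$participant_id %in% in_ids, ,
                       drop = FALSE]
  model_table <- filter_model_days(modeled, config$min_prompts)

  fit <- fit_alcohol_glmm(model_table)
  cmp <- null_model_comparison(fit)
  r2 <- pseudo_r2(fit)
  series <- if (isTRUE(config$series)) {
    sensitivity_series(modeled)
  }

  counts <- list(
    participants_raw = nrow(participants),
    participants_included = length(in_ids),
    participants_excluded_compliance = nrow(participants) - length(in_ids),
    gps_fixes = nrow(gps),
    geo_days = nrow(geo),
    ema_days = nrow(day_table),
    days_excluded = nrow(modeled) - nrow(model_table),
    day_exclusions = as.list(attr(model_table, "exclusions")),
    model_days = nrow(model_table)
  )
  report <- structure(
    list(
      counts = counts,
      compliance = compliance,
      day_table = day_table,
      model_table = model_table,
      fit = fit,
      null_comparison = cmp,
      r2 = r2,
      series = series,
      config = config,
      version = as.character(packageVersion("emaroam"))
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("EMA/GPS alcohol-use pipeline run\n")
  cat(sprintf(
    "  participants: %d raw, %d included (compliance >= %.0f%%)\n",
    x$counts$participants_raw, x$counts$participants_included,
    100 * x$config$min_compliance
  ))
  cat(sprintf(
    "  model days: %d (min %d prompts/day)\n",
    x$counts$model_days, x$config$min_prompts
  ))
  cat(sprintf(
    "  LRT chi-square %.2f on %d df, p = %.3g; R2 marginal %.3f, conditional %.3f\n",
    x$null_comparison$lr_chisq, x$null_comparison$df,
    x$null_comparison$p, x$r2$r2_marginal, x$r2$r2_conditional
  ))
  print(x$fit)
  invisible(x)
}

# Serialize a run report to JSON + Markdown + CSV intermediates.
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$day_table, file.path(dir, "day_table.csv"),
            row.names = FALSE)
  write.csv(report$model_table, file.path(dir, "model_table.csv"),
            row.names = FALSE)
  write.csv(report$compliance, file.path(dir, "compliance.csv"),
            row.names = FALSE)
  write.csv(report$fit$coefficients, file.path(dir, "coefficients.csv"),
            row.names = FALSE)
  if (!is.null(report$series)) {
    write.csv(summarize_series(report$series),
              file.path(dir, "sensitivity_series.csv"), row.names = FALSE)
  }
  json <- list(
    counts = report$counts,
    model = list(
      coefficients = report$fit$coefficients,
      sigma_u2 = report$fit$sigma_u2,
      deviance = report$fit$deviance,
      lr_chisq = report$null_comparison$lr_chisq,
      lr_df = report$null_comparison$df,
      lr_p = report$null_comparison$p,
      r2_marginal = report$r2$r2_marginal,
      r2_conditional = report$r2$r2_conditional,
      n_days = report$fit$n_days,
      n_participants = report$fit$n_participants
    ),
    settings = list(
      radius_m = report$config$radius_m,
      decimals = report$config$decimals,
      min_prompts = report$config$min_prompts,
      min_compliance = report$config$min_compliance,
      tz = report$config$tz,
      seed = report$config$seed
    ),
    version = report$version
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  md <- c(
    "# Pipeline run report",
    "",
    sprintf("- participants: %d raw, %d included",
            report$counts$participants_raw,
            report$counts$participants_included),
    sprintf("- model days: %d (threshold %d prompts/day)",
            report$counts$model_days, report$config$min_prompts),
    sprintf("- LRT: chi-square %.3f, df %d, p %.4g",
            report$null_comparison$lr_chisq, report$null_comparison$df,
            report$null_comparison$p),
    sprintf("- pseudo-R2: marginal %.3f, conditional %.3f",
            report$r2$r2_marginal, report$r2$r2_conditional),
    "",
    "## Coefficients",
    "",
    paste0("| term | b | SE | z | p |"),
    paste0("|---|---|---|---|---|"),
    sprintf("| %s | %.3f | %.3f | %.3f | %.4g |",
            report$fit$coefficients$term, report$fit$coefficients$b,
            report$fit$coefficients$se, report$fit$coefficients$z,
            report$fit$coefficients$p)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
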