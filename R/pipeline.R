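#' Run the complete falling-weight study end to end
#'
#' Orchestrates the full pipeline: synthetic dataset generation, trace
#' segmentation, per-test energy metrics, reference-energy detection,
#' undamped-force estimation, per-layer transfer functions and the
#' repeated-loading statistics. All stage outputs are returned and, when
#' `out_dir` is given, written as CSV files together with a run manifest
#' and a plain-text summary report. The pair (config, seed) fully
#' determines every output.
#'
#' @param config A [study_config()].
#' @param params A [foam_params()]; the frozen calibrated defaults if
#'   omitted.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param out_dir Optional output directory.
#' @return An object of class `impact_study`: a list with `config`,
#'   `params`, `seed`, `dataset`, `metrics`, `e_ref`, `undamped`,
#'   `transfer` (list of `transfer_fn`), `table1` (list of
#'   `repeated_loading_result`), and `manifest`.
#' @export
run_full_study <- function(config = study_config(), params = foam_params(),
                           seed = config$seed, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dataset <- stage("simulate", generate_dataset(config, params, seed))
  e_ref <- stage("reference_energy", reference_energy(dataset, config))
  metrics <- stage("metrics", compute_metrics(dataset, e_ref = as.numeric(e_ref)))
  undamped <- stage("undamped", undamped_force_table(metrics))
  transfer <- stage("transfer", fit_all_transfer_functions(metrics, undamped))
  table1 <- stage("stats", build_table1(metrics, as.numeric(e_ref), config))

  manifest <- list(
    package_version = as.character(utils::packageVersion("foamimpact")),
    seed = seed,
    config = unclass(config),
    params = unclass(params),
    n_traces = length(dataset$traces),
    created = format(Sys.time(), tz = "UTC")
  )
  out <- structure(
    list(config = config, params = params, seed = seed, dataset = dataset,
         metrics = metrics, e_ref = e_ref, undamped = undamped,
         transfer = transfer, table1 = table1, manifest = manifest),
    class = "impact_study"
  )
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' Write all result tables of a study to a directory
#'
#' @param study An `impact_study` from [run_full_study()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(study$dataset$traces, study$dataset$manifest,
                file.path(out_dir, "traces"))
  readr::write_csv(study$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(study$undamped, file.path(out_dir, "undamped_forces.csv"))
  readr::write_csv(purrr::map_dfr(study$transfer, glance.transfer_fn),
                   file.path(out_dir, "transfer_functions.csv"))
  readr::write_csv(
    purrr::map_dfr(study$table1, tidy.repeated_loading_result),
    file.path(out_dir, "table1.csv")
  )
  readr::write_csv(purrr::map_dfr(study$table1, glance.repeated_loading_result),
                   file.path(out_dir, "anova.csv"))
  yaml::write_yaml(study$manifest, file.path(out_dir, "run_manifest.yaml"))
  writeLines(report_summary(study), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.impact_study <- function(x, ...) {
  cat(paste(report_summary(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Human-readable summary of a study
#'
#' Renders the headline numbers: reference energy, per-layer transfer
#' slopes (one decimal) with R^2 and CI, attenuation ratios relative to the
#' single layer, optional undamped-force predictions for user-supplied
#' measured forces, and the repeated-loading table.
#'
#' @param study An `impact_study`.
#' @param predict_forces Optional named or unnamed numeric vector of
#'   measured forces in kN to convert with the single-layer transfer slope.
#' @return Character vector of report lines (invisibly printable).
#' @export
report_summary <- function(study, predict_forces = NULL) {
  if (!inherits(study, "impact_study")) {
    stop("`study` must be an impact_study.", call. = FALSE)
  }
  for (part in c("transfer", "table1", "undamped")) {
    if (is.null(study[[part]]) || length(study[[part]]) == 0) {
      stop("missing result table: ", part, call. = FALSE)
    }
  }
  lines <- c(
    "Falling-weight impact study",
    sprintf("  seed %d, %d traces, E_ref = %.0f J",
            study$seed, length(study$dataset$traces), study$e_ref),
    "Transfer functions (undamped = k * measured):"
  )
  slopes <- purrr::map_dbl(study$transfer, "slope")
  for (tf in study$transfer) {
    lines <- c(lines, sprintf(
      "  %d layer(s): k = %.1f  (R^2 = %.3f, 95%% CI [%.2f, %.2f], n = %d)",
      tf$n_layers, tf$slope, tf$r_squared, tf$ci95[1], tf$ci95[2], tf$n_points
    ))
  }
  single <- slopes[[1]]
  if (length(slopes) > 1) {
    for (i in 2:length(slopes)) {
      lines <- c(lines, sprintf(
        "  %s layers attenuate %.1f times more than a single layer",
        names(slopes)[i], attenuation_ratio(slopes[[i]], single)
      ))
    }
  }
  if (!is.null(predict_forces)) {
    lines <- c(lines, "Undamped-force predictions (single layer):")
    for (fkn in predict_forces) {
      lines <- c(lines, sprintf("  measured %.1f kN -> undamped %.1f kN",
                                fkn, round(predict_undamped(fkn, single), 1)))
    }
  }
  lines <- c(lines, sprintf("Repeated loading at E_ref = %.0f J:", study$e_ref))
  for (res in study$table1) {
    s <- res$summary
    lines <- c(lines, sprintf(
      "  %d layer(s): F(%d,%d) = %.2f, p = %.3g, eta^2 = %.3f",
      res$n_layers, res$anova$df1, res$anova$df2, res$anova$F,
      res$anova$p_value, res$anova$eta_squared
    ))
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf(
        "    rep %d: %5.0f +/- %4.0f N  %+3.0f%%%s",
        s$repetition[i], s$mean_n[i], s$sd_n[i], round(s$increase_pct[i]),
        if (is.na(s$p_value[i])) "" else sprintf("  p = %.3g", s$p_value[i])
      ))
    }
  }
  lines
}
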