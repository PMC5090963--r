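# End-to-end smoke pipeline: simulate -> endpoints -> cross-validate ->
# evaluate -> empirical-Bayes normalize -> ranked report, with every output
# written deterministically to one directory.

.run_all_defaults <- function() {
  list(n_drugs = 60, n_targets = 12, n_diseases = 6, causal_per_disease = 2,
       effect = 3, prevalence = 0.15, score_noise_sd = 0.1,
       n_decoy_diseases = 2, level = "both", min_positives = 5, k = 5,
       repeats = 2, reg_strength = 0.1, floor = 0, seed = 1)
}

#' Run the full pipeline end to end
#'
#' Generates a synthetic CPI benchmark, builds endpoints, fits and
#' cross-validates the models, evaluates the mean out-of-fold predictions
#' under the three protocols, and writes a ranked indication report for the
#' first synthetic drug.  The resolved configuration (including the seed) is
#' serialized alongside the outputs; identical configuration and seed give
#' byte-identical output files.  On failure a `FAILED` marker with the error
#' message is left in the output directory and the error is re-raised.
#'
#' @param config Named list overriding the smoke defaults (tiny sizes chosen
#'   to finish in seconds); unknown keys are an error.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
run_all <- function(config = list(), out_dir) {
  defaults <- .run_all_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  paths <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths <<- c(paths, p)
    p
  }
  tryCatch({
    cfg_ord <- cfg[order(names(cfg))]
    writeLines(jsonlite::toJSON(cfg_ord, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), emit("config.json"))
    sim <- generate_cpi_data(synthetic_config(
      n_drugs = cfg$n_drugs, n_targets = cfg$n_targets,
      n_diseases = cfg$n_diseases,
      causal_per_disease = cfg$causal_per_disease, effect = cfg$effect,
      prevalence = cfg$prevalence, score_noise_sd = cfg$score_noise_sd,
      n_decoy_diseases = cfg$n_decoy_diseases, seed = cfg$seed))
    write_cpi_matrix(sim$cpi, emit("cpi.tsv"))
    write_indication_labels(sim$labels, emit("labels.tsv"))
    paths <- c(paths, file.path(out_dir, "labels.tsv.universe"))
    fit <- cpirank(sim$cpi, sim$labels, level = cfg$level,
                   min_positives = cfg$min_positives, k = cfg$k,
                   repeats = cfg$repeats, reg_strength = cfg$reg_strength,
                   seed = cfg$seed)
    for (tier in intersect(c("disease", "family"), names(fit))) {
      t <- fit[[tier]]
      write_endpoints(t$endpoints, emit(paste0("endpoints_", tier, ".tsv")))
      m <- t$cv$metrics
      writeLines(c("metric\tmean\tsd",
                   sprintf("%s\t%.6f\t%s", m$metric, m$mean,
                           ifelse(is.na(m$sd), "NA",
                                  sprintf("%.6f", m$sd)))),
                 emit(paste0("cv_metrics_", tier, ".tsv")))
      rep_lines <- "mode\tmetric\tmean\tsd\tn_evaluated\tn_skipped"
      for (mode in c("global", "drug_centric", "disease_centric")) {
        r <- tryCatch(aggregate_metrics(t$train_scores, sim$labels, mode,
                                        threshold = t$threshold),
                      error = function(e) NULL)
        if (is.null(r)) next
        mm <- r$metrics
        rep_lines <- c(rep_lines, sprintf(
          "%s\t%s\t%.6f\t%s\t%d\t%d", mode, mm$metric, mm$mean,
          ifelse(is.na(mm$sd), "NA", sprintf("%.6f", mm$sd)),
          r$n_evaluated, r$n_skipped))
      }
      writeLines(rep_lines, emit(paste0("eval_", tier, ".tsv")))
    }
    report <- predict(fit, sim$cpi[1, ], type = "report", floor = cfg$floor)
    write_ranked_report(report, emit("report.tsv"), format = "tsv")
    write_ranked_report(report, emit("report.json"), format = "json")
    invisible(paths)
  }, error = function(e) {
    writeLines(conditionMessage(e), marker)
    stop(e)
  })
}
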