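# Two-tier indication prediction for a new drug profile and the hierarchical
# ranked report (ICD-9 families ordered by family-tier confidence, member
# diseases ordered within each family).

#' Predict two-tier indication confidences for one CPI profile
#'
#' Scores the profile with every disease-level and family-level endpoint
#' model, then normalizes each tier's raw scores with its empirical-Bayes
#' distributions.  The family confidence comes from the family-level model,
#' never from an aggregate of member diseases.
#'
#' @param models_disease Named list of `endpoint_model`s keyed by ICD-9 code.
#' @param models_family Named list of `endpoint_model`s keyed by family code.
#' @param profile Named numeric vector of docking scores covering every
#'   model target.
#' @param eb Either one [eb_distributions] object used for both tiers or a
#'   list with elements `disease` and `family`.
#' @return List with named confidence vectors `disease` and `family` and the
#'   raw score vectors `raw_disease` and `raw_family`.
#' @export
predict_indications <- function(models_disease, models_family, profile, eb) {
  score_tier <- function(models) {
    if (!length(models)) return(numeric())
    feats <- names(models[[1]]$weights)
    miss <- setdiff(feats, names(profile))
    if (length(miss))
      stop("profile is missing target(s): ", paste(miss, collapse = ", "))
    vapply(models, function(m) {
      if (!identical(names(m$weights), feats))
        stop("models trained on different target panels")
      predict_scores(m, profile[feats])
    }, numeric(1))
  }
  raw_d <- score_tier(models_disease)
  raw_f <- score_tier(models_family)
  eb_d <- if (inherits(eb, "eb_distributions")) eb else eb$disease
  eb_f <- if (inherits(eb, "eb_distributions")) eb else eb$family
  list(disease = normalize_profile(raw_d, eb_d),
       family = normalize_profile(raw_f, eb_f),
       raw_disease = raw_d, raw_family = raw_f)
}

#' Build a hierarchical ranked indication report
#'
#' Families are ordered by family-tier confidence descending (ties broken by
#' ascending code) and assigned ranks 1..n; member diseases are listed within
#' their family ordered by confidence descending (ties by ascending code).
#' Confidences are carried through unchanged — a family confidence may exceed
#' every member's and the report does not reconcile them.  Disease codes
#' whose family is absent from the family tier are kept under a flagged
#' family entry with `NA` confidence, placed after the ranked families.
#'
#' @param confidences List with named numeric vectors `disease` and `family`
#'   (e.g. from [predict_indications()]).
#' @param top_n Keep only the `top_n` best-ranked families (default all).
#' @param floor Drop families whose confidence is below `floor`
#'   (default 0, i.e. keep all); applied before `top_n`.
#' @return An object of class `ranked_report`: a data frame with columns
#'   `rank`, `family_code`, `code`, `level` (`"family"`/`"disease"`) and
#'   `confidence`, one family row followed by its member rows.
#' @export
build_ranked_report <- function(confidences, top_n = NULL, floor = 0) {
  fam_conf <- confidences$family
  dis_conf <- confidences$disease
  if (!length(fam_conf) && !length(dis_conf))
    stop("empty confidence map")
  dis_fam <- if (length(dis_conf)) parse_icd9(names(dis_conf))$family else
    character()
  extra <- setdiff(unique(dis_fam), names(fam_conf))
  fam_all <- c(fam_conf, stats::setNames(rep(NA_real_, length(extra)), extra))
  if (!is.null(floor) && floor > 0)
    fam_all <- fam_all[is.na(fam_all) | fam_all >= floor]
  # ranked families first (confidence desc, code asc), flagged ones last
  o <- order(is.na(fam_all), -ifelse(is.na(fam_all), 0, fam_all),
             names(fam_all))
  fam_all <- fam_all[o]
  if (!is.null(top_n)) fam_all <- fam_all[seq_len(min(top_n, length(fam_all)))]
  rows <- list()
  for (i in seq_along(fam_all)) {
    fc <- names(fam_all)[i]
    rows[[length(rows) + 1L]] <- data.frame(
      rank = i, family_code = fc, code = fc, level = "family",
      confidence = unname(fam_all[i]), stringsAsFactors = FALSE)
    members <- which(dis_fam == fc)
    if (length(members)) {
      mc <- dis_conf[members]
      om <- order(-mc, names(mc))
      rows[[length(rows) + 1L]] <- data.frame(
        rank = i, family_code = fc, code = names(mc)[om], level = "disease",
        confidence = unname(mc[om]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ranked_report", class(out))
  out
}

#' @export
print.ranked_report <- function(x, ...) {
  cat("ranked indication report: ", max(x$rank), " families, ",
      sum(x$level == "disease"), " member diseases\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (x$level[i] == "family") {
      cat(sprintf("%3d  %-8s %s\n", x$rank[i], x$code[i],
                  ifelse(is.na(x$confidence[i]), "(no family model)",
                         sprintf("%.2f", x$confidence[i]))))
    } else {
      cat(sprintf("     - %-8s %.2f\n", x$code[i], x$confidence[i]))
    }
  }
  invisible(x)
}

#' Write a ranked report to disk
#'
#' Deterministic, byte-identical serialization for identical reports: fixed
#' column order, 6-decimal confidences, ordered JSON keys.
#'
#' @param report A `ranked_report`.
#' @param path Output file.
#' @param format `"tsv"` (default) or `"json"`.
#' @export
write_ranked_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  if (format == "tsv") {
    header <- "rank\tfamily_code\tcode\tlevel\tconfidence"
    rows <- if (nrow(report)) paste(report$rank, report$family_code,
                                    report$code, report$level,
                                    fmt(report$confidence), sep = "\t")
            else character()
    writeLines(c(header, rows), path)
  } else {
    fams <- lapply(unique(report$family_code[report$level == "family"]),
                   function(fc) {
      fr <- report[report$family_code == fc & report$level == "family", ]
      mr <- report[report$family_code == fc & report$level == "disease", ]
      list(rank = fr$rank[1], family_code = fc,
           confidence = fmt(fr$confidence[1]),
           members = if (nrow(mr)) lapply(seq_len(nrow(mr)), function(i)
             list(code = mr$code[i], confidence = fmt(mr$confidence[i])))
           else list())
    })
    writeLines(jsonlite::toJSON(fams, auto_unbox = TRUE, pretty = TRUE),
               path)
  }
  invisible(path)
}
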