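# ICD-9 code handling and endpoint construction.
#
# An "endpoint" is one binary classification task: does a drug treat this
# ICD-9 code (disease level) or any code in this 3-digit rubric (family
# level).  Endpoints are filtered by the standard rules: drop families in the
# symptoms/injury/poisoning range 780-999 and drop endpoints with fewer than
# `min_positives` treating drugs.

.icd9_regex <- "^[VE]?[0-9]{1,3}(\\.[0-9]{1,2})?$"

#' Parse ICD-9 codes
#'
#' Validates code syntax and derives the disease family: the portion before
#' the decimal point (the 3-digit rubric, e.g. `250.10 -> 250`).  V- and
#' E-codes carry no numeric family.
#'
#' @param code Character vector of ICD-9 code strings.
#' @return Data frame with columns `raw`, `family` and `numeric_family`
#'   (integer, `NA` for V/E codes).
#' @export
parse_icd9 <- function(code) {
  code <- as.character(code)
  if (!length(code) || any(!nzchar(code)) || anyNA(code))
    stop("empty ICD-9 code string")
  ok <- grepl(.icd9_regex, code)
  if (any(!ok))
    stop("malformed ICD-9 code(s): ",
         paste(unique(code[!ok]), collapse = ", "))
  family <- sub("\\..*$", "", code)
  numeric_family <- suppressWarnings(as.integer(family))
  data.frame(raw = code, family = family, numeric_family = numeric_family,
             stringsAsFactors = FALSE)
}

#' Build filtered endpoint sets from indication labels
#'
#' At `level = "disease"` each ICD-9 code is an endpoint; at
#' `level = "family"` codes are rolled up to their 3-digit rubric and a drug
#' is positive for a family iff it is positive for at least one member code.
#' After rollup (at the respective level) two filters apply: endpoints whose
#' integer family lies in `excluded_range` (inclusive on both ends) are
#' removed, and endpoints with fewer than `min_positives` positive drugs are
#' removed.  V- and E-codes are excluded by default since the range rule
#' presumes numeric families.
#'
#' @param labels An [indication_labels] object.
#' @param level `"disease"` or `"family"`.
#' @param min_positives Minimum number of treating drugs per endpoint.
#' @param excluded_range Integer interval of excluded families (inclusive).
#' @param keep_ve Keep V- and E-coded endpoints (default drop).
#' @return An object of class `endpoint_set`: list with `level`, `endpoints`
#'   (named list, code -> character vector of positive drug ids, sorted by
#'   code), `min_positives`, `excluded_range`.
#' @export
build_endpoints <- function(labels, level = c("disease", "family"),
                            min_positives = 5, excluded_range = c(780, 999),
                            keep_ve = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(labels, "indication_labels"))
  if (length(excluded_range) != 2 || excluded_range[1] > excluded_range[2])
    stop("excluded_range must be an interval c(lo, hi)")
  p <- labels$positives
  if (!nrow(p)) stop("no positive pairs in labels")
  parsed <- parse_icd9(p$icd9_code)
  key <- if (level == "disease") parsed$raw else parsed$family
  fam <- parsed$numeric_family
  keep <- is.na(fam) | fam < excluded_range[1] | fam > excluded_range[2]
  if (!keep_ve) keep <- keep & !is.na(fam)
  p <- p[keep, , drop = FALSE]
  key <- key[keep]
  pos <- lapply(split(p$drug_id, key), function(d) sort(unique(d)))
  pos <- pos[lengths(pos) >= min_positives]
  if (!length(pos))
    stop("no endpoints survive the filters; consider relaxing ",
         "min_positives or excluded_range")
  pos <- pos[order(names(pos))]
  structure(list(level = level, endpoints = pos,
                 min_positives = min_positives,
                 excluded_range = as.integer(excluded_range)),
            class = "endpoint_set")
}

#' @export
print.endpoint_set <- function(x, ...) {
  cat("endpoint set (", x$level, " level): ", length(x$endpoints),
      " endpoints, ", x$min_positives, "+ positives each, families ",
      x$excluded_range[1], "-", x$excluded_range[2], " excluded\n", sep = "")
  invisible(x)
}

#' Write an endpoint set to a TSV file
#'
#' One row per endpoint: `code<TAB>n_positives<TAB>drug1,drug2,...`.
#'
#' @param endpoints An `endpoint_set`.
#' @param path Output file.
#' @export
write_endpoints <- function(endpoints, path) {
  rows <- vapply(names(endpoints$endpoints), function(code) {
    d <- endpoints$endpoints[[code]]
    paste(code, length(d), paste(d, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("code\tn_positives\tdrugs", rows), path)
  invisible(path)
}
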