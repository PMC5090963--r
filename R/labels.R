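#' Construct a drug-indication label set
#'
#' Sparse positive labels: a (drug, ICD-9 code) pair present means the drug
#' is reported to treat the indication (label 1); an absent pair over the
#' drug universe means label 0.
#'
#' @param pairs Data frame (or coercible) with columns `drug_id` and
#'   `icd9_code`; duplicated pairs are stored once.
#' @param universe Optional character vector of drug ids; the stored universe
#'   is the union of `universe` and all drug ids appearing in `pairs`.
#' @return An object of class `indication_labels`: a list with elements
#'   `universe` (character) and `positives` (data frame `drug_id`,
#'   `icd9_code`).
#' @export
indication_labels <- function(pairs, universe = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) && ncol(pairs) < 2)
    stop("pairs must have columns drug_id and icd9_code")
  if (nrow(pairs)) {
    pairs <- data.frame(drug_id = as.character(pairs[[1]]),
                        icd9_code = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
    parse_icd9(unique(pairs$icd9_code))  # validates; errors name the string
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs$drug_id, pairs$icd9_code), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(drug_id = character(), icd9_code = character(),
                        stringsAsFactors = FALSE)
  }
  universe <- sort(unique(c(as.character(universe), pairs$drug_id)))
  structure(list(universe = universe, positives = pairs),
            class = "indication_labels")
}

#' @export
print.indication_labels <- function(x, ...) {
  cat("indication labels: ", nrow(x$positives), " positive pairs, ",
      length(unique(x$positives$icd9_code)), " codes, universe of ",
      length(x$universe), " drugs\n", sep = "")
  invisible(x)
}

#' Read drug-indication labels from a TSV file
#'
#' Expects columns `drug_id<TAB>icd9_code[<TAB>label]` without a header.
#' Rows with label 0 are ignored with a warning; any malformed ICD-9 code is
#' an error reporting the offending line number.
#'
#' @param path Label file.
#' @param universe_path Optional file listing one drug id per line; the
#'   universe becomes the union of this list and the drugs seen in `path`.
#' @return An [indication_labels] object.
#' @export
read_indication_labels <- function(path, universe_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (length(n) && any(n < 2))
    stop("line ", which(n < 2)[1], ": expected at least 2 tab-separated fields")
  drug <- vapply(fields, `[[`, character(1), 1)
  code <- vapply(fields, `[[`, character(1), 2)
  ok <- grepl(.icd9_regex, code)
  if (any(!ok))
    stop("line ", which(!ok)[1], ": malformed ICD-9 code '",
         code[which(!ok)[1]], "'")
  if (length(n) && any(n >= 3)) {
    lab <- rep("1", length(fields))
    lab[n >= 3] <- vapply(fields[n >= 3], `[[`, character(1), 3)
    if (!all(lab %in% c("0", "1")))
      stop("line ", which(!lab %in% c("0", "1"))[1],
           ": label must be 0 or 1")
    if (any(lab == "0")) {
      warning(sum(lab == "0"), " row(s) with label 0 ignored")
      drug <- drug[lab == "1"]
      code <- code[lab == "1"]
    }
  }
  universe <- NULL
  if (!is.null(universe_path)) {
    if (!file.exists(universe_path))
      stop("file not found: ", universe_path)
    universe <- readLines(universe_path)
    universe <- universe[nzchar(universe)]
  }
  indication_labels(data.frame(drug_id = drug, icd9_code = code,
                               stringsAsFactors = FALSE), universe)
}

#' Write drug-indication labels to a TSV file
#'
#' Positive pairs are written as `drug_id<TAB>icd9_code`; drugs in the
#' universe without any positive are appended to a companion
#' `<path>.universe` file so that a write/read round trip reproduces the
#' object exactly.
#'
#' @param labels An [indication_labels] object.
#' @param path Output file for the pairs.
#' @param universe_path Output file for the full universe (default
#'   `paste0(path, ".universe")`).
#' @export
write_indication_labels <- function(labels, path,
                                    universe_path = paste0(path, ".universe")) {
  p <- labels$positives
  writeLines(paste(p$drug_id, p$icd9_code, sep = "\t"), path)
  writeLines(labels$universe, universe_path)
  invisible(path)
}
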