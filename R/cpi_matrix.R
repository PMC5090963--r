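#' Construct a CPI matrix
#'
#' A chemical-protein interactome (CPI) matrix holds docking scores
#' (kcal/mol, more negative = stronger predicted binding) for a panel of
#' drugs (rows) against a panel of protein targets (columns).
#'
#' @param scores Numeric matrix of docking scores.
#' @param drug_ids Character vector of unique drug identifiers (rows).
#' @param target_ids Character vector of unique target identifiers (columns).
#' @return An object of class `cpi_matrix`: a numeric matrix with dimnames.
#' @export
cpi_matrix <- function(scores, drug_ids = rownames(scores),
                       target_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (length(drug_ids) != nrow(scores))
    stop("length of drug_ids (", length(drug_ids),
         ") does not match number of rows (", nrow(scores), ")")
  if (length(target_ids) != ncol(scores))
    stop("length of target_ids (", length(target_ids),
         ") does not match number of columns (", ncol(scores), ")")
  dup <- unique(drug_ids[duplicated(drug_ids)])
  if (length(dup))
    stop("duplicate drug id(s): ", paste(dup, collapse = ", "))
  dup <- unique(target_ids[duplicated(target_ids)])
  if (length(dup))
    stop("duplicate target id(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(scores))) {
    bad <- which(!is.finite(scores), arr.ind = TRUE)[1, ]
    stop("non-finite score at row ", bad[1], ", column ", bad[2])
  }
  dimnames(scores) <- list(drug_ids, target_ids)
  class(scores) <- c("cpi_matrix", class(scores))
  scores
}

#' @export
print.cpi_matrix <- function(x, ...) {
  cat("CPI matrix: ", nrow(x), " drugs x ", ncol(x),
      " targets (docking scores, kcal/mol)\n", sep = "")
  cat("score range: [", sprintf("%.3f", min(x)), ", ",
      sprintf("%.3f", max(x)), "]\n", sep = "")
  invisible(x)
}

#' Read a CPI matrix from a delimited text file
#'
#' Expects a header row of target ids and a first column of drug ids; the
#' body holds docking scores.  Malformed input is rejected, never coerced:
#' duplicate ids and non-numeric cells are hard errors.  Missing cells
#' (`NA` or empty) are a hard error unless `impute = "target_mean"`, in
#' which case each missing cell is replaced by the column mean of the
#' remaining entries.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param impute Missing-cell policy: `"error"` (default) or `"target_mean"`.
#' @return A [cpi_matrix].
#' @export
read_cpi_matrix <- function(path, dialect = c("tsv", "csv"),
                            impute = c("error", "target_mean")) {
  dialect <- match.arg(dialect)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "", comment.char = "",
                           na.strings = NULL)
  if (ncol(raw) < 2) stop("expected a drug-id column plus >=1 target column")
  drug_ids <- raw[[1]]
  target_ids <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  missing <- body %in% c("NA", "", "NaN") | is.na(body)
  dim(missing) <- dim(body)
  bad <- is.na(num) & !missing
  if (any(bad)) {
    co <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", body[co[1], co[2]], "' at data row ", co[1],
         ", column ", co[2] + 1L, " of ", path)
  }
  if (any(missing)) {
    if (impute == "error") {
      co <- which(missing, arr.ind = TRUE)[1, ]
      stop("missing score at data row ", co[1], ", column ", co[2] + 1L,
           " (use impute = \"target_mean\" to impute column means)")
    }
    for (j in seq_len(ncol(num))) {
      mj <- missing[, j]
      if (any(mj)) {
        if (all(mj)) stop("column ", target_ids[j], " is entirely missing")
        num[mj, j] <- mean(num[!mj, j])
      }
    }
  }
  out <- cpi_matrix(num, drug_ids, target_ids)
  message("read CPI matrix: ", nrow(out), " drugs, ", ncol(out), " targets")
  out
}

#' Write a CPI matrix to a delimited text file
#'
#' Scores are serialized with 6 decimal places so identical objects produce
#' byte-identical files.
#'
#' @param x A [cpi_matrix].
#' @param path Output file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_cpi_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  header <- paste(c("drug_id", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.6f", x[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
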