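#' Construct a fingerprint set
#'
#' Binary molecular fingerprints stored sparsely: per drug the set of on-bit
#' indices (0-based) in `[0, bit_length)`.  All drugs in a set share the same
#' bit length.
#'
#' @param bits Named list of integer vectors of on-bit indices (0-based).
#' @param bit_length Positive integer, the common fingerprint length.
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(bits, bit_length) {
  bit_length <- as.integer(bit_length)
  if (length(bit_length) != 1L || is.na(bit_length) || bit_length <= 0L)
    stop("bit_length must be a positive integer")
  if (is.null(names(bits)) || any(!nzchar(names(bits))))
    stop("bits must be a named list keyed by drug id")
  if (anyDuplicated(names(bits)))
    stop("duplicate drug id(s): ",
         paste(unique(names(bits)[duplicated(names(bits))]), collapse = ", "))
  bits <- lapply(bits, function(b) {
    b <- as.integer(b)
    if (anyDuplicated(b)) stop("duplicate bit indices in a fingerprint")
    if (length(b) && (min(b) < 0L || max(b) >= bit_length))
      stop("bit index out of range [0, ", bit_length, ")")
    sort(b)
  })
  structure(list(bits = bits, bit_length = bit_length),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("fingerprint set: ", length(x$bits), " drugs, ", x$bit_length,
      " bits\n", sep = "")
  invisible(x)
}

#' Read binary fingerprints from a TSV file
#'
#' Two formats are supported: `bitstring` lines `drug_id<TAB>0101...` and
#' `indices` lines `drug_id<TAB>length<TAB>i1,i2,...` (0-based on-bit
#' indices; the third field may be empty for an all-zero fingerprint).
#' Inconsistent bit lengths across lines are an error.
#'
#' @param path Fingerprint file.
#' @param format `"bitstring"` (default) or `"indices"`.
#' @return A [fingerprint_set].
#' @export
read_fingerprints <- function(path, format = c("bitstring", "indices")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty fingerprint file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1)
  if (format == "bitstring") {
    bs <- vapply(fields, function(f) {
      if (length(f) < 2) stop("expected drug_id<TAB>bitstring")
      f[[2]]
    }, character(1))
    if (any(grepl("[^01]", bs)))
      stop("line ", which(grepl("[^01]", bs))[1],
           ": bitstring may contain only 0 and 1")
    lens <- nchar(bs)
    if (length(unique(lens)) != 1L)
      stop("inconsistent bit lengths across lines: ",
           paste(unique(lens), collapse = ", "))
    bits <- lapply(bs, function(s)
      which(strsplit(s, "", fixed = TRUE)[[1]] == "1") - 1L)
    names(bits) <- ids
    fingerprint_set(bits, unique(lens))
  } else {
    lens <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
    if (any(is.na(lens)))
      stop("line ", which(is.na(lens))[1], ": bad declared length")
    if (length(unique(lens)) != 1L)
      stop("inconsistent bit lengths across lines: ",
           paste(unique(lens), collapse = ", "))
    bits <- lapply(fields, function(f) {
      if (length(f) < 3 || !nzchar(f[[3]])) return(integer())
      as.integer(strsplit(f[[3]], ",", fixed = TRUE)[[1]])
    })
    names(bits) <- ids
    fingerprint_set(bits, unique(lens))
  }
}
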