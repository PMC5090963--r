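# Tanimoto similarity on binary fingerprints and the train/validation
# leakage filter.

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|` on the on-bit index sets.  Two all-zero
#' fingerprints yield 0 with a warning (0/0 is undefined; 0 is the
#' conservative "not similar" convention).
#'
#' @param a,b Integer vectors of on-bit indices, or a [fingerprint_set] entry.
#' @param bit_length Optional common length check; if both vectors carry a
#'   `bit_length` attribute the lengths must agree.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, bit_length = NULL) {
  la <- attr(a, "bit_length")
  lb <- attr(b, "bit_length")
  if (!is.null(la) && !is.null(lb) && la != lb)
    stop("fingerprint bit lengths differ: ", la, " vs ", lb)
  if (!is.null(bit_length)) {
    if (length(a) && max(a) >= bit_length) stop("bit index out of range")
    if (length(b) && max(b) >= bit_length) stop("bit index out of range")
  }
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  if (!length(a) && !length(b)) {
    warning("both fingerprints are empty; returning 0")
    return(0)
  }
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Remove validation drugs structurally similar to training drugs
#'
#' A validation drug is removed iff its maximum Tanimoto similarity towards
#' any training drug is strictly greater than `cutoff` (a maximum of exactly
#' `cutoff` is retained).  With an empty training set every validation drug
#' is retained.
#'
#' @param validation_ids Character vector of validation drug ids.
#' @param training_ids Character vector of training drug ids.
#' @param fps A [fingerprint_set] covering all listed drugs.
#' @param cutoff Strict similarity cutoff (default 0.7).
#' @return List with `retained` (sorted character vector) and `removed`
#'   (data frame `drug_id`, `max_similarity`, `nearest_training_drug`,
#'   sorted by drug id).
#' @export
filter_leakage <- function(validation_ids, training_ids, fps, cutoff = 0.7) {
  stopifnot(inherits(fps, "fingerprint_set"))
  validation_ids <- sort(unique(as.character(validation_ids)))
  training_ids <- sort(unique(as.character(training_ids)))
  missing <- setdiff(c(validation_ids, training_ids), names(fps$bits))
  if (length(missing))
    stop("missing fingerprint(s) for: ", paste(missing, collapse = ", "))
  removed <- data.frame(drug_id = character(), max_similarity = numeric(),
                        nearest_training_drug = character(),
                        stringsAsFactors = FALSE)
  retained <- character()
  for (v in validation_ids) {
    if (!length(training_ids)) {
      retained <- c(retained, v)
      next
    }
    sims <- vapply(training_ids, function(t)
      suppressWarnings(tanimoto(fps$bits[[v]], fps$bits[[t]])), numeric(1))
    mx <- max(sims)
    if (mx > cutoff) {
      removed <- rbind(removed, data.frame(
        drug_id = v, max_similarity = mx,
        nearest_training_drug = training_ids[which.max(sims)],
        stringsAsFactors = FALSE))
    } else {
      retained <- c(retained, v)
    }
  }
  rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}
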