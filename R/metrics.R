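# Confusion metrics, AUROC, AUPR and the three aggregation protocols
# (global / drug-centric / disease-centric).

.confusion_from_counts <- function(tp, fp, fn, tn) {
  undefined <- character()
  precision <- if (tp + fp == 0) {
    undefined <- c(undefined, "precision")
    NA_real_
  } else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0) {
    undefined <- c(undefined, "sensitivity")
    NA_real_
  } else tp / (tp + fn)
  specificity <- if (tn + fp == 0) {
    undefined <- c(undefined, "specificity")
    NA_real_
  } else tn / (tn + fp)
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = precision, sensitivity = sensitivity,
       specificity = specificity, undefined = undefined)
}

#' Confusion metrics at a decision threshold
#'
#' A sample is predicted positive iff its score is `>=` the threshold
#' (inclusive, matching the smallest-threshold-at-max-F convention of
#' [select_threshold()]).  Metrics undefined on the input (no positives, no
#' predicted positives, no negatives) are returned as `NA` and named in the
#' `undefined` element rather than silently set to 0.
#'
#' @param scores Numeric score vector.
#' @param y Binary 0/1 labels.
#' @param threshold Decision threshold.
#' @return List with `accuracy`, `precision`, `sensitivity`, `specificity`
#'   and `undefined` (character vector of flagged metrics).
#' @export
confusion_metrics <- function(scores, y, threshold) {
  y <- as.numeric(y)
  if (length(scores) != length(y)) stop("lengths differ")
  pred <- scores >= threshold
  .confusion_from_counts(sum(pred & y == 1), sum(pred & y == 0),
                         sum(!pred & y == 1), sum(!pred & y == 0))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via midranks, which equals the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric score vector.
#' @param y Binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y) {
  y <- as.numeric(y)
  if (length(scores) != length(y)) stop("lengths differ")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC requires at least one positive and one negative")
  (sum(rank(scores)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: stepping down the distinct score values,
#' `AP = sum over steps of (recall_i - recall_(i-1)) * precision_i`.  No
#' linear interpolation of precision is applied (trapezoidal PR interpolation
#' is biased optimistic).  Tied scores are handled as one step.
#'
#' @param scores Numeric score vector.
#' @param y Binary 0/1 labels; at least one positive required.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, y) {
  y <- as.numeric(y)
  if (length(scores) != length(y)) stop("lengths differ")
  npos <- sum(y == 1)
  if (npos == 0) stop("AUPR requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yo <- y[o]
  # indices where the score strictly drops: one PR point per distinct value
  cut <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(yo)[cut]
  pp <- cut                      # predicted positives at each cut
  prec <- tp / pp
  rec <- tp / npos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Aggregate predictions under an evaluation protocol
#'
#' Three protocols: `global` pools every (drug, endpoint) cell into one
#' vector; `drug_centric` computes metrics per drug and averages over drugs;
#' `disease_centric` computes metrics per endpoint and averages over
#' endpoints.  Entities whose metrics are undefined (single-class labels)
#' are skipped and counted.  Entity averages are reported as mean and
#' population standard deviation (divisor n).
#'
#' @param preds Numeric matrix of scores, drugs in rows (row names = drug
#'   ids), endpoints in columns (column names = codes); e.g. one element of
#'   the `predictions` list of a [cross_validate()] result.
#' @param labels An [indication_labels] object.
#' @param mode `"global"`, `"drug_centric"` or `"disease_centric"`.
#' @param threshold Decision threshold for the confusion metrics; default is
#'   the max-F threshold of the pooled scores.
#' @return An object of class `metric_report`: list with `mode`, `metrics`
#'   (data frame metric/mean/sd), `n_evaluated`, `n_skipped`, `threshold`.
#' @export
aggregate_metrics <- function(preds, labels,
                              mode = c("global", "drug_centric",
                                       "disease_centric"),
                              threshold = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(preds), inherits(labels, "indication_labels"))
  if (is.null(rownames(preds)) || is.null(colnames(preds)))
    stop("preds must carry drug ids as rownames and codes as colnames")
  pos <- labels$positives
  level_family <- all(!grepl("\\.", colnames(preds)))
  code_of <- if (level_family) parse_icd9(pos$icd9_code)$family else
    pos$icd9_code
  Y <- matrix(0, nrow(preds), ncol(preds), dimnames = dimnames(preds))
  hit <- code_of %in% colnames(preds) & pos$drug_id %in% rownames(preds)
  Y[cbind(pos$drug_id[hit], code_of[hit])] <- 1

  if (is.null(threshold)) threshold <- select_threshold(as.vector(preds),
                                                        as.vector(Y))
  one <- function(s, y) {
    cm <- confusion_metrics(s, y, threshold)
    c(auroc = auroc(s, y), aupr = aupr(s, y), accuracy = cm$accuracy,
      precision = cm$precision, sensitivity = cm$sensitivity,
      specificity = cm$specificity)
  }
  mets <- c("auroc", "aupr", "accuracy", "precision", "sensitivity",
            "specificity")
  if (mode == "global") {
    v <- one(as.vector(preds), as.vector(Y))
    metrics <- data.frame(metric = mets, mean = unname(v[mets]),
                          sd = NA_real_)
    n_eval <- 1L
    n_skip <- 0L
  } else {
    entities <- if (mode == "drug_centric") seq_len(nrow(preds)) else
      seq_len(ncol(preds))
    vals <- lapply(entities, function(i) {
      s <- if (mode == "drug_centric") preds[i, ] else preds[, i]
      y <- if (mode == "drug_centric") Y[i, ] else Y[, i]
      if (sum(y) == 0 || sum(y) == length(y)) return(NULL)
      one(s, y)
    })
    keep <- !vapply(vals, is.null, logical(1))
    n_eval <- sum(keep)
    n_skip <- sum(!keep)
    if (n_eval == 0)
      stop("no evaluable entities in ", mode, " mode (", n_skip,
           " skipped: single-class labels)")
    V <- do.call(rbind, vals[keep])
    pop_sd <- function(x) {
      x <- x[!is.na(x)]
      sqrt(mean((x - mean(x))^2))
    }
    metrics <- data.frame(
      metric = mets,
      mean = vapply(mets, function(m) mean(V[, m], na.rm = TRUE), numeric(1)),
      sd = vapply(mets, function(m) pop_sd(V[, m]), numeric(1)),
      row.names = NULL)
  }
  structure(list(mode = mode, metrics = metrics, n_evaluated = n_eval,
                 n_skipped = n_skip, threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("metric report (", x$mode, "): ", x$n_evaluated, " evaluated, ",
      x$n_skipped, " skipped; threshold ", sprintf("%.4f", x$threshold),
      "\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.*f", m$metric[i], digits, m$mean[i]))
    if (!is.na(m$sd[i])) cat(sprintf(" +/- %.*f", digits, m$sd[i]))
    cat("\n")
  }
  invisible(x)
}
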