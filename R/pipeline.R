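# The main model-fitting entry point: per-endpoint classifiers at one or two
# ICD-9 tiers, cross-validated, with empirical-Bayes normalization fitted on
# out-of-fold scores, returned as one S3 object with the usual methods.

#' Fit a CPI indication-prediction model
#'
#' For each requested ICD-9 tier (individual disease codes and/or 3-digit
#' families) this builds the filtered endpoint set, runs repeated k-fold
#' cross-validation, fits one final L2-logistic model per endpoint on all
#' drugs, selects the max-F decision threshold on the pooled out-of-fold
#' scores, and fits empirical-Bayes normalization distributions on the mean
#' out-of-fold scores (pooled over drugs by default).
#'
#' @param cpi A [cpi_matrix] (drugs x targets docking scores).
#' @param labels An [indication_labels] object.
#' @param level `"disease"`, `"family"` or `"both"` (default).
#' @param min_positives,excluded_range,keep_ve Endpoint filters, see
#'   [build_endpoints()].
#' @param k,repeats Cross-validation design, see [cross_validate()].
#' @param reg_strength Inverse ridge penalty (default 0.1).
#' @param seed Integer seed; the family tier uses `seed + 5000L`.
#' @param eb_mode `"pooled"` (default) or `"per_drug"` is the mode later used
#'   by [predict.cpirank()]; pooled distributions are always fitted.
#' @param threshold_policy Passed to [cross_validate()].
#' @return An object of class `cpirank`: list with one entry per tier
#'   (`endpoints`, `cv`, `models`, `eb`, `threshold`, `train_scores`) plus
#'   `call`, `target_ids`, `seed`, `reg_strength`.
#' @seealso [predict.cpirank()], [coef.cpirank()], [plot.cpirank()]
#' @export
cpirank <- function(cpi, labels, level = c("both", "disease", "family"),
                    min_positives = 5, excluded_range = c(780, 999),
                    keep_ve = FALSE, k = 10, repeats = 10,
                    reg_strength = 0.1, seed = 1,
                    eb_mode = c("pooled", "per_drug"),
                    threshold_policy = c("global", "per_endpoint")) {
  level <- match.arg(level)
  eb_mode <- match.arg(eb_mode)
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(inherits(cpi, "cpi_matrix"), inherits(labels, "indication_labels"))
  tiers <- if (level == "both") c("disease", "family") else level
  fit_tier <- function(tier, tier_seed) {
    eps <- build_endpoints(labels, level = tier,
                           min_positives = min_positives,
                           excluded_range = excluded_range, keep_ve = keep_ve)
    cv <- cross_validate(cpi, labels, eps, k = k, repeats = repeats,
                         reg_strength = reg_strength, seed = tier_seed,
                         threshold_policy = threshold_policy)
    drugs <- rownames(cpi)
    models <- lapply(names(eps$endpoints), function(code) {
      y <- as.numeric(drugs %in% eps$endpoints[[code]])
      fit_endpoint_model(cpi, y, reg_strength, code)
    })
    names(models) <- names(eps$endpoints)
    train_scores <- Reduce(`+`, cv$predictions) / length(cv$predictions)
    eb <- fit_eb_training(train_scores, eps, mode = "pooled")
    Y <- vapply(colnames(train_scores), function(code)
      as.numeric(drugs %in% eps$endpoints[[code]]),
      numeric(length(drugs)))
    thr <- select_threshold(as.vector(train_scores), as.vector(Y))
    models <- lapply(models, function(m) {
      m$threshold <- thr
      m
    })
    list(endpoints = eps, cv = cv, models = models, eb = eb,
         threshold = thr, train_scores = train_scores)
  }
  out <- list(call = match.call(), target_ids = colnames(cpi),
              n_drugs = nrow(cpi), seed = as.integer(seed),
              reg_strength = reg_strength, eb_mode = eb_mode, level = level)
  for (tier in tiers)
    out[[tier]] <- fit_tier(tier, if (tier == "family") seed + 5000L else seed)
  class(out) <- "cpirank"
  out
}

#' @export
print.cpirank <- function(x, ...) {
  cat("CPI indication-prediction model (", x$n_drugs, " drugs, ",
      length(x$target_ids), " targets)\n", sep = "")
  for (tier in intersect(c("disease", "family"), names(x))) {
    t <- x[[tier]]
    a <- t$cv$metrics[t$cv$metrics$metric == "auroc", ]
    cat(sprintf("  %s tier: %d endpoints, CV global AUROC %.3f%s\n", tier,
                length(t$models), a$mean,
                if (!is.na(a$sd)) sprintf(" +/- %.3f", a$sd) else ""))
  }
  invisible(x)
}

#' @export
summary.cpirank <- function(object, ...) {
  structure(list(fit = object), class = "summary.cpirank")
}

#' @export
print.summary.cpirank <- function(x, ...) {
  print(x$fit)
  for (tier in intersect(c("disease", "family"), names(x$fit))) {
    t <- x$fit[[tier]]
    cat("\n--", tier, "tier cross-validation (k =", t$cv$k, ", repeats =",
        t$cv$repeats, ") --\n")
    print(t$cv)
    cat("  max-F threshold:", sprintf("%.4f", t$threshold), "\n")
    cat("  EB prior P(G1):", sprintf("%.4f", t$eb$prior_g1), "\n")
  }
  invisible(x)
}

#' Extract per-endpoint model coefficients
#'
#' @param object A `cpirank` fit.
#' @param tier `"disease"` or `"family"`.
#' @param ... Unused.
#' @return Numeric matrix, endpoints in rows, targets in columns (weights on
#'   the standardized feature scale); attribute `"intercept"` carries the
#'   per-endpoint intercepts.
#' @export
coef.cpirank <- function(object, tier = c("disease", "family"), ...) {
  tier <- match.arg(tier)
  if (is.null(object[[tier]])) stop("tier '", tier, "' was not fitted")
  models <- object[[tier]]$models
  W <- t(vapply(models, function(m) m$weights,
                numeric(length(object$target_ids))))
  dimnames(W) <- list(names(models), object$target_ids)
  attr(W, "intercept") <- vapply(models, function(m) m$intercept, numeric(1))
  W
}

#' Predict indications for new drug profiles
#'
#' @param object A `cpirank` fit.
#' @param newdata Named numeric vector (one profile) or matrix with target
#'   columns; names must cover the fit's target panel.
#' @param type `"report"` (default; hierarchical [build_ranked_report()],
#'   single profile only), `"confidence"` (EB-normalized confidences) or
#'   `"response"` (raw model probabilities).
#' @param top_n,floor Report controls, see [build_ranked_report()].
#' @param ... Unused.
#' @return A `ranked_report`, or a list of per-tier named vectors.
#' @export
predict.cpirank <- function(object, newdata, type = c("report", "confidence",
                                                      "response"),
                            top_n = NULL, floor = 0, ...) {
  type <- match.arg(type)
  if (is.matrix(newdata) && nrow(newdata) > 1 && type == "report")
    stop("type = 'report' expects a single profile")
  profile <- if (is.matrix(newdata)) newdata[1, ] else newdata
  md <- if (!is.null(object$disease)) object$disease$models else list()
  mf <- if (!is.null(object$family)) object$family$models else list()
  eb <- list(
    disease = if (!is.null(object$disease)) object$disease$eb,
    family = if (!is.null(object$family)) object$family$eb)
  if (is.null(eb$disease)) eb$disease <- eb$family
  if (is.null(eb$family)) eb$family <- eb$disease
  conf <- predict_indications(md, mf, profile, eb)
  switch(type,
         report = build_ranked_report(conf, top_n = top_n, floor = floor),
         confidence = conf[c("disease", "family")],
         response = conf[c("raw_disease", "raw_family")])
}

#' Plot the pooled cross-validated ROC curve
#'
#' @param x A `cpirank` fit.
#' @param tier `"disease"` or `"family"`.
#' @param ... Passed to [plot()].
#' @export
plot.cpirank <- function(x, tier = c("disease", "family"), ...) {
  tier <- match.arg(tier)
  if (is.null(x[[tier]])) stop("tier '", tier, "' was not fitted")
  t <- x[[tier]]
  drugs <- rownames(t$train_scores)
  Y <- vapply(colnames(t$train_scores), function(code)
    as.numeric(drugs %in% t$endpoints$endpoints[[code]]),
    numeric(length(drugs)))
  s <- as.vector(t$train_scores)
  y <- as.vector(Y)
  o <- order(s, decreasing = TRUE)
  tpr <- c(0, cumsum(y[o]) / sum(y))
  fpr <- c(0, cumsum(1 - y[o]) / sum(1 - y))
  plot(fpr, tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Pooled CV ROC (%s tier), AUROC %.3f", tier,
                      auroc(s, y)), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
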