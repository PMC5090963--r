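# Per-endpoint L2-regularized logistic classifiers on CPI features.
#
# Features are z-scored per target on each training split (docking scores
# share units but differ in location per target; the penalty needs
# comparable scales).  The penalized fit is delegated to glmnet with
# alpha = 0 and lambda = 1 / (n * reg_strength), so `reg_strength` is the
# usual inverse penalty C of a per-sample objective.

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1  # zero-variance sentinel
  list(mean = mu, sd = sdv)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}

#' Fit one endpoint classifier
#'
#' L2-regularized (ridge) logistic regression of a binary endpoint on CPI
#' features.  Standardization parameters are fitted on the supplied rows and
#' stored in the model so that prediction applies the identical transform.
#' The coordinate-descent solver runs to a tight convergence threshold
#' (1e-14) so that symmetric problems yield symmetric weights; the fit is
#' deterministic given identical input.
#'
#' @param X Numeric matrix of CPI feature rows (drugs x targets).
#' @param y Binary 0/1 vector aligned with the rows of `X`.
#' @param reg_strength Positive inverse regularization strength C; the ridge
#'   penalty per sample is `1/(2*C*n) * ||w||^2`.  Default 0.1, chosen for
#'   endpoints with few positives relative to the feature count.
#' @param endpoint_code Optional endpoint label stored in the model.
#' @return An object of class `endpoint_model`: list with `weights` (aligned
#'   to targets), `intercept`, `feature_means`, `feature_sds`,
#'   `reg_strength`, `threshold` (NA until selected), `endpoint_code`.
#' @export
fit_endpoint_model <- function(X, y, reg_strength = 0.1,
                               endpoint_code = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (any(!is.finite(X))) stop("non-finite feature value in X")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("y has a single class; cannot fit a classifier")
  if (!is.numeric(reg_strength) || reg_strength <= 0)
    stop("reg_strength must be positive")
  st <- .standardize_fit(X)
  Xz <- .standardize_apply(X, st)
  lambda <- 1 / (nrow(X) * reg_strength)
  fit <- withCallingHandlers(
    glmnet::glmnet(Xz, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE,
                   thresh = 1e-14, maxit = 100000L),
    warning = function(w) {
      # lognet emits an advisory when a class has < 8 observations; rare
      # endpoints are expected here and handled by the caller's fallback
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  structure(list(endpoint_code = endpoint_code,
                 weights = beta,
                 intercept = as.numeric(fit$a0),
                 feature_means = st$mean,
                 feature_sds = st$sd,
                 reg_strength = reg_strength,
                 threshold = NA_real_,
                 constant = NA_real_),
            class = "endpoint_model")
}

# Degenerate fallback used by cross_validate when a training split has fewer
# than two positives (or negatives): predict the training prevalence.
.constant_model <- function(prevalence, n_targets, target_ids = NULL,
                            endpoint_code = NA_character_) {
  structure(list(endpoint_code = endpoint_code,
                 weights = stats::setNames(rep(0, n_targets), target_ids),
                 intercept = stats::qlogis(min(max(prevalence, 1e-12),
                                               1 - 1e-12)),
                 feature_means = rep(0, n_targets),
                 feature_sds = rep(1, n_targets),
                 reg_strength = NA_real_,
                 threshold = NA_real_,
                 constant = prevalence),
            class = "endpoint_model")
}

#' @export
print.endpoint_model <- function(x, ...) {
  if (!is.na(x$constant)) {
    cat("endpoint model", if (!is.na(x$endpoint_code)) x$endpoint_code,
        ": constant (training prevalence ",
        sprintf("%.4f", x$constant), ")\n", sep = "")
  } else {
    cat("endpoint model", if (!is.na(x$endpoint_code))
        paste0(" ", x$endpoint_code), ": ", length(x$weights),
        " features, C = ", x$reg_strength, "\n", sep = "")
  }
  invisible(x)
}

#' Predict endpoint probabilities
#'
#' Applies the model's stored standardization and logistic link; scores are
#' monotone in the linear predictor.
#'
#' @param model An `endpoint_model`.
#' @param X CPI feature rows with the model's feature count (a vector is
#'   treated as one row).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "endpoint_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop("feature count mismatch: model has ", length(model$weights),
         ", input has ", ncol(X))
  Xz <- .standardize_apply(X, list(mean = model$feature_means,
                                   sd = model$feature_sds))
  as.numeric(stats::plogis(model$intercept + Xz %*% model$weights))
}

#' Select the maximum-F decision threshold
#'
#' Sweeps candidate thresholds (midpoints between consecutive sorted unique
#' scores plus sentinels below the minimum and above the maximum) and returns
#' the smallest candidate attaining the maximal F-score, where a sample is
#' predicted positive iff its score is `>=` the threshold.  Ties in F are
#' broken toward the smaller threshold (higher sensitivity).
#'
#' @param scores Numeric score vector.
#' @param y Binary 0/1 labels.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(scores, y) {
  y <- as.numeric(y)
  if (length(scores) != length(y)) stop("lengths differ")
  if (sum(y) == 0) stop("no positives; F-score undefined")
  npos <- sum(y)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yo <- y[o]
  # distinct score values v_1 > ... > v_m; predicting positive at a
  # threshold in (v_(k+1), v_k] selects the prefix of the k largest values
  ends <- c(which(diff(s) != 0), length(s))
  v <- s[ends]
  m <- length(v)
  tp <- cumsum(yo)[ends]
  # F = 2TP / (2TP + FP + FN) = 2TP / (predicted_pos + npos)
  f <- ifelse(tp == 0, 0, 2 * tp / (ends + npos))
  # candidate thresholds: low sentinel (predict all), midpoints, high
  # sentinel (predict none); ascending order pairs with prefixes m..1, none
  cand <- c(v[m] - 1, if (m > 1) rev((v[-m] + v[-1]) / 2), v[1] + 1)
  f_asc <- c(rev(f), 0)
  best <- 1L
  for (i in seq_along(cand))
    if (f_asc[i] > f_asc[best] + 1e-15) best <- i
  cand[best]
}

#' Repeated k-fold cross-validation over all endpoints
#'
#' Per repeat one random drug-level partition into `k` folds (sizes differing
#' by at most one) is shared across all endpoints, so that pooled "global"
#' metrics are well defined; with `stratified = TRUE` each endpoint instead
#' gets its own label-stratified partition.  Each endpoint's model is trained
#' on k-1 folds and scored on the held-out fold; training splits with fewer
#' than two positives (or negatives) degrade to a constant
#' training-prevalence model (counted in the output).  All randomness flows
#' from `seed`: repeat `r` uses seed `seed + r`.
#'
#' @param cpi A [cpi_matrix].
#' @param labels An [indication_labels] object.
#' @param endpoints An `endpoint_set` from [build_endpoints()].
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated partitions (default 10).
#' @param reg_strength Inverse penalty passed to [fit_endpoint_model()].
#' @param seed Integer seed.
#' @param stratified Per-endpoint stratified folds instead of one shared
#'   partition.
#' @param threshold_policy `"global"` (one max-F threshold on the pooled
#'   out-of-fold scores per repeat) or `"per_endpoint"`.
#' @return An object of class `cpi_cv`: list with `predictions` (one
#'   drugs x endpoints out-of-fold score matrix per repeat), `fold_maps`,
#'   `thresholds`, `per_repeat` (data frame of global metrics per repeat),
#'   `metrics` (mean and sd over repeats), `n_degenerate_fits`.
#' @export
cross_validate <- function(cpi, labels, endpoints, k = 10, repeats = 10,
                           reg_strength = 0.1, seed = 1, stratified = FALSE,
                           threshold_policy = c("global", "per_endpoint")) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(inherits(cpi, "cpi_matrix"), inherits(labels, "indication_labels"),
            inherits(endpoints, "endpoint_set"))
  drugs <- rownames(cpi)
  n <- length(drugs)
  if (k > n) stop("k (", k, ") exceeds number of drugs (", n, ")")
  codes <- names(endpoints$endpoints)
  Y <- vapply(codes, function(code)
    as.numeric(drugs %in% endpoints$endpoints[[code]]), numeric(n))
  dimnames(Y) <- list(drugs, codes)

  predictions <- vector("list", repeats)
  fold_maps <- vector("list", repeats)
  thresholds <- vector("list", repeats)
  per_repeat <- vector("list", repeats)
  n_degenerate <- 0L

  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    shared_fold <- sample(rep_len(seq_len(k), n))
    S <- matrix(NA_real_, n, length(codes), dimnames = list(drugs, codes))
    fold_mat <- matrix(shared_fold, n, length(codes),
                       dimnames = list(drugs, codes))
    for (j in seq_along(codes)) {
      yj <- Y[, j]
      fold <- if (stratified) {
        f <- integer(n)
        f[yj == 1] <- sample(rep_len(seq_len(k), sum(yj == 1)))
        f[yj == 0] <- sample(rep_len(seq_len(k), sum(yj == 0)))
        f
      } else shared_fold
      fold_mat[, j] <- fold
      for (f in seq_len(k)) {
        tr <- fold != f
        ytr <- yj[tr]
        if (sum(ytr) < 2 || sum(1 - ytr) < 2) {
          n_degenerate <- n_degenerate + 1L
          S[!tr, j] <- mean(ytr)
        } else {
          m <- fit_endpoint_model(cpi[tr, , drop = FALSE], ytr,
                                  reg_strength, codes[j])
          S[!tr, j] <- predict_scores(m, cpi[!tr, , drop = FALSE])
        }
      }
    }
    pooled_s <- as.vector(S)
    pooled_y <- as.vector(Y)
    thr <- if (threshold_policy == "global") {
      stats::setNames(rep(select_threshold(pooled_s, pooled_y),
                          length(codes)), codes)
    } else {
      stats::setNames(vapply(seq_along(codes), function(j)
        if (sum(Y[, j]) > 0) select_threshold(S[, j], Y[, j]) else NA_real_,
        numeric(1)), codes)
    }
    cm <- if (threshold_policy == "global") {
      confusion_metrics(pooled_s, pooled_y, thr[1])
    } else {
      pred <- sweep(S, 2, thr, ">=")
      .confusion_from_counts(sum(pred & Y == 1), sum(pred & Y == 0),
                             sum(!pred & Y == 1), sum(!pred & Y == 0))
    }
    per_repeat[[r]] <- data.frame(
      repeat_index = r,
      auroc = auroc(pooled_s, pooled_y),
      aupr = aupr(pooled_s, pooled_y),
      accuracy = cm$accuracy, precision = cm$precision,
      sensitivity = cm$sensitivity, specificity = cm$specificity)
    predictions[[r]] <- S
    fold_maps[[r]] <- fold_mat
    thresholds[[r]] <- thr
  }
  per_repeat <- do.call(rbind, per_repeat)
  mets <- c("auroc", "aupr", "accuracy", "precision", "sensitivity",
            "specificity")
  metrics <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(mets, function(m)
      if (repeats > 1) stats::sd(per_repeat[[m]]) else NA_real_, numeric(1)),
    row.names = NULL)
  if (n_degenerate > 0)
    message(n_degenerate,
            " training split(s) had <2 positives or <2 negatives; ",
            "constant-prevalence fallback used")
  structure(list(predictions = predictions, fold_maps = fold_maps,
                 thresholds = thresholds, per_repeat = per_repeat,
                 metrics = metrics, k = k, repeats = repeats, seed = seed,
                 reg_strength = reg_strength, level = endpoints$level,
                 threshold_policy = threshold_policy,
                 n_degenerate_fits = n_degenerate),
            class = "cpi_cv")
}

#' @export
print.cpi_cv <- function(x, digits = 3, ...) {
  cat(x$k, "-fold cross-validation, ", x$repeats, " repeat(s), ",
      ncol(x$predictions[[1]]), " endpoints (", x$level, " level)\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.*f", m$metric[i], digits, m$mean[i]))
    if (!is.na(m$sd[i])) cat(sprintf(" +/- %.*f", digits, m$sd[i]))
    cat("\n")
  }
  invisible(x)
}
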