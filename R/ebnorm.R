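# Empirical-Bayes posterior normalization of per-endpoint prediction scores.
#
# For one drug, split the endpoints into group G1 (diseases the drug treats)
# and G0 (diseases it does not).  Given a raw score y, the normalized
# confidence is the posterior
#   P(G1 | y) = f1(y) P(G1) / (f1(y) P(G1) + f0(y) P(G0)),
# with f1, f0 estimated from the empirical score distributions of the two
# groups and P(G1) the training proportion of treatable diseases.

#' Construct empirical-Bayes normalization distributions
#'
#' Low-level constructor taking arbitrary density functions; usually built
#' via [fit_eb()] or [fit_eb_training()].
#'
#' @param prior_g1 Prior probability of group 1, in `[0, 1]`.
#' @param density_g1,density_g0 Vectorized nonnegative density functions
#'   evaluable on `[0, 1]` (and outside it).
#' @param provenance Free-form provenance tag (e.g. `"pooled"` or a drug id).
#' @return An object of class `eb_distributions`.
#' @export
eb_distributions <- function(prior_g1, density_g1, density_g0,
                             provenance = "pooled") {
  if (!is.numeric(prior_g1) || length(prior_g1) != 1 ||
      prior_g1 < 0 || prior_g1 > 1)
    stop("prior_g1 must be a probability in [0, 1]")
  stopifnot(is.function(density_g1), is.function(density_g0))
  structure(list(prior_g1 = prior_g1, prior_g0 = 1 - prior_g1,
                 density_g1 = density_g1, density_g0 = density_g0,
                 provenance = provenance),
            class = "eb_distributions")
}

#' @export
print.eb_distributions <- function(x, ...) {
  cat("empirical-Bayes distributions (", x$provenance, "): P(G1) = ",
      sprintf("%.4f", x$prior_g1), "\n", sep = "")
  invisible(x)
}

# Gaussian KDE with Silverman bandwidth, evaluable at arbitrary points.
# Groups with fewer than `min_kde` samples fall back to a single Gaussian at
# the group mean with the pooled bandwidth (per-drug G1 groups are often
# tiny, so a hard small-sample policy is mandatory).  Each returned density
# closure carries a "log_density" attribute so the posterior can be formed
# on the log scale: far in the tails the densities underflow double
# precision while their ratio is still perfectly well defined.
.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

.kde_or_gaussian <- function(xs, pooled, min_kde = 5) {
  fallback_bw <- function(v) {
    bw <- if (length(v) >= 2) stats::bw.nrd0(v) else 0
    if (!is.finite(bw) || bw <= 0) bw <- stats::sd(v)
    if (!is.finite(bw) || bw <= 0) bw <- 0.05
    bw
  }
  if (length(xs) >= min_kde) {
    h <- stats::bw.nrd0(xs)
    if (!is.finite(h) || h <= 0) h <- fallback_bw(pooled)
    ld <- function(y) vapply(y, function(yi)
      .logsumexp(stats::dnorm(yi, xs, h, log = TRUE)) - log(length(xs)),
      numeric(1))
  } else {
    mu <- mean(xs)
    h <- fallback_bw(pooled)
    ld <- function(y) stats::dnorm(y, mu, h, log = TRUE)
  }
  f <- function(y) exp(ld(y))
  attr(f, "log_density") <- ld
  f
}

#' Fit empirical-Bayes distributions from two score groups
#'
#' Each group's score density is a Gaussian kernel density estimate with
#' Silverman bandwidth; groups with fewer than `min_kde` samples fall back
#' to a single Gaussian centred on the group mean with the pooled-sample
#' bandwidth.
#'
#' @param scores_g1 Raw scores of group-1 (treated) endpoints, in `[0, 1]`.
#' @param scores_g0 Raw scores of group-0 endpoints, in `[0, 1]`.
#' @param prior_g1 Prior `P(G1)`, e.g. the training proportion of diseases
#'   the drug treats.
#' @param min_kde Minimum group size for the KDE (default 5).
#' @param provenance Provenance tag stored in the result.
#' @return An [eb_distributions] object.
#' @export
fit_eb <- function(scores_g1, scores_g0, prior_g1, min_kde = 5,
                   provenance = "pooled") {
  if (!length(scores_g1))
    stop("empty G1 score sample; cannot fit the treated-group density")
  if (!length(scores_g0))
    stop("empty G0 score sample; cannot fit the untreated-group density")
  if (any(scores_g1 < 0 | scores_g1 > 1) || any(scores_g0 < 0 | scores_g0 > 1))
    stop("scores must lie in [0, 1]")
  pooled <- c(scores_g1, scores_g0)
  eb_distributions(prior_g1,
                   .kde_or_gaussian(scores_g1, pooled, min_kde),
                   .kde_or_gaussian(scores_g0, pooled, min_kde),
                   provenance)
}

#' Fit normalization distributions from training predictions
#'
#' Splits a drugs x endpoints score matrix by the training labels.  In
#' `"pooled"` mode all (drug, endpoint) score pairs feed one pair of
#' densities and the prior is the pooled label prevalence (the default for
#' novel drugs); in `"per_drug"` mode only the named training drug's row is
#' used and the prior is the proportion of endpoints that drug treats.
#'
#' @param train_scores Numeric matrix of training prediction scores (drug ids
#'   as rownames, endpoint codes as colnames), e.g. averaged out-of-fold
#'   cross-validation scores.
#' @param endpoints The `endpoint_set` defining positives per code.
#' @param mode `"pooled"` or `"per_drug"`.
#' @param drug_id Training drug id, required for `"per_drug"`.
#' @param min_kde Minimum group size for the KDE.
#' @return An [eb_distributions] object.
#' @export
fit_eb_training <- function(train_scores, endpoints,
                            mode = c("pooled", "per_drug"), drug_id = NULL,
                            min_kde = 5) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(train_scores), inherits(endpoints, "endpoint_set"))
  codes <- colnames(train_scores)
  if (!all(codes %in% names(endpoints$endpoints)))
    stop("train_scores columns must be endpoint codes")
  drugs <- rownames(train_scores)
  Y <- vapply(codes, function(code)
    as.numeric(drugs %in% endpoints$endpoints[[code]]),
    numeric(length(drugs)))
  if (mode == "per_drug") {
    if (is.null(drug_id) || !drug_id %in% drugs)
      stop("per_drug mode requires a training drug_id present in train_scores")
    s <- train_scores[drug_id, ]
    y <- Y[match(drug_id, drugs), ]
    if (sum(y) == 0)
      stop("drug ", drug_id, " treats no endpoint; G1 sample empty")
    fit_eb(s[y == 1], s[y == 0], prior_g1 = mean(y), min_kde = min_kde,
           provenance = paste0("per_drug:", drug_id))
  } else {
    s <- as.vector(train_scores)
    y <- as.vector(Y)
    fit_eb(s[y == 1], s[y == 0], prior_g1 = mean(y), min_kde = min_kde,
           provenance = "pooled")
  }
}

#' Normalize a raw score to a posterior confidence
#'
#' Applies Bayes' rule.  Density functions fitted by [fit_eb()] carry a
#' log-density and the posterior is formed from the log likelihood ratio, so
#' scores far outside the fitted support keep a well-defined posterior even
#' where both densities underflow double precision.  Plain density functions
#' are floored at `eps` before the ratio to avoid 0/0; when both floored
#' densities sit at the floor and the prior is degenerate the prior is
#' returned with a warning.
#'
#' @param eb An [eb_distributions] object.
#' @param y Raw score(s) in `[0, 1]` (vectorized).
#' @param eps Density floor for densities without a log form (default 1e-12).
#' @return Posterior `P(G1 | y)` in `[0, 1]`, same length as `y`.
#' @export
eb_normalize <- function(eb, y, eps = 1e-12) {
  stopifnot(inherits(eb, "eb_distributions"))
  if (length(y) == 0) return(numeric())
  if (eb$prior_g1 == 0) return(rep(0, length(y)))
  if (eb$prior_g1 == 1) return(rep(1, length(y)))
  ld1 <- attr(eb$density_g1, "log_density")
  ld0 <- attr(eb$density_g0, "log_density")
  if (!is.null(ld1) && !is.null(ld0)) {
    llr <- ld1(y) - ld0(y)
    llr[is.nan(llr)] <- 0  # both kernels at -Inf: no evidence either way
    return(stats::plogis(llr + stats::qlogis(eb$prior_g1)))
  }
  f1 <- pmax(eb$density_g1(y), eps)
  f0 <- pmax(eb$density_g0(y), eps)
  num <- f1 * eb$prior_g1
  den <- num + f0 * eb$prior_g0
  out <- ifelse(den > 0, num / den, eb$prior_g1)
  if (any(den == 0))
    warning("degenerate prior with floored densities; returning the prior")
  out
}

#' Normalize a drug's per-endpoint score profile
#'
#' Element-wise [eb_normalize()]; output order (and names) match the input.
#'
#' @param raw_scores Named numeric vector of raw per-endpoint scores for one
#'   drug.
#' @param eb An [eb_distributions] object (pooled, or per-drug for a training
#'   drug).
#' @return Named numeric vector of confidences in `[0, 1]`.
#' @export
normalize_profile <- function(raw_scores, eb) {
  stats::setNames(eb_normalize(eb, as.numeric(raw_scores)),
                  names(raw_scores))
}
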