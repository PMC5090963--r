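# Synthetic CPI benchmark generator with planted target-disease
# associations, plus the label-permutation null control.
#
# Per target t a baseline docking score mu_t is drawn uniformly from
# `score_location`; drug d's latent binding boost towards t is
# b_dt ~ |Normal(0,1)| (kcal/mol) and the observed score is
# s_dt = mu_t - b_dt + eps, eps ~ Normal(0, score_noise_sd) — boosts subtract
# because more negative means stronger binding.  Each disease j is assigned
# `causal_per_disease` causal targets T_j and labels follow
# y_dj ~ Bernoulli(plogis(alpha_j + effect * mean_{t in T_j} z_dt)) where
# z_dt is the standardized binding strength (b centred and scaled to unit
# variance, so `effect` is a log-odds change per SD of latent binding) and
# alpha_j is solved by bisection so the expected prevalence over the drug
# sample matches `prevalence`.

#' Configuration for the synthetic CPI generator
#'
#' Defaults reproduce the package's reference study conditions: 300 drugs,
#' 50 targets, 20 diseases, 3 causal targets per disease, effect 3 (log-odds
#' per SD of latent binding strength), prevalence 0.1, baseline scores
#' uniform on [-9, -5] kcal/mol with 0.1 kcal/mol docking noise.
#'
#' @param n_drugs,n_targets,n_diseases Positive integer dimensions.
#' @param causal_per_disease Number of causal targets per disease (>= 1).
#' @param effect Effect size beta >= 0 on the label logit.
#' @param prevalence Target label prevalence in (0, 1).
#' @param score_location Interval (length-2 numeric) for per-target baseline
#'   means, kcal/mol.
#' @param score_noise_sd Positive docking-noise standard deviation, kcal/mol.
#' @param n_decoy_diseases Optional count of decoy diseases with codes in the
#'   excluded 780-999 family range (exercise the endpoint filter).
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 300, n_targets = 50, n_diseases = 20,
                             causal_per_disease = 3, effect = 3,
                             prevalence = 0.1,
                             score_location = c(-9, -5),
                             score_noise_sd = 0.1,
                             n_decoy_diseases = 0, seed = 1) {
  stopifnot(n_drugs >= 1, n_targets >= 1, n_diseases >= 1,
            causal_per_disease >= 1, causal_per_disease <= n_targets,
            effect >= 0, prevalence > 0, prevalence < 1,
            length(score_location) == 2,
            score_location[1] <= score_location[2],
            score_noise_sd > 0, n_decoy_diseases >= 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 n_diseases = as.integer(n_diseases),
                 causal_per_disease = as.integer(causal_per_disease),
                 effect = effect, prevalence = prevalence,
                 score_location = as.numeric(score_location),
                 score_noise_sd = score_noise_sd,
                 n_decoy_diseases = as.integer(n_decoy_diseases),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Solve the label-model intercept by bisection on the empirical drug sample
# so |mean(plogis(a + beta*z)) - prevalence| <= tol.
.solve_alpha <- function(zbar, effect, prevalence, tol = 1e-4) {
  f <- function(a) mean(stats::plogis(a + effect * zbar)) - prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("cannot bracket the intercept for prevalence ", prevalence)
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol || (hi - lo) < 1e-12) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
}

#' Generate a synthetic CPI benchmark with planted associations
#'
#' @param config A [synthetic_config()].
#' @return List with `cpi` (a [cpi_matrix]), `labels` (an
#'   [indication_labels] over all drugs), and `truth` (list: `causal_targets`
#'   per disease, latent `boost` matrix, `alpha` per disease, realized
#'   `label_matrix`, `disease_codes`).
#' @export
generate_cpi_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nd <- config$n_drugs; nt <- config$n_targets; nj <- config$n_diseases
  drug_ids <- sprintf("SD%04d", seq_len(nd))
  target_ids <- sprintf("T%03d", seq_len(nt))
  mu <- stats::runif(nt, config$score_location[1], config$score_location[2])
  boost <- abs(matrix(stats::rnorm(nd * nt), nd, nt))
  eps <- matrix(stats::rnorm(nd * nt, sd = config$score_noise_sd), nd, nt)
  scores <- sweep(-boost + eps, 2, mu, "+")
  cpi <- cpi_matrix(scores, drug_ids, target_ids)
  # standardized latent binding strength: unit-variance half-normal
  z <- (boost - sqrt(2 / pi)) / sqrt(1 - 2 / pi)

  n_total <- nj + config$n_decoy_diseases
  # signal codes spread over families 100-699, one code per family;
  # decoy codes live in the excluded 780-999 block
  fam <- 100 + round(seq(0, 599, length.out = max(nj, 2)))[seq_len(nj)]
  codes <- sprintf("%d.0", fam)
  if (config$n_decoy_diseases > 0) {
    dfam <- 780 + round(seq(0, 219,
                            length.out = max(config$n_decoy_diseases, 2)))
    codes <- c(codes, sprintf("%d.0", dfam[seq_len(config$n_decoy_diseases)]))
  }
  causal <- lapply(seq_len(nj), function(j)
    sort(sample.int(nt, config$causal_per_disease)))
  alpha <- numeric(nj)
  Y <- matrix(0L, nd, n_total, dimnames = list(drug_ids, codes))
  for (j in seq_len(nj)) {
    zbar <- rowMeans(z[, causal[[j]], drop = FALSE])
    alpha[j] <- .solve_alpha(zbar, config$effect, config$prevalence)
    Y[, j] <- stats::rbinom(nd, 1, stats::plogis(alpha[j] +
                                                 config$effect * zbar))
  }
  for (j in seq_len(config$n_decoy_diseases))
    Y[, nj + j] <- stats::rbinom(nd, 1, config$prevalence)
  pos <- which(Y == 1L, arr.ind = TRUE)
  labels <- indication_labels(
    data.frame(drug_id = drug_ids[pos[, 1]], icd9_code = codes[pos[, 2]],
               stringsAsFactors = FALSE),
    universe = drug_ids)
  truth <- list(causal_targets = stats::setNames(causal, codes[seq_len(nj)]),
                boost = boost, alpha = alpha, label_matrix = Y,
                disease_codes = codes)
  list(cpi = cpi, labels = labels, truth = truth)
}

#' Permute labels within each endpoint (null control)
#'
#' Drug identities are permuted uniformly within each endpoint's label
#' column, preserving every endpoint's positive count while destroying any
#' drug-feature association.
#'
#' @param labels An [indication_labels] object.
#' @param seed Integer seed.
#' @return An [indication_labels] object over the same universe.
#' @export
permute_labels <- function(labels, seed) {
  stopifnot(inherits(labels, "indication_labels"))
  set.seed(seed)
  universe <- labels$universe
  codes <- sort(unique(labels$positives$icd9_code))
  out <- lapply(codes, function(code) {
    n_pos <- sum(labels$positives$icd9_code == code)
    data.frame(drug_id = sample(universe, n_pos), icd9_code = code,
               stringsAsFactors = FALSE)
  })
  indication_labels(do.call(rbind, out), universe = universe)
}
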