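# Empirical-Bayes posterior normalization.

test_that("posterior equals the prior when both groups share one distribution", {
  set.seed(51)
  s <- runif(40)
  eb <- fit_eb(s, s, prior_g1 = 0.2)
  ys <- c(0.05, 0.3, 0.5, 0.77, 0.99)
  expect_equal(eb_normalize(eb, ys), rep(0.2, 5), tolerance = 1e-12)
})

test_that("priors are stored as training proportions", {
  eb <- fit_eb(runif(3), runif(97), prior_g1 = 3 / 100)
  expect_equal(eb$prior_g1, 0.03)
  expect_equal(eb$prior_g0, 0.97)
})

test_that("tiny groups fall back to a single Gaussian with pooled bandwidth", {
  g1 <- 0.8
  g0 <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4)
  eb <- fit_eb(g1, g0, prior_g1 = 0.1)
  h <- stats::bw.nrd0(c(g1, g0))
  ys <- c(0.2, 0.5, 0.8)
  expect_equal(eb$density_g1(ys), dnorm(ys, mean = 0.8, sd = h),
               tolerance = 1e-12)
})

test_that("normalization follows Bayes' rule on hand-computed cases", {
  eb <- eb_distributions(prior_g1 = 0.1,
                         density_g1 = function(y) rep(0.9, length(y)),
                         density_g0 = function(y) rep(0.1, length(y)))
  # 0.9*0.1 / (0.9*0.1 + 0.1*0.9) = 0.5
  expect_equal(eb_normalize(eb, 0.5), 0.5, tolerance = 1e-12)

  eb1 <- eb_distributions(prior_g1 = 1,
                          density_g1 = function(y) dnorm(y, 0.5, 0.1),
                          density_g0 = function(y) dnorm(y, 0.2, 0.1))
  expect_equal(eb_normalize(eb1, c(0.1, 0.5, 0.9)), rep(1, 3))
})

test_that("histogram densities match the discrete-Bayes oracle", {
  set.seed(52)
  breaks <- seq(0, 1, length.out = 11)  # 10-bin grid
  for (i in 1:200) {
    mass_g1 <- as.vector(rmultinom(1, 50, runif(10))) / 50
    mass_g0 <- as.vector(rmultinom(1, 50, runif(10))) / 50
    prior <- runif(1, 0.05, 0.95)
    widths <- diff(breaks)
    d1 <- function(y) {
      b <- findInterval(y, breaks, rightmost.closed = TRUE)
      mass_g1[b] / widths[b]
    }
    d0 <- function(y) {
      b <- findInterval(y, breaks, rightmost.closed = TRUE)
      mass_g0[b] / widths[b]
    }
    eb <- eb_distributions(prior, d1, d0)
    y <- runif(5)
    keep <- d1(y) > 0 | d0(y) > 0  # avoid 0/0 cells, floored by design
    expect_equal(eb_normalize(eb, y[keep]),
                 oracle_discrete_posterior(y[keep], breaks, mass_g1, mass_g0,
                                           prior),
                 tolerance = 1e-10)
  }
})

test_that("confidences are monotone when the likelihood ratio is monotone", {
  # both groups below the KDE size threshold fall back to single Gaussians
  # with the shared pooled bandwidth: the log likelihood ratio is then
  # exactly linear increasing in y, so confidences must increase strictly
  g1 <- c(0.68, 0.70, 0.72)
  g0 <- c(0.28, 0.30, 0.32)
  eb <- fit_eb(g1, g0, prior_g1 = 0.1)
  ys <- seq(0.05, 0.95, by = 0.05)
  conf <- eb_normalize(eb, ys)
  expect_true(all(diff(conf) > 0))
  expect_true(all(conf >= 0 & conf <= 1))

  # full KDEs with well-separated groups: confidences increase across the
  # bulk of the support and stay monotone beyond it (log-space evaluation)
  set.seed(53)
  g1k <- pmin(pmax(rnorm(60, 0.7, 0.1), 0), 1)
  g0k <- pmin(pmax(rnorm(200, 0.3, 0.1), 0), 1)
  ebk <- fit_eb(g1k, g0k, prior_g1 = 0.1)
  confk <- eb_normalize(ebk, c(0.5, 0.7, 0.9, 0.99))
  expect_true(!is.unsorted(confk))          # monotone into the far tail
  expect_gt(confk[2], confk[1])             # strictly so before saturation
  # the log likelihood ratio itself keeps increasing where the posterior
  # saturates in double precision
  llr <- attr(ebk$density_g1, "log_density")(c(0.9, 0.99)) -
    attr(ebk$density_g0, "log_density")(c(0.9, 0.99))
  expect_gt(llr[2], llr[1])
})

test_that("profile normalization is element-wise, order-preserving and deterministic", {
  set.seed(54)
  eb <- fit_eb(runif(20, 0.5, 1), runif(50, 0, 0.5), prior_g1 = 0.2)
  raw <- c("250.00" = 0.4, "401.1" = 0.8, "272.0" = 0.4)
  conf <- normalize_profile(raw, eb)
  expect_named(conf, names(raw))
  expect_identical(unname(conf[1]), unname(conf[3]))  # same y, same confidence
  expect_identical(conf, normalize_profile(raw, eb))
  # constant profile gives constant confidences
  const <- normalize_profile(c(a = 0.3, b = 0.3, c = 0.3), eb)
  expect_length(unique(const), 1)
})

test_that("per-drug and pooled sources differ for an atypical training drug", {
  set.seed(55)
  n_drugs <- 12; n_codes <- 40
  drugs <- sprintf("D%02d", 1:n_drugs)
  codes <- sprintf("%d.0", 100 + seq_len(n_codes) * 3)
  S <- matrix(runif(n_drugs * n_codes, 0, 0.6), n_drugs, n_codes,
              dimnames = list(drugs, codes))
  # positives score high for most drugs...
  pos <- lapply(seq_len(n_codes), function(j)
    sort(sample(drugs, 6)))
  names(pos) <- codes
  for (j in seq_len(n_codes))
    S[pos[[j]], j] <- runif(6, 0.6, 1)
  # ...but drug D01 is atypical: its scores are uniformly low
  S["D01", ] <- runif(n_codes, 0, 0.2)
  eps <- structure(list(level = "disease", endpoints = pos,
                        min_positives = 1, excluded_range = c(780L, 999L)),
                   class = "endpoint_set")
  pooled <- fit_eb_training(S, eps, mode = "pooled")
  perdrug <- fit_eb_training(S, eps, mode = "per_drug", drug_id = "D01")
  y <- 0.15
  expect_false(isTRUE(all.equal(eb_normalize(pooled, y),
                                eb_normalize(perdrug, y))))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(fit_eb(numeric(), runif(5), 0.1), "empty G1")
  expect_error(fit_eb(runif(5), numeric(), 0.1), "empty G0")
  expect_error(fit_eb(c(0.2, 1.4), runif(5), 0.1), "\\[0, 1\\]")
  expect_error(eb_distributions(1.2, identity, identity), "probability")
})
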