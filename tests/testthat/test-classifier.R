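# Per-endpoint ridge-logistic models, threshold selection and
# cross-validation mechanics.

test_that("a linearly separable toy problem is fit perfectly", {
  X <- rbind(c(-9, -7), c(-8.5, -7.2), c(-5, -7.1), c(-5.5, -6.9))
  y <- c(1, 1, 0, 0)
  m <- fit_endpoint_model(X, y, reg_strength = 10)
  s <- predict_scores(m, X)
  expect_equal(auroc(s, y), 1.0)
})

test_that("single-class labels and malformed input are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_endpoint_model(X, rep(1, 5)), "single class")
  expect_error(fit_endpoint_model(X, rep(0, 5)), "single class")
  Xbad <- X; Xbad[2, 3] <- Inf
  expect_error(fit_endpoint_model(Xbad, c(1, 0, 1, 0, 1)), "non-finite")
  expect_error(fit_endpoint_model(X, c(1, 0, 1, 0, 2)), "binary")
})

test_that("duplicated feature columns receive equal weights under L2", {
  set.seed(31)
  X <- matrix(rnorm(200), 50, 4)
  X <- cbind(X, X[, 2])  # column 5 duplicates column 2
  lp <- -0.5 + X[, 2] * 1.5
  y <- rbinom(50, 1, plogis(lp))
  m <- fit_endpoint_model(X, y, reg_strength = 1)
  expect_equal(unname(m$weights[2]), unname(m$weights[5]), tolerance = 1e-6)
})

test_that("predict_scores applies the logistic link and stored standardization", {
  m <- structure(list(endpoint_code = NA, weights = c(a = 0, b = 0),
                      intercept = 0, feature_means = c(0, 0),
                      feature_sds = c(1, 1), reg_strength = 1,
                      threshold = NA_real_, constant = NA_real_),
                 class = "endpoint_model")
  expect_equal(predict_scores(m, matrix(rnorm(10), 5, 2)), rep(0.5, 5))

  m$weights <- c(a = 1, b = -0.5)
  x <- c(0.3, 0.1)
  base <- predict_scores(m, x)
  expect_gt(predict_scores(m, x + c(0.1, 0)), base)   # positive weight
  expect_lt(predict_scores(m, x + c(0, 0.1)), base)   # negative weight
  expect_error(predict_scores(m, matrix(0, 1, 3)), "mismatch")

  # determinism across repeated fits on identical input
  set.seed(77)
  X <- matrix(rnorm(120), 30, 4)
  y <- rbinom(30, 1, 0.4)
  m1 <- fit_endpoint_model(X, y)
  m2 <- fit_endpoint_model(X, y)
  expect_identical(predict_scores(m1, X), predict_scores(m2, X))
})

test_that("select_threshold matches hand-enumerated cases", {
  # perfect separation: max F = 1 on (0.4, 0.8]; smallest candidate is the
  # midpoint 0.6
  expect_equal(select_threshold(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 0.6)
  # all positives: predict everything positive from the low sentinel
  expect_equal(select_threshold(c(0.3, 0.7), c(1, 1)), 0.3 - 1)
  # inverted pair: best F = 2/3 by predicting all positive (low sentinel)
  expect_equal(select_threshold(c(0.2, 0.9), c(1, 0)), 0.2 - 1)
  expect_error(select_threshold(c(0.2, 0.9), c(0, 0)), "no positives")
})

test_that("select_threshold equals the exhaustive sweep oracle on random instances", {
  set.seed(123)
  for (i in 1:500) {
    n <- sample(2:12, 1)
    scores <- round(runif(n), 2)  # ties likely
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[sample(n, 1)] <- 1
    expect_identical(select_threshold(scores, y),
                     oracle_max_f_threshold(scores, y))
  }
})

test_that("cross-validation is deterministic and scores every drug once per repeat", {
  sim <- generate_cpi_data(synthetic_config(
    n_drugs = 20, n_targets = 6, n_diseases = 3, causal_per_disease = 2,
    effect = 2, prevalence = 0.3, seed = 9))
  eps <- build_endpoints(sim$labels, "disease", min_positives = 3)
  cv1 <- suppressMessages(cross_validate(sim$cpi, sim$labels, eps, k = 10,
                                         repeats = 2, seed = 4))
  cv2 <- suppressMessages(cross_validate(sim$cpi, sim$labels, eps, k = 10,
                                         repeats = 2, seed = 4))
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$metrics, cv2$metrics)
  for (S in cv1$predictions) expect_false(anyNA(S))
  expect_error(
    cross_validate(sim$cpi, sim$labels, eps, k = 21, repeats = 1, seed = 1),
    "exceeds")
})

test_that("a held-out drug's own label cannot influence its out-of-fold score", {
  sim <- generate_cpi_data(synthetic_config(
    n_drugs = 40, n_targets = 8, n_diseases = 2, causal_per_disease = 2,
    effect = 3, prevalence = 0.3, seed = 13))
  eps <- build_endpoints(sim$labels, "disease", min_positives = 3)
  cv <- suppressMessages(cross_validate(sim$cpi, sim$labels, eps, k = 5,
                                        repeats = 1, seed = 2))
  code <- names(eps$endpoints)[1]
  drugs <- rownames(sim$cpi)
  # flip one drug's label for this endpoint
  flip <- drugs[1]
  pos <- eps$endpoints[[code]]
  new_pos <- if (flip %in% pos) setdiff(pos, flip) else sort(c(pos, flip))
  eps2 <- eps
  eps2$endpoints[[code]] <- new_pos
  pairs2 <- do.call(rbind, lapply(names(eps2$endpoints), function(cd)
    data.frame(drug_id = eps2$endpoints[[cd]], icd9_code = cd)))
  lab2 <- indication_labels(pairs2, universe = drugs)
  cv2 <- suppressMessages(cross_validate(sim$cpi, lab2, eps2, k = 5,
                                         repeats = 1, seed = 2))
  expect_identical(cv$predictions[[1]][flip, code],
                   cv2$predictions[[1]][flip, code])
})

test_that("constant fallback engages when a training split lacks positives", {
  # 2 positives among 12 drugs under leave-one-out: whenever a positive is
  # held out, the training split has a single positive and must degrade to
  # the constant training-prevalence model
  cpi <- toy_cpi(12, 4)
  lab <- toy_labels(list(c("D1", "250.00"), c("D2", "250.00")),
                    universe = rownames(cpi))
  eps <- build_endpoints(lab, "disease", min_positives = 2)
  expect_message(
    cv <- cross_validate(cpi, lab, eps, k = 12, repeats = 1, seed = 1),
    "fallback")
  expect_false(anyNA(cv$predictions[[1]]))
  expect_equal(cv$n_degenerate_fits, 2)
  # the two positives' out-of-fold scores equal the training prevalence 1/11
  S <- cv$predictions[[1]]
  expect_equal(unname(S[c("D1", "D2"), "250.00"]), rep(1 / 11, 2))
})
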