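# Confusion metrics, AUROC, AUPR and the three aggregation protocols.

test_that("confusion metrics match a hand contingency table", {
  m <- confusion_metrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0), 0.5)
  # TP=1 FP=1 FN=1 TN=1
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_length(m$undefined, 0)

  perfect <- confusion_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1))

  above <- confusion_metrics(c(0.3, 0.2), c(1, 0), 0.9)
  expect_equal(above$specificity, 1)
  expect_equal(above$sensitivity, 0)
  expect_true("precision" %in% above$undefined)
  expect_true(is.na(above$precision))
})

test_that("AUROC handles perfect, anti-perfect and all-tie cases", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.1), c(0, 1)), 0.0)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auroc(c(0.5, 0.6), c(1, 1)), "positive and one negative")
})

test_that("AUROC equals the all-pairs oracle and is rank-invariant", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(1:3, 1))
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    expect_equal(auroc(scores, y), oracle_auroc(scores, y),
                 tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  set.seed(43)
  s <- runif(25)
  y <- rbinom(25, 1, 0.4); y[1:2] <- c(0, 1)
  a <- auroc(s, y)
  expect_equal(auroc(exp(3 * s), y), a, tolerance = 1e-12)
  expect_equal(auroc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y), a,
               tolerance = 1e-12)
})

test_that("AUPR matches hand-enumerated PR curves and analytic limits", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # 6-point instance, enumerated by the oracle walking distinct thresholds
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  y <- c(1, 0, 1, 1, 0, 0)
  # by hand: recall steps at ranks 1 (P=1), 3 (P=2/3), 4 (P=3/4)
  expect_equal(aupr(s, y), (1 / 3) * (1 + 2 / 3 + 3 / 4))
  expect_equal(aupr(s, y), oracle_aupr(s, y), tolerance = 1e-12)
  # ties handled as single steps
  set.seed(44)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    scores <- round(runif(n), 1)
    y2 <- rbinom(n, 1, 0.5)
    if (sum(y2) == 0) y2[1] <- 1
    expect_equal(aupr(scores, y2), oracle_aupr(scores, y2),
                 tolerance = 1e-12)
  }
  # random scores converge to prevalence
  set.seed(45)
  n <- 20000
  y3 <- rbinom(n, 1, 0.15)
  expect_equal(aupr(runif(n), y3), 0.15, tolerance = 0.02)
  expect_error(aupr(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("AUPR beats prevalence for a better-than-random ranking", {
  y <- c(rep(1, 10), rep(0, 90))
  s <- c(runif(10, 0.5, 1), runif(90, 0, 0.8))
  expect_gt(aupr(s, y), mean(y))
})

test_that("global and drug-centric aggregation differ on an asymmetric fixture", {
  # 2 drugs x 2 diseases with hand-chosen scores
  preds <- matrix(c(0.9, 0.2,   # drug A: disease1, disease2
                    0.6, 0.8),  # drug B
                  2, 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("250.00", "401.1")))
  lab <- toy_labels(list(c("A", "250.00"), c("B", "401.1")),
                    universe = c("A", "B"))
  g <- aggregate_metrics(preds, lab, "global", threshold = 0.5)
  d <- aggregate_metrics(preds, lab, "drug_centric", threshold = 0.5)
  # pooled: scores (.9,.2,.6,.8) labels (1,0,0,1): 3 of 4 pos-neg pairs won,
  # oracle AUROC 3/4
  expect_equal(g$metrics$mean[g$metrics$metric == "auroc"],
               oracle_auroc(c(0.9, 0.2, 0.6, 0.8), c(1, 0, 0, 1)))
  # per drug both AUROCs are 1, so the mean is 1 and differs from global
  expect_equal(d$metrics$mean[d$metrics$metric == "auroc"], 1)
  expect_equal(d$n_evaluated, 2)

  # disease-centric on the same fixture
  dc <- aggregate_metrics(preds, lab, "disease_centric", threshold = 0.5)
  expect_equal(dc$metrics$mean[dc$metrics$metric == "auroc"],
               mean(c(auroc(c(0.9, 0.6), c(1, 0)),
                      auroc(c(0.2, 0.8), c(0, 1)))))
})

test_that("entities with single-class labels are skipped and counted", {
  preds <- matrix(c(0.9, 0.2, 0.6, 0.8), 2, 2,
                  dimnames = list(c("A", "B"), c("250.00", "401.1")))
  # both diseases treated by both drugs: every drug row is all-positive
  lab <- toy_labels(list(c("A", "250.00"), c("A", "401.1"),
                         c("B", "250.00"), c("B", "401.1")))
  expect_error(aggregate_metrics(preds, lab, "drug_centric", threshold = 0.5),
               "no evaluable")
})

test_that("global aggregation of a single entity equals the per-entity metric", {
  preds <- matrix(c(0.9, 0.3, 0.7, 0.1), 1, 4,
                  dimnames = list("A", c("250.00", "401.1", "272.0", "300.4")))
  lab <- toy_labels(list(c("A", "250.00"), c("A", "272.0")))
  g <- aggregate_metrics(preds, lab, "global", threshold = 0.5)
  expect_equal(g$metrics$mean[g$metrics$metric == "auroc"],
               auroc(c(0.9, 0.3, 0.7, 0.1), c(1, 0, 1, 0)))
})
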