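test_that("regression metrics reproduce worked examples", {
  y <- c(1.2, 3.4, 2.2, 5.6, 0.1)
  expect_equal(unname(regression_metrics(y, y)), c(0, 1, 1))
  # reversed ranks give Spearman -1
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(regression_metrics(x, rev(x))["spearman"]), -1)
  # actual (1, 2), predicted (3, 5): rmse = sqrt((4 + 9) / 2)
  expect_equal(unname(regression_metrics(c(1, 2), c(3, 5))["rmse"]),
               sqrt(6.5), tolerance = 1e-12)
  expect_error(regression_metrics(1:3, 1:4), "length")
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "zero variance")
})

test_that("the alternative printed R-squared denominator is available", {
  set.seed(5)
  a <- rnorm(20); p <- a + rnorm(20, sd = 0.5)
  std <- regression_metrics(a, p)["r2"]
  alt <- regression_metrics(a, p, printed_denominator = TRUE)["r2"]
  expect_equal(unname(std), 1 - sum((a - p)^2) / sum((a - mean(a))^2))
  expect_equal(unname(alt), 1 - sum((a - p)^2) / sum((p - mean(a))^2))
  expect_false(isTRUE(all.equal(std, alt)))
})

test_that("Spearman handles ties by average ranks and is transform-invariant", {
  set.seed(6)
  for (rep in 1:10) {
    a <- sample(1:6, 30, replace = TRUE) + rnorm(30, sd = 0.01 * (rep %% 2))
    p <- sample(1:4, 30, replace = TRUE) / 2
    got <- unname(regression_metrics(a, p)["spearman"])
    expect_equal(got, oracle_spearman(a, p), tolerance = 1e-10)
    # invariance under strictly increasing transforms
    expect_equal(unname(regression_metrics(exp(a / 10), p^3 + 2 * p)["spearman"]),
                 got, tolerance = 1e-10)
  }
  # without ties the textbook rank-difference formula agrees
  a <- rnorm(25); p <- rnorm(25)
  expect_equal(unname(regression_metrics(a, p)["spearman"]),
               oracle_spearman_d2(a, p), tolerance = 1e-10)
})

test_that("classification metrics reproduce the confusion-matrix arithmetic", {
  # TP = 2, FP = 1, FN = 1, TN = 6
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.2, 0.7, 0.3, 0.2, 0.1, 0.15, 0.05, 0.25)
  m <- classification_metrics(labels, probs, cutoff = 0.5)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["f1"]), 2 / 3)  # f1 = precision = recall here
  expect_equal(unname(m["accuracy"]), 0.8)
  # perfectly separating scores
  sep <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unname(sep["auroc"]), 1)
  expect_equal(unname(sep["aupr"]), 1)
  # all scores tied, balanced classes: AUROC is 0.5 by the tie convention
  tied <- classification_metrics(c(0, 1, 0, 1), rep(0.4, 4))
  expect_equal(unname(tied["auroc"]), 0.5)
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.3)), "one class")
})

test_that("AUROC by rank statistic equals the ROC step-curve integral", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 40
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    probs <- if (rep %% 2) runif(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    got <- unname(classification_metrics(labels, probs)["auroc"])
    expect_equal(got, oracle_auroc_curve(labels, probs), tolerance = 1e-10)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                            direction = "<")))
      expect_equal(got, ref, tolerance = 1e-10)
    }
    expect_equal(unname(classification_metrics(labels, probs)["aupr"]),
                 oracle_aupr(labels, probs), tolerance = 1e-10)
  }
})

test_that("cross-validation aggregation gives means and sample variances", {
  r1 <- list(loewe = c(rmse = 8), synergy = c(auroc = 0.8))
  r2 <- list(loewe = c(rmse = 10), synergy = c(auroc = 0.9))
  agg <- aggregate_cv(list(r1, r2))
  expect_equal(unname(agg$mean$loewe["rmse"]), 9)
  expect_equal(unname(agg$variance$loewe["rmse"]), 2)
  expect_equal(unname(agg$mean$synergy["auroc"]), 0.85)
  # identical folds have zero variance
  agg0 <- aggregate_cv(list(r1, r1, r1))
  expect_equal(unname(agg0$variance$loewe["rmse"]), 0)
  # brute-force mean over five random folds
  set.seed(8)
  reports <- lapply(1:5, function(i) list(loewe = c(rmse = runif(1, 5, 12))))
  agg5 <- aggregate_cv(reports)
  expect_equal(unname(agg5$mean$loewe["rmse"]),
               mean(vapply(reports, function(r) r$loewe["rmse"], numeric(1))),
               tolerance = 1e-12)
  expect_error(aggregate_cv(list(r1, list(bliss = c(rmse = 1)))), "mismatched")
  expect_error(aggregate_cv(list(r1)), "at least two")
})

test_that("support counting reproduces the published screening rows", {
  # predicted scores of two reported candidate combinations
  expect_equal(count_support(c(zip = 6.84, bliss = 7.7, hsa = 8.48,
                               s = 20.53, loewe = 5.66)), 5)
  expect_equal(count_support(c(zip = 3.14, bliss = 14.22, hsa = 7.27,
                               s = 13.53, loewe = 6.7)), 4)
  expect_equal(count_support(rep(0, 5)), 0)
  expect_equal(count_support(rep(5, 5)), 0)  # strict inequality
  expect_error(count_support(c(zip = 1, bliss = 2, hsa = 3, s = 4)), "missing")
  expect_error(count_support(c(1, 2, 3)), "expected 5")
  # monotone non-increasing in the threshold
  sc <- c(loewe = 6, bliss = 2, zip = 9, hsa = 5.5, s = -4)
  counts <- vapply(c(-10, 0, 5, 6, 10), function(th) count_support(sc, th),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pairwise score correlations match the textbook formula", {
  set.seed(9)
  m <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, c("loewe", "bliss", "zip", "hsa", "s")))
  m[, 2] <- 2 * m[, 1] + 1  # exact linearity
  cm <- pairwise_score_correlation(m)
  expect_equal(dim(cm), c(5, 5))
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_equal(cm["loewe", "bliss"], 1)
  expect_equal(cm, t(cm))
  for (pair in list(c(1, 3), c(2, 4), c(3, 5))) {
    expect_equal(cm[pair[1], pair[2]],
                 oracle_pearson(m[, pair[1]], m[, pair[2]]), tolerance = 1e-10)
  }
  # masked subset
  mask <- m[, "loewe"] > 0
  cms <- pairwise_score_correlation(m, mask)
  expect_equal(cms["zip", "hsa"],
               oracle_pearson(m[mask, "zip"], m[mask, "hsa"]), tolerance = 1e-10)
  m2 <- m; m2[, "s"] <- 7
  expect_error(pairwise_score_correlation(m2), "'s'")
})

pred_table <- function() {
  data.frame(
    drug_x = c("a", "b", "c", "d"), drug_y = c("e", "f", "g", "h"),
    cell_line = "c1",
    pred_loewe = c(35, 10, 40, 6), pred_bliss = c(33, 4, 45, 7),
    pred_zip = c(31, 12, 50, 2), pred_hsa = c(36, 11, 41, 9),
    pred_s = c(38, 20, 44, 1),
    prob_synergy = c(0.995, 0.95, 0.999, 0.3),
    prob_ddi = c(0.1, 0.2, 0.95, 0.05), stringsAsFactors = FALSE)
}

test_that("screening rules mirror the published protocol", {
  p <- pred_table()
  # all five predicted scores above 30 retains only such rows
  high <- screen_candidates(p, list(screen_rule("all_scores_threshold", 30)))
  expect_equal(high$drug_x, c("a", "c"))
  expect_equal(high$support, c(5L, 5L))
  # probability 0.99 rule removes a 0.95 row
  conf <- screen_candidates(p, list(screen_rule("prob_threshold", 0.99)))
  expect_false("b" %in% conf$drug_x)
  # DDI exclusion drops high adverse-interaction probability
  safe <- screen_candidates(p, list(screen_rule("prob_threshold", 0.99),
                                    screen_rule("ddi_exclude", 0.9)))
  expect_equal(safe$drug_x, "a")
  # empty rule list is the identity (plus support annotation)
  all_rows <- screen_candidates(p)
  expect_equal(nrow(all_rows), 4)
  expect_equal(all_rows$support, c(5L, 4L, 5L, 3L))
  # support-count rule
  sup <- screen_candidates(p, list(screen_rule("support_count", 5, min_support = 5)))
  expect_equal(sup$drug_x, c("a", "c"))
  # pure filters commute
  r1 <- screen_rule("prob_threshold", 0.99)
  r2 <- screen_rule("all_scores_threshold", 30)
  expect_identical(screen_candidates(p, list(r1, r2)),
                   screen_candidates(p, list(r2, r1)))
  expect_error(screen_candidates(p[, setdiff(names(p), "prob_synergy")],
                                 list(r1)), "missing columns")
})
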