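test_that("metrics identities reproduce the published worked examples", {
  # printed per-class rates with class sizes 49 preterm / 18 term
  rf <- metricsFromRates(tpr = 0.94, tnr = 0.06, n_pos = 49, n_neg = 18,
                         fpr = 0.94, fnr = 0.06)
  expect_equal(round(rf$accuracy, 2), 0.70)
  expect_equal(round(rf$f1, 2), 0.82)
  gbm <- metricsFromRates(tpr = 0.88, tnr = 0.28, n_pos = 49, n_neg = 18,
                          fpr = 0.72, fnr = 0.12)
  expect_equal(round(gbm$accuracy, 2), 0.72)
  expect_equal(round(gbm$f1, 2), 0.82)
  svm <- metricsFromRates(tpr = 1, tnr = 0, n_pos = 49, n_neg = 18,
                          fpr = 1, fnr = 0)
  expect_equal(round(svm$accuracy, 2), 0.73)
  expect_equal(round(svm$f1, 2), 0.84)
  # perfect classifier
  perf <- metricsFromRates(1, 1, 49, 18)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)
  # no positive predictions: F1 defined as 0 with a warning
  expect_warning(z <- metricsFromRates(0, 1, 5, 5, fpr = 0),
                 "F1 defined as 0")
  expect_equal(z$f1, 0)
})

test_that("confusion rates are complementary and preterm-positive", {
  pred <- c("preterm", "preterm", "term", "term", "preterm")
  truth <- c("preterm", "term", "term", "preterm", "preterm")
  r <- confusionRates(pred, truth)
  expect_equal(r$tpr + r$fnr, 1)
  expect_equal(r$fpr + r$tnr, 1)
  expect_equal(r$tpr, 2 / 3)
  expect_equal(r$tnr, 1 / 2)
})

test_that("the LOOCV loop matches exhaustive enumeration with 1NN", {
  x <- matrix(c(0, 1, 5, 6, 10, 11), ncol = 1)
  y <- c("preterm", "preterm", "preterm", "term", "term", "term")
  res <- loocv(x, y, model = "1NN", seed = 1)
  # independent enumeration of every fold
  oracle <- vapply(1:6, function(i) {
    d <- abs(x[-i, 1] - x[i, 1])
    y[-i][which.min(d)]
  }, character(1))
  expect_identical(res$predictions, oracle)
  # hand-checked: sample 3 (5) sits nearest 6 (term); sample 4 (6)
  # nearest 5 (preterm); the rest stay within their cluster
  expect_identical(res$predictions,
                   c("preterm", "preterm", "term", "preterm",
                     "term", "term"))
  expect_equal(res$rates$tpr, 2 / 3)
  expect_equal(res$rates$tnr, 2 / 3)
})

test_that("well-separated clusters are classified perfectly", {
  sep <- separableFeatures(n_pos = 9, n_neg = 7, shift = 8)
  for (m in c("RF", "GBM", "SVM")) {
    res <- loocv(sep$x, sep$y, model = m, seed = 2)
    expect_equal(res$metrics$accuracy, 1, label = m)
  }
})

test_that("LOOCV predictions do not depend on sample order", {
  sep <- separableFeatures(n_pos = 6, n_neg = 6, shift = 2, seed = 3)
  res <- loocv(sep$x, sep$y, model = "1NN", seed = 5)
  perm <- c(4, 1, 12, 7, 2, 3, 9, 10, 5, 11, 8, 6)
  res_p <- loocv(sep$x[perm, ], sep$y[perm], model = "1NN", seed = 5)
  expect_identical(res_p$predictions, res$predictions[perm])
})

test_that("LOOCV is deterministic under a fixed seed", {
  sep <- separableFeatures(n_pos = 7, n_neg = 5, shift = 1.5, seed = 8)
  a <- loocv(sep$x, sep$y, model = "RF", seed = 11)
  b <- loocv(sep$x, sep$y, model = "RF", seed = 11)
  expect_identical(a$predictions, b$predictions)
})

test_that("PC-input LOOCV enforces the k boundary", {
  sep <- separableFeatures(n_pos = 4, n_neg = 4, p = 10, shift = 6)
  expect_error(loocvOnPCs(sep$x, "1NN", k = 7, labels = sep$y),
               "n - 2")
  res <- loocvOnPCs(sep$x, "1NN", k = 6, labels = sep$y)
  expect_identical(res$metrics$n_pcs, 6L)
})

test_that("strict and global leakage modes agree on an easy cohort", {
  set.seed(42)
  n <- 120; p <- 40
  y <- rep(c("preterm", "term"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "preterm", 1:5] <- x[y == "preterm", 1:5] + 1.5
  a_s <- loocvOnPCs(x, "SVM", 3, seed = 1, leakage = "strict",
                    labels = y)$metrics$accuracy
  a_g <- loocvOnPCs(x, "SVM", 3, seed = 1, leakage = "global",
                    labels = y)$metrics$accuracy
  expect_lt(abs(a_s - a_g), 0.03)
})

test_that("identical features degrade every model to the majority rate", {
  x <- matrix(3.2, 12, 5)
  y <- rep(c("preterm", "term"), c(8, 4))
  for (m in c("RF", "GBM", "SVM")) {
    res <- loocv(x, y, model = m, seed = 4)
    expect_equal(res$metrics$accuracy, 8 / 12, label = m)
  }
})

test_that("the PC sweep covers the full grid and breaks ties as specified", {
  sep <- separableFeatures(n_pos = 12, n_neg = 8, p = 15, shift = 6,
                           seed = 10)
  sw <- sweepPCCount(sep$x, k_range = 3:10, seed = 1, labels = sep$y)
  expect_identical(nrow(sw$table), 24L)
  expect_identical(sort(unique(sw$table$k)), 3:10)
  expect_setequal(unique(sw$table$model), c("RF", "GBM", "SVM"))
  # perfectly separable: every model at ceiling, so the tie-break gives
  # the smallest k and the RF < GBM < SVM model order
  expect_equal(max(sw$table$accuracy), 1)
  expect_identical(sw$best_k, 3L)
  expect_identical(sw$best_model, "RF")
})

test_that("random-forest PC importance finds a planted signal component", {
  hits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    n <- 60
    y <- rep(c("preterm", "term"), each = n / 2)
    scores <- matrix(rnorm(n * 4), n, 4)
    scores[y == "preterm", 2] <- scores[y == "preterm", 2] + 3
    imp <- rfPCImportance(scores, y, seed = 300 + s, n_shuffle = 25)
    which.max(imp$importance) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("noise components carry (near) zero importance", {
  set.seed(77)
  n <- 60
  y <- rep(c("preterm", "term"), each = n / 2)
  scores <- matrix(rnorm(n * 4), n, 4)
  scores[y == "preterm", 1] <- scores[y == "preterm", 1] + 4
  imp <- rfPCImportance(scores, y, seed = 77, n_shuffle = 25)
  expect_gt(imp$importance[1], 0.2)
  expect_true(all(imp$importance[2:4] < 0.1))
  expect_true(all(imp$importance >= 0))
})

test_that("Welch t from summaries matches t.test on raw data", {
  set.seed(15)
  a <- rnorm(25, 1, 2); b <- rnorm(40, 0.2, 1.1)
  ours <- groupTTest(mean(a), sd(a), 25, mean(b), sd(b), 40)
  ref <- t.test(a, b)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("published group comparisons reproduce their significance calls", {
  # gestational age 30.25 (2.72) n=49 vs 38.52 (1.44) n=18
  ga <- groupTTest(30.25, 2.72, 49, 38.52, 1.44, 18)
  expect_lt(ga$p.value, 0.05)
  # identical summaries: t = 0, p = 1
  id <- groupTTest(5, 1, 10, 5, 1, 10)
  expect_equal(id$statistic, 0)
  expect_equal(id$p.value, 1)
  expect_error(groupTTest(1, 0, 5, 2, 0, 5), "zero")
  # male sex 31/49 vs 12/18: not significant by Pearson chi-squared
  cs <- groupChisqTest(31, 49, 12, 18)
  expect_gt(cs$p.value, 0.05)
  # hand Pearson oracle for the same table
  O <- rbind(c(31, 18), c(12, 6))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  expect_equal(cs$statistic, chi2, tolerance = 1e-10)
  expect_equal(cs$p.value, pchisq(chi2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})
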