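## LOOCV classification on spectral bins or leading principal
## components.  The positive class is "preterm" throughout.
##
## Frozen default hyperparameters (determinism, not tuning):
##   RF  - 500 trees, floor(sqrt(p)) candidate features per split
##   GBM - 100 boosting rounds, depth 3, learning rate 0.1
##   SVM - radial kernel, cost 1, gamma = 1 / (p * var(training matrix))
## "1NN" (single nearest neighbour, Euclidean) is a deliberately simple
## stand-in model used to validate the cross-validation loop itself.

.MODELS <- c("RF", "GBM", "SVM")

.fold_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 131 + i * 7919) %% 2147483629)
}

# run expr under its own seed, then restore the caller's RNG stream so
# model fitting never perturbs outer randomness (e.g. permutation loops)
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.as_group_factor <- function(y) {
  f <- factor(as.character(y), levels = c("preterm", "term"))
  if (anyNA(f)) stop("labels must be 'preterm' or 'term'")
  f
}

.fit_predict <- function(model_name, xtr, ytr, xte, seed) {
  xtr <- as.matrix(xtr)
  if (is.null(dim(xte))) xte <- matrix(xte, nrow = 1L)
  xte <- as.matrix(xte)
  p <- ncol(xtr)
  ytr <- droplevels(.as_group_factor(ytr))
  if (nlevels(ytr) < 2L)
    stop("a training fold lost one class entirely")
  ytr <- factor(as.character(ytr), levels = c("preterm", "term"))
  colnames(xtr) <- colnames(xte) <- sprintf("f%04d", seq_len(p))
  if (model_name %in% .MODELS && all(sweep(xtr, 2L, xtr[1L, ]) == 0)) {
    # no informative feature: every model degenerates to majority vote
    maj <- names(which.max(table(ytr)))
    return(rep(maj, nrow(xte)))
  }
  if (model_name == "RF") {
    fit <- .with_seed(seed, randomForest::randomForest(
      x = xtr, y = ytr, ntree = 500L,
      mtry = max(1L, floor(sqrt(p)))))
    as.character(stats::predict(fit, xte))
  } else if (model_name == "GBM") {
    dtr <- xgboost::xgb.DMatrix(xtr,
                                label = as.numeric(ytr == "preterm"),
                                nthread = 1L)
    fit <- .with_seed(seed, xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "binary:logistic",
                                   max_depth = 3L, learning_rate = 0.1,
                                   tree_method = "exact",
                                   nthread = 1L, seed = seed),
      data = dtr, nrounds = 100L, verbose = 0L))
    prob <- stats::predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1L))
    ifelse(prob > 0.5, "preterm", "term")
  } else if (model_name == "SVM") {
    v <- stats::var(as.vector(xtr))
    gam <- if (is.finite(v) && v > 0) 1 / (p * v) else 1 / p
    fit <- .with_seed(seed, e1071::svm(x = xtr, y = ytr,
                                       kernel = "radial", cost = 1,
                                       gamma = gam, scale = FALSE))
    as.character(stats::predict(fit, xte))
  } else if (model_name == "1NN") {
    apply(xte, 1L, function(row) {
      d2 <- rowSums(sweep(xtr, 2L, row)^2)
      as.character(ytr[which.min(d2)])
    })
  } else {
    stop("unknown model: ", model_name)
  }
}

#' Confusion rates of a two-group prediction
#'
#' @param pred,truth vectors of \code{"preterm"}/\code{"term"} labels;
#'   preterm is the positive class.
#' @return list with tpr, tnr, fpr, fnr, n_pos, n_neg.
#' @export
confusionRates <- function(pred, truth) {
  pred <- .as_group_factor(pred); truth <- .as_group_factor(truth)
  n_pos <- sum(truth == "preterm"); n_neg <- sum(truth == "term")
  if (n_pos == 0L || n_neg == 0L)
    stop("both groups must be present in the truth labels")
  tp <- sum(pred == "preterm" & truth == "preterm")
  tn <- sum(pred == "term" & truth == "term")
  list(tpr = tp / n_pos, tnr = tn / n_neg,
       fpr = (n_neg - tn) / n_neg, fnr = (n_pos - tp) / n_pos,
       n_pos = n_pos, n_neg = n_neg)
}

#' Accuracy, F1 and precision from confusion rates and class sizes
#'
#' Implements the identities linking per-class rates to the summary
#' metrics, with preterm as the positive class:
#' accuracy = (tpr n+ + tnr n-) / (n+ + n-);
#' precision = tpr n+ / (tpr n+ + fpr n-);
#' f1 = 2 precision tpr / (precision + tpr).
#'
#' @param tpr,tnr true positive/negative rates in [0, 1].
#' @param n_pos,n_neg class sizes (preterm, term), >= 1.
#' @param fpr,fnr false rates; default to the complements of
#'   \code{tnr}/\code{tpr} but may be given independently (e.g. when
#'   quoting rounded published rates).
#' @return list with accuracy, f1, precision.
#' @export
metricsFromRates <- function(tpr, tnr, n_pos, n_neg,
                             fpr = 1 - tnr, fnr = 1 - tpr) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  acc <- (tpr * n_pos + tnr * n_neg) / (n_pos + n_neg)
  denom <- tpr * n_pos + fpr * n_neg
  if (denom == 0) {
    warning("no positive predictions; F1 defined as 0")
    return(list(accuracy = acc, f1 = 0, precision = NA_real_))
  }
  prec <- tpr * n_pos / denom
  f1 <- if (prec + tpr == 0) 0 else 2 * prec * tpr / (prec + tpr)
  list(accuracy = acc, f1 = f1, precision = prec)
}

.metrics_row <- function(model_name, pred, truth, feature_mode, n_pcs) {
  r <- confusionRates(pred, truth)
  m <- metricsFromRates(r$tpr, r$tnr, r$n_pos, r$n_neg,
                        fpr = r$fpr, fnr = r$fnr)
  data.frame(model = model_name, feature_mode = feature_mode,
             n_pcs = if (is.null(n_pcs)) NA_integer_
                     else as.integer(n_pcs),
             accuracy = m$accuracy, f1 = m$f1,
             precision = m$precision,
             tpr = r$tpr, tnr = r$tnr, fpr = r$fpr, fnr = r$fnr,
             n_pos = r$n_pos, n_neg = r$n_neg)
}

#' Leave-one-out cross-validated classification
#'
#' For each sample i the model is trained on the other n-1 samples
#' (fold seed derived deterministically from \code{(seed, i)}) and
#' predicts sample i; confusion rates and metrics are computed from the
#' n held-out predictions.
#'
#' @param x numeric feature matrix, samples x features.
#' @param y labels (\code{"preterm"}/\code{"term"}), one per row.
#' @param model one of \code{"RF"}, \code{"GBM"}, \code{"SVM"} (or
#'   \code{"1NN"}, a stand-in used to validate the loop).
#' @param seed integer global seed.
#' @param feature_mode recorded in the metrics row (default "bins").
#' @param n_pcs recorded in the metrics row (default NA).
#' @return list with \code{predictions}, \code{rates} and a one-row
#'   \code{metrics} data.frame.
#' @export
loocv <- function(x, y, model = "RF", seed = 1L,
                  feature_mode = "bins", n_pcs = NULL) {
  x <- as.matrix(x)
  y <- .as_group_factor(y)
  n <- nrow(x)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  if (length(y) != n) stop("one label per sample is required")
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- .fit_predict(model, x[-i, , drop = FALSE], y[-i],
                            x[i, , drop = FALSE],
                            .fold_seed(seed, i))
  }
  list(predictions = pred, rates = confusionRates(pred, y),
       metrics = .metrics_row(model, pred, y, feature_mode, n_pcs))
}

# Per-fold PC score computation shared by loocvOnPCs and sweepPCCount.
# strict: Pareto scaling and PCA refit on each fold's n-1 training rows,
# the held-out row projected.  global: one fit on all rows.
.fold_pc_scores <- function(x, k, leakage) {
  n <- nrow(x)
  if (leakage == "global") {
    sc <- paretoScale(x)
    mod <- fitPCA(sc$x, k)
    lapply(seq_len(n), function(i) {
      list(train = mod@scores[-i, , drop = FALSE],
           test = mod@scores[i, , drop = FALSE])
    })
  } else {
    lapply(seq_len(n), function(i) {
      sc <- paretoScale(x[-i, , drop = FALSE])
      mod <- fitPCA(sc$x, k, center = sc$center, scale = sc$scale)
      list(train = mod@scores,
           test = projectSamples(mod, x[i, , drop = FALSE]))
    })
  }
}

#' LOOCV classification on leading principal components
#'
#' In the default \code{leakage = "strict"} mode, Pareto scaling and
#' PCA are refit inside every fold on the n-1 training rows and the
#' held-out sample is projected into that fold's space, so no
#' information from the held-out sample reaches the features.  The
#' \code{"global"} mode fits scaling and PCA once on all samples (the
#' conventional, slightly optimistic variant) and is retained for
#' comparability.
#'
#' @param x a \linkS4class{BinnedSpectra} or samples x bins matrix.
#' @param model,seed as in \code{\link{loocv}}.
#' @param k number of leading components, \code{<= n - 2}.
#' @param leakage \code{"strict"} or \code{"global"}.
#' @param labels group labels; default taken from \code{colData}.
#' @return as \code{\link{loocv}}.
#' @export
loocvOnPCs <- function(x, model = "RF", k = 3L, seed = 1L,
                       leakage = c("strict", "global"), labels = NULL) {
  leakage <- match.arg(leakage)
  if (is(x, "BinnedSpectra")) {
    if (is.null(labels)) labels <- sampleGroups(x)
    x <- binMatrix(x)
  }
  x <- as.matrix(x)
  y <- .as_group_factor(labels)
  n <- nrow(x)
  if (k > n - 2L)
    stop(sprintf("k must be <= n - 2 = %d (PCA inside an n-1 fold)", n - 2L))
  folds <- .fold_pc_scores(x, k, leakage)
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- .fit_predict(model, folds[[i]]$train, y[-i],
                            folds[[i]]$test, .fold_seed(seed, i))
  }
  list(predictions = pred, rates = confusionRates(pred, y),
       metrics = .metrics_row(model, pred, y, "pcs", k))
}

#' Sweep the number of principal components per classifier
#'
#' Runs \code{\link{loocvOnPCs}} for every (model, k) combination; per
#' fold, PC scores are computed once at the largest k and truncated
#' (singular vectors are nested, so this equals refitting at each k).
#' The best configuration maximizes accuracy; ties prefer the smaller
#' k, then the model order RF, GBM, SVM.
#'
#' @param x a \linkS4class{BinnedSpectra} or samples x bins matrix.
#' @param models classifier names to sweep.
#' @param k_range component counts (default 3:10).
#' @param seed,leakage,labels as in \code{\link{loocvOnPCs}}.
#' @return list with \code{table} (model, k, accuracy), \code{best_model}
#'   and \code{best_k}.
#' @export
sweepPCCount <- function(x, models = .MODELS, k_range = 3:10,
                         seed = 1L, leakage = c("strict", "global"),
                         labels = NULL) {
  leakage <- match.arg(leakage)
  if (is(x, "BinnedSpectra")) {
    if (is.null(labels)) labels <- sampleGroups(x)
    x <- binMatrix(x)
  }
  x <- as.matrix(x)
  y <- .as_group_factor(labels)
  n <- nrow(x)
  kmax <- max(k_range)
  if (kmax > n - 2L) stop("max(k_range) must be <= n - 2")
  folds <- .fold_pc_scores(x, kmax, leakage)
  grid <- expand.grid(model = models, k = sort(k_range),
                      stringsAsFactors = FALSE)
  grid$accuracy <- NA_real_
  for (r in seq_len(nrow(grid))) {
    k <- grid$k[r]
    pred <- character(n)
    for (i in seq_len(n)) {
      pred[i] <- .fit_predict(
        grid$model[r],
        folds[[i]]$train[, seq_len(k), drop = FALSE], y[-i],
        folds[[i]]$test[, seq_len(k), drop = FALSE],
        .fold_seed(seed, i))
    }
    grid$accuracy[r] <- mean(pred == as.character(y))
  }
  ord <- order(-grid$accuracy, grid$k,
               match(grid$model, .MODELS))
  list(table = grid, best_model = grid$model[ord[1L]],
       best_k = grid$k[ord[1L]])
}

#' Permutation importance of principal components under a random forest
#'
#' Fits a random forest on all samples' scores, then measures, for each
#' component, the mean drop in prediction accuracy when that score
#' column is shuffled (default 50 shuffles), clipped at zero, with the
#' Monte-Carlo sd of the drop.
#'
#' @param scores samples x k PC score matrix.
#' @param labels group labels.
#' @param seed integer seed (forest and shuffles).
#' @param n_shuffle shuffles per component.
#' @return data.frame with pc, importance, mc_sd.
#' @export
rfPCImportance <- function(scores, labels, seed = 1L, n_shuffle = 50L) {
  scores <- as.matrix(scores)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  y <- .as_group_factor(labels)
  .with_seed(seed, {
    fit <- randomForest::randomForest(
      x = scores, y = y, ntree = 500L,
      mtry = max(1L, floor(sqrt(ncol(scores)))))
    base <- mean(as.character(stats::predict(fit, scores)) ==
                   as.character(y))
    k <- ncol(scores)
    imp <- numeric(k); mc_sd <- numeric(k)
    for (j in seq_len(k)) {
      set.seed(.fold_seed(seed, j))
      drops <- vapply(seq_len(n_shuffle), function(s) {
        xp <- scores
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base - mean(as.character(stats::predict(fit, xp)) ==
                      as.character(y))
      }, numeric(1L))
      imp[j] <- max(mean(drops), 0)
      mc_sd[j] <- stats::sd(drops)
    }
    data.frame(pc = seq_len(k), importance = imp, mc_sd = mc_sd)
  })
}

#' Welch two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group mean, sample sd and size
#'   (n >= 2 each; the sds must not both be zero).
#' @return list with statistic, df and p.value.
#' @export
groupTTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0)
    stop("both group sds are zero; the t statistic is undefined")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test for a 2x2 frequency comparison
#'
#' Builds the success/failure table from per-group counts and applies
#' the Pearson chi-squared test without continuity correction.
#'
#' @param x1,n1 successes and size in group 1.
#' @param x2,n2 successes and size in group 2.
#' @return list with statistic, df and p.value.
#' @export
groupChisqTest <- function(x1, n1, x2, n2) {
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  if (any(tab < 0)) stop("counts must be non-negative")
  res <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}
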