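#' Mean-center and Pareto-scale a feature matrix
#'
#' Each column j is transformed to \code{(x - mean_j) / sqrt(sd_j)},
#' with the sample standard deviation (n-1 denominator).  Pareto
#' scaling sits between no scaling and unit-variance autoscaling,
#' damping the dominance of intense bins without blowing up noise
#' bins.  Columns with sd below 1e-12 are centered only and their scale
#' recorded as 1.
#'
#' @param x numeric matrix, samples x bins (>= 2 samples).
#' @return list with \code{x} (scaled matrix), \code{center} (column
#'   means) and \code{scale} (column divisors).
#' @export
paretoScale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("Pareto scaling needs at least 2 samples")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sds <- sqrt(colSums(xc^2) / (nrow(x) - 1L))
  scl <- ifelse(sds < 1e-12, 1, sqrt(sds))
  list(x = sweep(xc, 2L, scl, "/"), center = ctr, scale = scl)
}

#' Fit a PCA model
#'
#' Computes the top-k right singular vectors of the centered,
#' Pareto-scaled matrix.  Signs are fixed deterministically: each
#' loading's largest-magnitude entry is made positive, so reports and
#' loading thresholds are reproducible.  The explained-variance ratio
#' is relative to the total variance of the scaled matrix.
#'
#' @param x a \linkS4class{BinnedSpectra} (scaled internally) or a
#'   ready-scaled samples x bins matrix.
#' @param k number of components, \code{<= min(samples - 1, bins)}.
#' @param center,scale per-bin constants to record when \code{x} is a
#'   pre-scaled matrix (defaults: 0 and 1).
#' @param binCenters per-bin ppm centers to record for matrix input.
#' @return A \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, k, center = NULL, scale = NULL, binCenters = NULL) {
  if (is(x, "BinnedSpectra")) {
    sc <- paretoScale(binMatrix(x))
    return(fitPCA(sc$x, k, center = sc$center, scale = sc$scale,
                  binCenters = binCenters(x)))
  }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (k < 1L || k > min(n - 1L, p))
    stop(sprintf("k must be in 1..min(samples-1, bins) = %d", min(n - 1L, p)))
  sv <- svd(x)
  L <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  scores <- x %*% L
  total <- sum(sv$d^2)
  evr <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
  new("PCAModel",
      loadings = L, scores = scores, varExplained = evr,
      center = if (is.null(center)) numeric(p) else as.numeric(center),
      scale = if (is.null(scale)) rep(1, p) else as.numeric(scale),
      binCenters = if (is.null(binCenters)) rep(NA_real_, p)
                   else as.numeric(binCenters),
      sampleIds = if (is.null(rownames(x)))
        sprintf("S%03d", seq_len(n)) else rownames(x))
}

#' @rdname pcaAccessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' Accessors for PCA models
#'
#' @param object a \linkS4class{PCAModel}.
#' @return \code{pcaLoadings}: bins x k matrix; \code{pcaScores}:
#'   samples x k matrix; \code{varExplained}: per-component fraction of
#'   total variance.
#' @name pcaAccessors
#' @export
setMethod("pcaLoadings", "PCAModel", function(object) object@loadings)

#' @rdname pcaAccessors
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @rdname pcaAccessors
#' @export
setMethod("pcaScores", "PCAModel", function(object) object@scores)

#' @rdname pcaAccessors
#' @export
setGeneric("varExplained", function(object) standardGeneric("varExplained"))

#' @rdname pcaAccessors
#' @export
setMethod("varExplained", "PCAModel", function(object) object@varExplained)

#' Project new samples into a fitted PCA space
#'
#' With \code{scaled = FALSE} (default) the model's stored per-bin
#' means and Pareto divisors are applied first, so held-out samples are
#' projected without refitting — the leakage-free path used inside
#' cross-validation folds.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param newdata numeric matrix (or vector) of rows in bin space.
#' @param scaled set TRUE if \code{newdata} is already centered/scaled.
#' @return scores matrix, rows x k.
#' @export
projectSamples <- function(model, newdata, scaled = FALSE) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(model@loadings))
    stop(sprintf("newdata has %d columns but the model expects %d bins",
                 ncol(newdata), nrow(model@loadings)))
  if (!scaled)
    newdata <- sweep(sweep(newdata, 2L, model@center), 2L,
                     model@scale, "/")
  newdata %*% model@loadings
}

#' Flag potential outlier samples in PCA score space
#'
#' Reports (never removes) samples whose Mahalanobis distance over the
#' first \code{npcs} score dimensions exceeds the chi-squared quantile
#' at \code{level}.
#'
#' @param model a \linkS4class{PCAModel} with at least \code{npcs}
#'   components.
#' @param npcs number of leading components to use (default 3).
#' @param level chi-squared quantile (default 0.975).
#' @return data.frame with sample_id, distance-squared, cutoff and flag.
#' @export
flagOutliers <- function(model, npcs = 3L, level = 0.975) {
  if (ncol(model@scores) < npcs)
    stop("model has fewer than npcs components")
  s <- model@scores[, seq_len(npcs), drop = FALSE]
  # pseudo-inverse Mahalanobis so degenerate (rank-deficient) score
  # clouds are still rankable
  ctr <- sweep(s, 2L, colMeans(s))
  ev <- eigen(stats::cov(s), symmetric = TRUE)
  tol <- max(ev$values, 0) * 1e-10
  keep <- ev$values > tol
  if (!any(keep)) {
    d2 <- rep(0, nrow(s))
  } else {
    proj <- ctr %*% ev$vectors[, keep, drop = FALSE]
    d2 <- rowSums(sweep(proj^2, 2L, ev$values[keep], "/"))
  }
  cut <- stats::qchisq(level, df = npcs)
  data.frame(sample_id = model@sampleIds, dist2 = d2, cutoff = cut,
             outlier = d2 > cut)
}

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d samples, %d bins, %d components\n",
              nrow(object@scores), nrow(object@loadings),
              ncol(object@loadings)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varExplained), collapse = ", "),
      "\n")
  invisible(NULL)
})
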