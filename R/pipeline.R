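#' Pipeline configuration
#'
#' One flat configuration with namespaced sections; unknown keys are
#' rejected so typos cannot silently fall back to defaults.  The
#' configuration (and seed) is echoed verbatim into the report bundle.
#'
#' @param seed global integer seed.
#' @param synth arguments passed to \code{\link{cohortConfig}} when the
#'   pipeline simulates its input (ignored when \code{x} is supplied to
#'   \code{\link{runPipeline}}).
#' @param align list: \code{enabled} (default TRUE), \code{max_shift_ppm}.
#' @param bins arguments passed to \code{\link{binSpec}}.
#' @param pca list: \code{k} (components to fit/report, default 10).
#' @param classify list: \code{models}, \code{k_range}, \code{leakage}.
#' @param regions list: \code{thresholds}, \code{n_pcs}, \code{gap_tol_bins}.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, synth = list(), align = list(),
                           bins = list(), pca = list(),
                           classify = list(), regions = list()) {
  merge_ns <- function(user, defaults, ns) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L)
      stop(sprintf("unknown key(s) in '%s': %s", ns,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(defaults, user)
  }
  structure(list(
    seed = as.integer(seed),
    synth = synth,     # validated by cohortConfig at run time
    align = merge_ns(align, list(enabled = TRUE, max_shift_ppm = 0.02),
                     "align"),
    bins = merge_ns(bins, list(ppm_min = 0.5, ppm_max = 9.5,
                               bin_width = 0.0025,
                               excluded_regions = list(c(4.6, 5.2),
                                                       c(-0.5, 0.5))),
                    "bins"),
    pca = merge_ns(pca, list(k = 10L), "pca"),
    classify = merge_ns(classify,
                        list(models = c("RF", "GBM", "SVM"),
                             k_range = 3:10, leakage = "strict"),
                        "classify"),
    regions = merge_ns(regions,
                       list(thresholds = c(0.1, 0.05, 0.025, 0.02),
                            n_pcs = 3L, gap_tol_bins = 2L),
                       "regions")),
    class = "PipelineConfig")
}

#' Run the full chemometrics pipeline
#'
#' Orchestrates simulate (or use supplied spectra) -> align -> bin ->
#' total-area normalize -> Pareto-PCA -> LOOCV classification on scaled
#' bins and on swept principal components -> loading-threshold region
#' selection.  Fully deterministic under the configured seed; when
#' spectra are supplied the synthetic module is never touched.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param x optional \linkS4class{NMRExperiment} with a \code{group}
#'   column; when NULL a cohort is simulated from \code{config$synth}.
#' @return a report bundle: list with config, seed, version, per-stage
#'   dimensions, PCA summary and outlier flags, bin-mode metrics, the
#'   PC sweep, best-PC metrics, PC importances and the region ladder.
#' @export
runPipeline <- function(config = pipelineConfig(), x = NULL) {
  stages <- list()
  if (is.null(x)) {
    syn <- do.call(cohortConfig,
                   utils::modifyList(config$synth,
                                     list(seed = config$seed)))
    x <- simulateCohort(syn)
    stages$simulate <- dim(x)
  }
  if (is.null(sampleGroups(x)))
    stop("stage input: spectra carry no 'group' labels")
  y <- sampleGroups(x)
  if (isTRUE(config$align$enabled)) {
    x <- alignSpectra(x, max_shift_ppm = config$align$max_shift_ppm)
    stages$align <- dim(x)
  }
  spec <- do.call(binSpec, config$bins)
  b <- binSpectra(x, spec)
  stages$bin <- dim(b)
  b <- normalizeTotalArea(b)
  stages$normalize <- dim(b)

  pca <- fitPCA(b, k = min(config$pca$k, ncol(b) - 1L))
  outliers <- flagOutliers(pca, npcs = min(3L, ncol(pcaScores(pca))))

  sc <- paretoScale(binMatrix(b))
  metrics_bins <- do.call(rbind, lapply(config$classify$models,
    function(m) loocv(sc$x, y, model = m, seed = config$seed)$metrics))

  sweep <- sweepPCCount(b, models = config$classify$models,
                        k_range = config$classify$k_range,
                        seed = config$seed,
                        leakage = config$classify$leakage)
  best <- loocvOnPCs(b, model = sweep$best_model, k = sweep$best_k,
                     seed = config$seed,
                     leakage = config$classify$leakage)
  importance <- rfPCImportance(
    pcaScores(pca)[, seq_len(min(config$pca$k,
                                 ncol(pcaScores(pca)))), drop = FALSE],
    y, seed = config$seed)

  ladder <- runThresholdLadder(
    pca, thresholds = config$regions$thresholds,
    n_pcs = config$regions$n_pcs,
    gap_tol_bins = config$regions$gap_tol_bins,
    bin_edges = binEdges(b))

  list(config = config, seed = config$seed,
       version = as.character(utils::packageVersion("urineNMR")),
       stages = stages,
       pca = list(var_explained = varExplained(pca),
                  outliers = outliers),
       metrics = rbind(metrics_bins, best$metrics),
       sweep = sweep$table,
       best_model = sweep$best_model, best_k = sweep$best_k,
       importance = importance,
       ladder = ladder)
}

#' Participant flow-chart accounting
#'
#' Running subtraction of per-stage removals from an initial eligible
#' count.
#'
#' @param initial initial eligible count.
#' @param removals named non-negative counts removed at each stage, in
#'   order.
#' @return list with \code{table} (stage, removed, remaining) and
#'   \code{final}.
#' @examples
#' cohortFlow(128, c(deceased = 23, untraceable = 32,
#'                   excluded = 9, denied = 15))$final  # 49
#' @export
cohortFlow <- function(initial, removals = numeric(0)) {
  if (initial < 0) stop("initial count must be non-negative")
  if (any(removals < 0)) stop("removals must be non-negative")
  remaining <- initial - cumsum(c(0, removals))[-1L]
  if (length(removals) > 0L && any(remaining < 0)) {
    bad <- which(remaining < 0)[1L]
    stop(sprintf("removals exceed the running total at stage '%s'",
                 names(removals)[bad]))
  }
  tab <- data.frame(stage = if (length(removals)) names(removals)
                            else character(0),
                    removed = as.numeric(removals),
                    remaining = as.numeric(remaining))
  list(table = tab,
       final = if (length(removals)) unname(remaining[length(remaining)])
               else initial)
}
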