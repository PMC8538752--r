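#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.PPM_UNIFORM_RTOL <- 1e-9

.check_uniform_ascending <- function(ppm) {
  if (length(ppm) < 2L)
    return("ppm grid must contain at least 2 points")
  d <- diff(ppm)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    return(sprintf("ppm grid not strictly increasing at row %d (%.6g -> %.6g)",
                   i + 1L, ppm[i], ppm[i + 1L]))
  }
  step <- mean(d)
  if (any(abs(d - step) > .PPM_UNIFORM_RTOL * max(abs(step), 1))) {
    i <- which(abs(d - step) > .PPM_UNIFORM_RTOL * max(abs(step), 1))[1L]
    return(sprintf("ppm grid not uniform at row %d (step %.10g vs %.10g)",
                   i + 1L, d[i], step))
  }
  NULL
}

#' Container for a set of 1D NMR spectra on a shared ppm grid
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are grid points
#' (ascending ppm in \code{rowData(x)$ppm}), columns are samples.  The
#' single assay \code{"intensity"} holds non-negative intensities.
#' Sample metadata (e.g. the \code{group} label \code{"preterm"} /
#' \code{"term"}) lives in \code{colData}.
#'
#' @export
setClass("NMRExperiment", contains = "SummarizedExperiment")

setValidity("NMRExperiment", function(object) {
  rd <- rowData(object)
  if (!"ppm" %in% colnames(rd))
    return("rowData must contain a 'ppm' column")
  msg <- .check_uniform_ascending(rd$ppm)
  if (!is.null(msg)) return(msg)
  if (!"intensity" %in% assayNames(object))
    return("assay 'intensity' is required")
  a <- assay(object, "intensity")
  if (any(!is.finite(a)))
    return("intensities must be finite")
  if (any(a < 0))
    return("intensities must be non-negative")
  TRUE
})

#' Binned spectral feature matrix
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are retained ppm
#' bins (edges in \code{rowData}: \code{ppm_lo}, \code{ppm_hi},
#' \code{ppm_center}), columns are samples.  \code{metadata(x)$normalized}
#' records whether each sample (column) has been scaled to unit total
#' area; \code{metadata(x)$binSpec} stores the binning specification.
#'
#' @export
setClass("BinnedSpectra", contains = "SummarizedExperiment")

setValidity("BinnedSpectra", function(object) {
  rd <- rowData(object)
  need <- c("ppm_lo", "ppm_hi", "ppm_center")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (nrow(object) > 0) {
    if (any(rd$ppm_hi <= rd$ppm_lo))
      return("bin edges must satisfy ppm_lo < ppm_hi")
    if (is.unsorted(rd$ppm_lo, strictly = TRUE))
      return("bins must be in ascending ppm order")
  }
  if (!"bins" %in% assayNames(object))
    return("assay 'bins' is required")
  a <- assay(object, "bins")
  if (any(!is.finite(a)))
    return("bin values must be finite")
  norm <- metadata(object)$normalized
  if (is.null(norm) || !is.logical(norm) || length(norm) != 1L)
    return("metadata(x)$normalized must be a single logical")
  if (isTRUE(norm) && ncol(object) > 0) {
    s <- colSums(a)
    if (any(abs(s - 1) > 1e-8))
      return("normalized flag set but some sample totals differ from 1")
  }
  TRUE
})

#' Principal component model of a centered, Pareto-scaled bin matrix
#'
#' Slots hold the orthonormal loadings (bins x k), the sample scores
#' (samples x k), the per-component fraction of total variance, and the
#' per-bin centering/scaling constants needed to project new samples.
#'
#' @slot loadings numeric matrix, bins x k, orthonormal columns.
#' @slot scores numeric matrix, samples x k.
#' @slot varExplained numeric length k, non-increasing, sums to <= 1.
#' @slot center numeric per-bin means removed before the fit.
#' @slot scale numeric per-bin divisors (sqrt of the sample sd for
#'   Pareto scaling; 1 for near-constant bins).
#' @slot binCenters numeric per-bin ppm centers (for region selection).
#' @slot sampleIds character sample identifiers, one per score row.
#' @export
setClass("PCAModel",
  representation(loadings = "matrix", scores = "matrix",
                 varExplained = "numeric", center = "numeric",
                 scale = "numeric", binCenters = "numeric",
                 sampleIds = "character"))

setValidity("PCAModel", function(object) {
  L <- object@loadings
  k <- ncol(L)
  if (ncol(object@scores) != k)
    return("scores and loadings must have the same number of components")
  if (length(object@varExplained) != k)
    return("varExplained must have one entry per component")
  g <- crossprod(L)
  if (max(abs(g - diag(k))) > 1e-8)
    return("loadings columns must be orthonormal")
  if (is.unsorted(rev(object@varExplained)))
    return("varExplained must be non-increasing")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("varExplained must sum to at most 1")
  if (length(object@center) != nrow(L) || length(object@scale) != nrow(L))
    return("center/scale must have one entry per bin")
  if (length(object@binCenters) != nrow(L))
    return("binCenters must have one entry per bin")
  TRUE
})

#' Contiguous discriminating ppm regions selected at a loading threshold
#'
#' @slot threshold numeric loading-magnitude cutoff used.
#' @slot regions data.frame with columns \code{lo_ppm}, \code{hi_ppm},
#'   \code{pcs} (comma-joined contributing components) and
#'   \code{annotations} (comma-joined metabolite names, possibly "").
#' @slot nSelected integer count of bins at or above the threshold.
#' @slot perPC list of selected bin indices for each component alone.
#' @export
setClass("RegionSet",
  representation(threshold = "numeric", regions = "data.frame",
                 nSelected = "integer", perPC = "list"))

setValidity("RegionSet", function(object) {
  r <- object@regions
  need <- c("lo_ppm", "hi_ppm", "pcs", "annotations")
  if (!all(need %in% colnames(r)))
    return(paste("regions must contain columns", paste(need, collapse = ", ")))
  if (nrow(r) > 1) {
    if (is.unsorted(r$lo_ppm, strictly = TRUE))
      return("regions must be ascending in ppm")
    if (any(r$lo_ppm[-1L] < r$hi_ppm[-nrow(r)] - 1e-12))
      return("regions must be disjoint")
  }
  if (nrow(r) > 0 && any(r$hi_ppm <= r$lo_ppm))
    return("each region must have lo_ppm < hi_ppm")
  TRUE
})
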