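#' Default metabolite assignment table
#'
#' The ppm positions (acidified urine) of the four discriminating
#' metabolite signals handled by the package: citrate at 3.13,
#' creatinine CH2 at 4.28, fumarate at 6.8 and the hippurate aromatic
#' multiplet over 7.6-7.8 ppm.
#'
#' @return data.frame with metabolite, lo_ppm, hi_ppm (points have
#'   lo = hi).
#' @export
defaultAssignmentTable <- function() {
  data.frame(
    metabolite = c("citrate", "creatinine_ch2", "fumarate", "hippurate"),
    lo_ppm = c(3.13, 4.28, 6.8, 7.6),
    hi_ppm = c(3.13, 4.28, 6.8, 7.8))
}

#' Select bins whose loading magnitude reaches a threshold
#'
#' A bin is selected when the maximum absolute loading over the first
#' \code{n_pcs} components is at least \code{threshold}.  Selections
#' are nested: a higher threshold always yields a subset.
#'
#' @param model a \linkS4class{PCAModel} with at least \code{n_pcs}
#'   components.
#' @param threshold positive loading-magnitude cutoff.
#' @param n_pcs number of leading components (default 3).
#' @return sorted integer bin indices.
#' @export
thresholdLoadings <- function(model, threshold, n_pcs = 3L) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (n_pcs > ncol(model@loadings))
    stop("n_pcs exceeds the number of fitted components")
  L <- abs(model@loadings[, seq_len(n_pcs), drop = FALSE])
  which(apply(L, 1L, max) >= threshold)
}

#' Merge selected bins into contiguous ppm ranges
#'
#' Runs of selected bins are merged, allowing up to
#' \code{gap_tol_bins} unselected bins between them; gaps wider than
#' that in ppm (in particular the excluded water region) are never
#' bridged.  Each range spans from the lo edge of its first bin to the
#' hi edge of its last.
#'
#' @param selected sorted unique bin indices.
#' @param edges bins x 2 matrix of (lo, hi) ppm edges for all retained
#'   bins.
#' @param gap_tol_bins maximum bridged gap, in bins (default 2).
#' @return data.frame with lo_ppm, hi_ppm, n_bins and the member
#'   indices as a list column.
#' @export
mergeBinsToRanges <- function(selected, edges, gap_tol_bins = 2L) {
  if (length(selected) == 0L)
    return(data.frame(lo_ppm = numeric(0), hi_ppm = numeric(0),
                      n_bins = integer(0)))
  selected <- sort(unique(as.integer(selected)))
  lo <- edges[, 1L]; hi <- edges[, 2L]
  w <- stats::median(hi - lo)
  tol <- 1e-9
  start <- selected[1L]; prev <- selected[1L]
  runs <- list()
  members <- list(); cur <- selected[1L]
  for (idx in selected[-1L]) {
    # bridge only if the ppm gap between runs is <= gap_tol bins wide
    if (lo[idx] - hi[prev] <= gap_tol_bins * w + tol) {
      prev <- idx
      cur <- c(cur, idx)
    } else {
      runs[[length(runs) + 1L]] <- c(start, prev)
      members[[length(members) + 1L]] <- cur
      start <- idx; prev <- idx; cur <- idx
    }
  }
  runs[[length(runs) + 1L]] <- c(start, prev)
  members[[length(members) + 1L]] <- cur
  out <- data.frame(
    lo_ppm = vapply(runs, function(r) lo[r[1L]], numeric(1L)),
    hi_ppm = vapply(runs, function(r) hi[r[2L]], numeric(1L)),
    n_bins = lengths(members))
  out$bins <- members
  out
}

#' Annotate ppm ranges with metabolite assignments
#'
#' A metabolite annotates a range when its assignment point lies inside
#' it or its assignment interval overlaps it (closed intervals).
#'
#' @param ranges data.frame with lo_ppm, hi_ppm columns.
#' @param table assignment table (see
#'   \code{\link{defaultAssignmentTable}}).
#' @return character vector, one comma-joined annotation string per
#'   range ("" when none).
#' @export
annotateRanges <- function(ranges, table = defaultAssignmentTable()) {
  vapply(seq_len(nrow(ranges)), function(i) {
    hit <- table$lo_ppm <= ranges$hi_ppm[i] &
      table$hi_ppm >= ranges$lo_ppm[i]
    paste(table$metabolite[hit], collapse = ",")
  }, character(1L))
}

#' Run the loading-threshold ladder
#'
#' Applies \code{\link{thresholdLoadings}} at each threshold (reported
#' in descending order), merges selected bins into contiguous ranges
#' and annotates them.  Per-component selections are retained in each
#' result for traceability.
#'
#' @param model a \linkS4class{PCAModel} fitted on a
#'   \linkS4class{BinnedSpectra} (so bin centers are recorded).
#' @param thresholds loading cutoffs (default 0.1, 0.05, 0.025, 0.02).
#' @param n_pcs leading components to aggregate over (default 3).
#' @param gap_tol_bins gap tolerance for merging (default 2).
#' @param assignments metabolite assignment table.
#' @param bin_edges optional bins x 2 edge matrix; reconstructed from
#'   the model's bin centers when omitted.
#' @return named list of \linkS4class{RegionSet}, one per threshold.
#' @export
runThresholdLadder <- function(model,
                               thresholds = c(0.1, 0.05, 0.025, 0.02),
                               n_pcs = 3L, gap_tol_bins = 2L,
                               assignments = defaultAssignmentTable(),
                               bin_edges = NULL) {
  if (is.null(bin_edges)) {
    ctr <- model@binCenters
    if (anyNA(ctr))
      stop("model records no bin centers; supply bin_edges")
    w <- stats::median(diff(ctr))
    bin_edges <- cbind(ctr - w / 2, ctr + w / 2)
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- lapply(thresholds, function(th) {
    sel <- thresholdLoadings(model, th, n_pcs)
    ranges <- mergeBinsToRanges(sel, bin_edges, gap_tol_bins)
    ann <- annotateRanges(ranges, assignments)
    per_pc <- lapply(seq_len(n_pcs), function(j)
      which(abs(model@loadings[, j]) >= th))
    names(per_pc) <- sprintf("PC%d", seq_len(n_pcs))
    pcs <- vapply(seq_len(nrow(ranges)), function(i) {
      inpc <- vapply(per_pc, function(s)
        any(s %in% ranges$bins[[i]]), logical(1L))
      paste(which(inpc), collapse = ",")
    }, character(1L))
    reg <- data.frame(lo_ppm = ranges$lo_ppm, hi_ppm = ranges$hi_ppm,
                      pcs = pcs, annotations = ann)
    new("RegionSet", threshold = th, regions = reg,
        nSelected = length(sel), perPC = per_pc)
  })
  names(out) <- sprintf("t%g", thresholds)
  out
}

#' @rdname regionAccessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' Accessors for region sets
#'
#' @param object a \linkS4class{RegionSet}.
#' @return \code{regions}: the per-range data.frame;
#'   \code{regionThreshold}: the loading cutoff used.
#' @name regionAccessors
#' @export
setMethod("regions", "RegionSet", function(object) object@regions)

#' @rdname regionAccessors
#' @export
setGeneric("regionThreshold",
           function(object) standardGeneric("regionThreshold"))

#' @rdname regionAccessors
#' @export
setMethod("regionThreshold", "RegionSet",
          function(object) object@threshold)

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: threshold %g, %d selected bins, %d region(s)\n",
              object@threshold, object@nSelected, nrow(object@regions)))
  if (nrow(object@regions) > 0) {
    r <- object@regions
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %.4f-%.4f ppm  [PC %s]  %s\n", r$lo_ppm[i],
                  r$hi_ppm[i], r$pcs[i],
                  ifelse(nzchar(r$annotations[i]), r$annotations[i], "-")))
  }
  invisible(NULL)
})
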