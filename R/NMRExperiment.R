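#' Construct an NMRExperiment from an intensity matrix and ppm grid
#'
#' @param intensity numeric matrix, grid points x samples, non-negative.
#' @param ppm numeric strictly increasing uniform grid, one value per row.
#' @param sampleData optional data.frame/DataFrame of per-sample metadata
#'   (e.g. a \code{group} column); rownames or a \code{sample_id} column
#'   supply sample identifiers.
#' @return An \linkS4class{NMRExperiment}.
#' @examples
#' ppm <- seq(0.5, 9.5, length.out = 101)
#' m <- matrix(1, 101, 2, dimnames = list(NULL, c("a", "b")))
#' NMRExperiment(m, ppm)
#' @export
NMRExperiment <- function(intensity, ppm, sampleData = NULL) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(ppm))
    stop("nrow(intensity) must equal length(ppm)")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("S%03d", seq_len(ncol(intensity)))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(intensity))
  } else {
    cd <- DataFrame(sampleData)
    if ("sample_id" %in% colnames(cd) && is.null(rownames(sampleData)))
      rownames(cd) <- cd$sample_id
    if (is.null(rownames(cd)))
      rownames(cd) <- colnames(intensity)
    cd
  }
  rownames(intensity) <- NULL
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(ppm = as.numeric(ppm)),
    colData = cd)
  new("NMRExperiment", se)
}

#' @rdname ppmGrid
#' @export
setGeneric("ppmGrid", function(x) standardGeneric("ppmGrid"))

#' Accessors for NMR containers
#'
#' \code{ppmGrid} returns the shared ascending ppm grid;
#' \code{spectraMatrix} the grid-points x samples intensity matrix;
#' \code{sampleGroups} the per-sample group factor (or NULL).
#'
#' @param x an \linkS4class{NMRExperiment}.
#' @return \code{ppmGrid}: numeric vector; \code{spectraMatrix}: matrix;
#'   \code{sampleGroups}: factor or NULL.
#' @name ppmGrid
#' @aliases ppmGrid,NMRExperiment-method
#' @export
setMethod("ppmGrid", "NMRExperiment", function(x) rowData(x)$ppm)

#' @rdname ppmGrid
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname ppmGrid
#' @export
setMethod("spectraMatrix", "NMRExperiment",
          function(x) assay(x, "intensity"))

#' @rdname ppmGrid
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

.groups_from_coldata <- function(x) {
  g <- colData(x)$group
  if (is.null(g)) return(NULL)
  factor(as.character(g), levels = c("preterm", "term"))
}

#' @rdname ppmGrid
#' @export
setMethod("sampleGroups", "NMRExperiment", .groups_from_coldata)

#' @rdname ppmGrid
#' @export
setMethod("sampleGroups", "BinnedSpectra", .groups_from_coldata)

setMethod("show", "NMRExperiment", function(object) {
  ppm <- ppmGrid(object)
  cat(sprintf("NMRExperiment: %d samples, %d grid points, %.4g-%.4g ppm (step %.3g)\n",
              ncol(object), nrow(object), min(ppm), max(ppm),
              mean(diff(ppm))))
  g <- sampleGroups(object)
  if (!is.null(g))
    cat("  groups:", paste(sprintf("%s=%d", levels(g), table(g)),
                           collapse = ", "), "\n")
  invisible(NULL)
})
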