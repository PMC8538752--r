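## File readers/writers.  All other modules consume NMRExperiment /
## BinnedSpectra objects only; no other module touches files.

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a spectra matrix from delimited text
#'
#' Expects a header line, a first column named \code{ppm} and one column
#' per sample.  Tab or comma delimiters are autodetected from the
#' header.  The ppm column must be strictly monotone and uniform; a
#' descending grid (the NMR plotting convention) is reversed to the
#' package's ascending orientation, intensities in lockstep.
#'
#' @param path file path.
#' @return An \linkS4class{NMRExperiment} (no sample metadata).
#' @export
readSpectraMatrix <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "numeric",
                          fill = FALSE)
  if (tolower(colnames(df)[1]) != "ppm")
    stop("first column must be named 'ppm'")
  if (ncol(df) < 2L) stop("no sample columns found")
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1L]
    stop(sprintf("missing value in data row %d; missing intensities are not allowed", bad))
  }
  ppm <- df[[1L]]
  m <- as.matrix(df[-1L])
  d <- diff(ppm)
  if (any(d == 0))
    stop(sprintf("duplicated ppm value at row %d",
                 which(d == 0)[1L] + 1L))
  if (all(d < 0)) {          # descending file: normalize to ascending
    ppm <- rev(ppm)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  msg <- .check_uniform_ascending(ppm)
  if (!is.null(msg)) stop(msg)
  NMRExperiment(m, ppm)
}

#' Write a spectra matrix as tab-delimited text
#'
#' The ppm column is printed with full double precision (so re-reading
#' preserves grid uniformity exactly); intensities at 9 significant
#' digits.
#'
#' @param x an \linkS4class{NMRExperiment}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSpectraMatrix <- function(x, path) {
  m <- spectraMatrix(x)
  lines <- c(paste(c("ppm", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(sprintf("%.17g", ppmGrid(x)[i]),
                       sprintf("%.9g", m[i, ])), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 1D JCAMP-DX spectrum
#'
#' Supports AFFN (plain numeric) \code{##XYDATA=(X++(Y..Y))} tables.
#' The ppm grid is reconstructed from \code{##FIRSTX}, \code{##LASTX}
#' and \code{##NPOINTS}; intensities are scaled by \code{##YFACTOR}.
#' Descending grids (the usual NMR convention) are reversed to
#' ascending with intensities in lockstep.
#'
#' @param path file path.
#' @param sample_id identifier for the returned sample; defaults to the
#'   \code{##TITLE} record (or the file name).
#' @return A one-sample \linkS4class{NMRExperiment}.
#' @export
readJCAMPDX <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lbl <- grepl("^##", lines)
  recs <- lines[lbl]
  get_rec <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), recs, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  required <- c("FIRSTX", "LASTX", "NPOINTS")
  missing <- required[vapply(required, function(r) is.null(get_rec(r)),
                             logical(1L))]
  xy_at <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (length(xy_at) == 0L) missing <- c(missing, "XYDATA")
  if (length(missing) > 0L)
    stop("missing required JCAMP-DX records: ",
         paste(missing, collapse = ", "))
  firstx <- as.numeric(get_rec("FIRSTX"))
  lastx <- as.numeric(get_rec("LASTX"))
  npoints <- as.integer(as.numeric(get_rec("NPOINTS")))
  yfactor <- get_rec("YFACTOR")
  yfactor <- if (is.null(yfactor)) 1 else as.numeric(yfactor)
  if (npoints < 2L) stop("NPOINTS must be >= 2")

  end_at <- grep("^##END\\s*=", lines, ignore.case = TRUE)
  end_at <- end_at[end_at > xy_at[1L]]
  stop_at <- if (length(end_at)) end_at[1L] - 1L else length(lines)
  body <- lines[seq(xy_at[1L] + 1L, stop_at)]
  body <- body[!grepl("^##", body)]
  y <- unlist(lapply(strsplit(trimws(body), "[\\s,]+", perl = TRUE),
                     function(tok) {
                       v <- suppressWarnings(as.numeric(tok))
                       if (anyNA(v)) stop("non-numeric token in XYDATA; only AFFN data are supported")
                       v[-1L]     # first token per line is the X value
                     }))
  if (length(y) != npoints)
    stop(sprintf("XYDATA contains %d Y values but NPOINTS=%d",
                 length(y), npoints))
  ppm <- seq(firstx, lastx, length.out = npoints)
  inten <- y * yfactor
  if (firstx > lastx) {       # descending: normalize
    ppm <- rev(ppm)
    inten <- rev(inten)
  }
  if (is.null(sample_id)) {
    sample_id <- get_rec("TITLE")
    if (is.null(sample_id) || !nzchar(sample_id))
      sample_id <- basename(path)
  }
  m <- matrix(inten, ncol = 1L, dimnames = list(NULL, sample_id))
  NMRExperiment(m, ppm)
}

#' Read a sample-metadata table
#'
#' Delimited text with at least \code{sample_id} and \code{group}
#' columns; values are whitespace-trimmed and group labels must be
#' \code{preterm} or \code{term}.
#'
#' @param path file path.
#' @return data.frame with character \code{sample_id} and factor
#'   \code{group}, plus any extra covariate columns.
#' @export
readSampleTable <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  colnames(df) <- trimws(colnames(df))
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("sample table must contain 'sample_id' and 'group' columns")
  df$sample_id <- trimws(df$sample_id)
  df$group <- trimws(df$group)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$group), c("preterm", "term"))
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = c("preterm", "term"))
  df
}

#' Attach sample metadata to a spectra container
#'
#' Joins a sample table onto an \linkS4class{NMRExperiment} by
#' \code{sample_id}; every spectrum must have exactly one row and vice
#' versa.
#'
#' @param x an \linkS4class{NMRExperiment}.
#' @param table data.frame from \code{\link{readSampleTable}}.
#' @return \code{x} with populated \code{colData}.
#' @export
attachSampleTable <- function(x, table) {
  ids <- colnames(x)
  orphan_spec <- setdiff(ids, table$sample_id)
  orphan_meta <- setdiff(table$sample_id, ids)
  if (length(orphan_spec) || length(orphan_meta))
    stop("spectra/metadata mismatch; spectra without metadata: [",
         paste(orphan_spec, collapse = ", "),
         "]; metadata without spectra: [",
         paste(orphan_meta, collapse = ", "), "]")
  rows <- match(ids, table$sample_id)
  cd <- DataFrame(table[rows, , drop = FALSE])
  rownames(cd) <- ids
  colData(x) <- cd
  x
}

#' Write a pipeline report
#'
#' Emits a machine-readable JSON file and, when the results contain
#' classifier metrics, a tab-delimited metrics table with the columns
#' Accuracy, F1, FPR, FNR, TPR and TNR (one row per model).
#'
#' @param results named list (e.g. the bundle from
#'   \code{\link{runPipeline}}, or any list with a \code{metrics}
#'   data.frame component).
#' @param path_json JSON output path.
#' @param path_tsv optional metrics TSV output path.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(results, path_json, path_tsv = NULL) {
  ser <- .jsonable(results)
  jsonlite::write_json(ser, path_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- path_json
  if (!is.null(path_tsv)) {
    met <- results$metrics
    if (is.null(met))
      stop("results contain no 'metrics' table to write")
    out <- data.frame(Model = met$model,
                      Accuracy = round(met$accuracy, 2),
                      F1 = round(met$f1, 2),
                      FPR = round(met$fpr, 2), FNR = round(met$fnr, 2),
                      TPR = round(met$tpr, 2), TNR = round(met$tnr, 2))
    utils::write.table(out, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, path_tsv)
  }
  invisible(written)
}

# strip S4/complex objects down to JSON-representable pieces
.jsonable <- function(x) {
  if (is(x, "RegionSet")) {
    return(list(threshold = x@threshold, n_selected = x@nSelected,
                regions = x@regions))
  }
  if (is(x, "PCAModel"))
    return(list(k = ncol(x@loadings), var_explained = x@varExplained))
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .jsonable))
  x
}
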