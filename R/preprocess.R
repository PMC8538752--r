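#' Uniform binning specification
#'
#' Defaults implement the standard urine protocol: 0.0025-ppm bins on
#' 0.5-9.5 ppm, excluding the water (4.6-5.2 ppm) and TSP reference
#' (-0.5-0.5 ppm) regions.  The TSP region lies entirely outside the
#' binned range, so with defaults exactly 3360 of the 3600 bins are
#' retained.
#'
#' @param ppm_min,ppm_max binned range (ppm); the span must be an
#'   integer multiple of \code{bin_width}.
#' @param bin_width bin width (ppm).
#' @param excluded_regions list of \code{c(lo, hi)} ppm intervals; any
#'   bin overlapping one is dropped.  Regions are clipped to the binned
#'   range.
#' @return A list of class \code{"BinSpec"} with precomputed bin edges
#'   and the retained-bin mask.
#' @export
binSpec <- function(ppm_min = 0.5, ppm_max = 9.5, bin_width = 0.0025,
                    excluded_regions = list(c(4.6, 5.2), c(-0.5, 0.5))) {
  if (ppm_max <= ppm_min) stop("ppm_max must exceed ppm_min")
  if (bin_width <= 0) stop("bin_width must be > 0")
  span <- ppm_max - ppm_min
  k <- round(span / bin_width)
  if (abs(k * bin_width - span) > 1e-9)
    stop("(ppm_max - ppm_min) must be an integer multiple of bin_width")
  lo <- ppm_min + (seq_len(k) - 1L) * bin_width
  hi <- ppm_min + seq_len(k) * bin_width
  keep <- rep(TRUE, k)
  excl <- lapply(excluded_regions, function(r) {
    r <- sort(as.numeric(r[1:2]))
    c(max(r[1], ppm_min), min(r[2], ppm_max))
  })
  excl <- Filter(function(r) r[2] > r[1], excl)
  tol <- 1e-9
  for (r in excl)
    keep <- keep & !(lo < r[2] - tol & hi > r[1] + tol)
  structure(list(ppm_min = ppm_min, ppm_max = ppm_max,
                 bin_width = bin_width, excluded_regions = excl,
                 lo = lo, hi = hi, keep = keep),
            class = "BinSpec")
}

.shift_vector <- function(x, t) {
  n <- length(x)
  if (t == 0L) return(x)
  if (t > 0L) c(rep(x[1L], t), x[seq_len(n - t)])
  else c(x[seq.int(1L - t, n)], rep(x[n], -t))
}

#' Align spectra by rigid shift against the median spectrum
#'
#' Each spectrum is shifted by an integer number of grid steps, chosen
#' to maximize its cross-correlation with the pointwise-median reference
#' spectrum within \code{+/- max_shift_ppm}; vacated edge points are
#' filled with the edge value.  Ties prefer the smaller absolute shift.
#' A warning is issued when a sample's best shift sits on the search
#' window edge (the true displacement may exceed the window).
#'
#' @param x an \linkS4class{NMRExperiment}.
#' @param max_shift_ppm half-width of the shift search window (ppm);
#'   must be below 10 percent of the grid span.
#' @return \code{x} with aligned intensities and the applied correction
#'   (ppm) in \code{colData(x)$shift_ppm}.
#' @export
alignSpectra <- function(x, max_shift_ppm = 0.02) {
  ppm <- ppmGrid(x)
  step <- mean(diff(ppm))
  span <- ppm[length(ppm)] - ppm[1L]
  if (max_shift_ppm < 0) stop("max_shift_ppm must be >= 0")
  if (max_shift_ppm > 0.1 * span)
    stop("max_shift_ppm exceeds 10% of the grid span")
  S <- as.integer(floor(max_shift_ppm / step + 1e-9))
  m <- spectraMatrix(x)
  ref <- apply(m, 1L, stats::median)
  shifts <- integer(ncol(m))
  out <- m
  if (S > 0L) {
    # FFT cross-correlation against the zero-padded reference:
    # score(t) = sum_i x[i - t] * ref[i]; ties prefer the smaller |t|
    n <- nrow(m)
    mfft <- stats::nextn(n + 2L * S)   # smooth length for the FFT
    rp <- c(ref, numeric(mfft - n))
    Fr <- stats::fft(rp)
    cand <- seq.int(-S, S)
    cand <- cand[order(abs(cand), cand)]
    idx <- ifelse(cand >= 0L, cand + 1L, mfft + cand + 1L)
    for (j in seq_len(ncol(m))) {
      xp <- c(m[, j], numeric(mfft - n))
      cc <- Re(stats::fft(Conj(stats::fft(xp)) * Fr,
                          inverse = TRUE)) / mfft
      sc <- cc[idx]
      best_t <- cand[which.max(sc > max(sc) - 1e-9 * max(abs(sc), 1))]
      if (abs(best_t) == S)
        warning(sprintf("sample '%s': best shift at the search-window edge (%+d steps)",
                        colnames(m)[j], best_t))
      shifts[j] <- best_t
      out[, j] <- .shift_vector(m[, j], best_t)
    }
  }
  assay(x, "intensity") <- out
  colData(x)$shift_ppm <- shifts * step
  x
}

# cumulative trapezoid integral, one column per sample
.cumtrapz <- function(ppm, m) {
  mids <- (m[-1L, , drop = FALSE] + m[-nrow(m), , drop = FALSE]) / 2 *
    diff(ppm)
  rbind(0, apply(mids, 2L, cumsum))
}

#' Bin spectra into a uniform feature matrix
#'
#' Each retained bin \code{[lo, hi)} gets the trapezoidal integral of
#' the intensity over the bin divided by the bin width (i.e. the mean
#' intensity), which is invariant to grid oversampling.  Bins
#' overlapping an excluded region are dropped.
#'
#' @param x an \linkS4class{NMRExperiment} whose grid covers the binned
#'   range.
#' @param spec a \code{\link{binSpec}}.
#' @return A \linkS4class{BinnedSpectra} (not yet normalized).
#' @export
binSpectra <- function(x, spec = binSpec()) {
  ppm <- ppmGrid(x)
  if (ppm[1L] > spec$ppm_min + 1e-9 ||
      ppm[length(ppm)] < spec$ppm_max - 1e-9)
    stop(sprintf("spectrum grid [%.4g, %.4g] does not cover the bin range [%.4g, %.4g]",
                 ppm[1L], ppm[length(ppm)], spec$ppm_min, spec$ppm_max))
  m <- spectraMatrix(x)
  C <- .cumtrapz(ppm, m)
  edges <- c(spec$lo, spec$hi[length(spec$hi)])
  Cedge <- apply(C, 2L, function(col)
    stats::approx(ppm, col, xout = edges, rule = 2)$y)
  vals <- (Cedge[-1L, , drop = FALSE] - Cedge[-nrow(Cedge), , drop = FALSE]) /
    spec$bin_width
  vals <- vals[spec$keep, , drop = FALSE]
  rd <- DataFrame(ppm_lo = spec$lo[spec$keep], ppm_hi = spec$hi[spec$keep],
                  ppm_center = (spec$lo[spec$keep] + spec$hi[spec$keep]) / 2)
  se <- SummarizedExperiment(assays = list(bins = vals), rowData = rd,
                             colData = colData(x))
  metadata(se)$normalized <- FALSE
  metadata(se)$binSpec <- spec
  new("BinnedSpectra", se)
}

#' Total-area normalization of a binned matrix
#'
#' Divides each sample's bins by their own total, cancelling per-sample
#' dilution differences.  The total is taken over the retained
#' (post-exclusion) bins, so the excluded water region cannot dominate
#' the denominator.
#'
#' @param x a \linkS4class{BinnedSpectra} with the normalized flag
#'   unset; every sample must have a positive total.
#' @return \code{x} with unit-total samples and the flag set.
#' @export
normalizeTotalArea <- function(x) {
  if (isTRUE(metadata(x)$normalized))
    stop("matrix is already normalized")
  a <- assay(x, "bins")
  s <- colSums(a)
  if (any(s <= 0))
    stop("non-positive total spectral area for sample(s): ",
         paste(colnames(x)[s <= 0], collapse = ", "))
  assay(x, "bins") <- sweep(a, 2L, s, "/")
  metadata(x)$normalized <- TRUE
  x
}

#' @rdname binAccessors
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))

#' Accessors for binned spectra
#'
#' \code{binMatrix} returns the samples x bins feature matrix (the
#' transposed assay, matching the orientation statistical models use);
#' \code{binEdges} the per-bin \code{(lo, hi)} edges; \code{binCenters}
#' the bin-center ppm values; \code{isNormalized} the total-area flag.
#'
#' @param x a \linkS4class{BinnedSpectra}.
#' @name binAccessors
#' @export
setMethod("binMatrix", "BinnedSpectra", function(x) t(assay(x, "bins")))

#' @rdname binAccessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname binAccessors
#' @export
setMethod("binEdges", "BinnedSpectra", function(x)
  cbind(lo = rowData(x)$ppm_lo, hi = rowData(x)$ppm_hi))

#' @rdname binAccessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binAccessors
#' @export
setMethod("binCenters", "BinnedSpectra", function(x) rowData(x)$ppm_center)

#' @rdname binAccessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname binAccessors
#' @export
setMethod("isNormalized", "BinnedSpectra", function(x)
  isTRUE(metadata(x)$normalized))

setMethod("show", "BinnedSpectra", function(object) {
  cat(sprintf("BinnedSpectra: %d samples x %d retained bins (width %.4g ppm)%s\n",
              ncol(object), nrow(object),
              metadata(object)$binSpec$bin_width,
              if (isNormalized(object)) ", total-area normalized" else ""))
  invisible(NULL)
})
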