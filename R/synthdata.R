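#' Describe one metabolite's NMR signal as a Lorentzian multiplet
#'
#' A peak is a set of Lorentzian lines sharing a linewidth: line j sits
#' at \code{center_ppm + line_offsets_ppm[j]} with peak height
#' proportional to \code{relative_amplitudes[j]}.
#'
#' @param name metabolite name.
#' @param center_ppm multiplet center (ppm).
#' @param relative_amplitudes per-line positive weights.
#' @param line_offsets_ppm per-line offsets from the center (ppm).
#' @param linewidth_ppm Lorentzian half-width at half-maximum (ppm).
#' @return A list of class \code{"MetabolitePeak"}.
#' @export
metabolitePeak <- function(name, center_ppm, relative_amplitudes = 1,
                           line_offsets_ppm = 0, linewidth_ppm = 0.002) {
  stopifnot(length(relative_amplitudes) == length(line_offsets_ppm))
  if (linewidth_ppm <= 0) stop("linewidth_ppm must be > 0")
  if (any(relative_amplitudes <= 0))
    stop("relative_amplitudes must all be > 0")
  pos <- center_ppm + line_offsets_ppm
  if (any(pos < 0.5 | pos > 9.5))
    stop(sprintf("lines of '%s' fall outside 0.5-9.5 ppm", name))
  structure(list(name = name, center_ppm = center_ppm,
                 relative_amplitudes = as.numeric(relative_amplitudes),
                 line_offsets_ppm = as.numeric(line_offsets_ppm),
                 linewidth_ppm = linewidth_ppm),
            class = "MetabolitePeak")
}

#' Default urinary metabolite library
#'
#' Positions for the four discriminating metabolites follow the acidified
#' (pH 1) urine assignments used throughout the package: citrate at
#' 3.13 ppm (AB system), creatinine CH2 at 4.28 ppm, fumarate at 6.8 ppm
#' and the hippurate aromatic multiplet spanning 7.6-7.8 ppm.  A
#' creatinine CH3 singlet is placed at the conventional 3.05 ppm (an
#' assumption: no acid-shifted position is tabulated here).  Six
#' non-discriminating background metabolites elsewhere in 0.5-9.5 ppm
#' make region selection non-trivial.
#'
#' @return A named list of \code{MetabolitePeak} objects.
#' @export
defaultMetaboliteLibrary <- function() {
  peaks <- list(
    metabolitePeak("citrate", 3.13,
                   relative_amplitudes = c(1, 1.4, 1.4, 1),
                   line_offsets_ppm = c(-0.021, -0.008, 0.008, 0.021)),
    metabolitePeak("creatinine_ch2", 4.28),
    metabolitePeak("creatinine_ch3", 3.05, relative_amplitudes = 1.5),
    metabolitePeak("fumarate", 6.8),
    metabolitePeak("hippurate", 7.7,
                   relative_amplitudes = c(2, 1, 2, 1, 2),
                   line_offsets_ppm = c(-0.09, -0.045, 0, 0.045, 0.09)),
    # background (non-discriminating) signals
    metabolitePeak("lactate", 1.33, relative_amplitudes = c(1, 1),
                   line_offsets_ppm = c(-0.006, 0.006)),
    metabolitePeak("alanine", 1.48, relative_amplitudes = c(1, 1),
                   line_offsets_ppm = c(-0.006, 0.006)),
    metabolitePeak("dimethylamine", 2.72),
    metabolitePeak("taurine", 3.27),
    metabolitePeak("glycine", 3.57),
    metabolitePeak("formate", 8.46))
  names(peaks) <- vapply(peaks, `[[`, "", "name")
  peaks
}

#' Configuration of a synthetic preterm/term urine NMR cohort
#'
#' Defaults emulate the study conditions the package targets: 49 preterm
#' and 18 term samples, a 1.5-fold preterm increase in citrate,
#' creatinine CH2, fumarate and hippurate, per-sample chemical-shift
#' jitter of sd 0.005 ppm (the pH effect), dilution factors drawn from
#' (0.7, 1.3), additive Gaussian noise of sd 0.02 intensity units, and a
#' 36,001-point grid on 0.5-9.5 ppm (0.00025 ppm step, ten raw points
#' per 0.0025-ppm bin).
#'
#' @param n_preterm,n_term group sizes (>= 1).
#' @param group_effects named multiplicative concentration ratios
#'   preterm/term; metabolites absent from the map have ratio 1.
#' @param base_concentrations named non-negative term-group
#'   concentrations; metabolites absent from the map default to 1.
#' @param shift_jitter_sd per-sample, per-metabolite chemical-shift
#'   jitter sd (ppm).
#' @param dilution_range (low, high) of the uniform per-sample dilution
#'   factor; low must be > 0.
#' @param noise_sd additive noise sd (intensity units).
#' @param baseline_amplitude height of a broad Gaussian baseline bump
#'   (0 disables it).
#' @param grid list or vector \code{(ppm_min, ppm_max, n_points)}.
#' @param seed integer seed making the cohort reproducible.
#' @return A list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(n_preterm = 49, n_term = 18,
                         group_effects = c(citrate = 1.75,
                                           creatinine_ch2 = 1.75,
                                           fumarate = 1.75,
                                           hippurate = 1.75),
                         base_concentrations = c(citrate = 1,
                                                 creatinine_ch2 = 0.8,
                                                 creatinine_ch3 = 0.8,
                                                 fumarate = 0.4,
                                                 hippurate = 0.9,
                                                 lactate = 0.7,
                                                 alanine = 0.5,
                                                 dimethylamine = 0.5,
                                                 taurine = 0.6,
                                                 glycine = 0.6,
                                                 formate = 0.3),
                         shift_jitter_sd = 0.005,
                         dilution_range = c(0.7, 1.3),
                         noise_sd = 0.02,
                         baseline_amplitude = 0,
                         grid = c(0.5, 9.5, 36001),
                         seed = 1L) {
  grid <- as.numeric(unlist(grid))
  if (length(grid) != 3L || grid[2] <= grid[1] || grid[3] < 2)
    stop("grid must be (ppm_min, ppm_max, n_points) with ppm_min < ppm_max and n_points >= 2")
  if (n_preterm < 1 || n_term < 1) stop("group sizes must be >= 1")
  if (dilution_range[1] <= 0 || dilution_range[2] < dilution_range[1])
    stop("dilution_range must satisfy 0 < low <= high")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (shift_jitter_sd < 0) stop("shift_jitter_sd must be >= 0")
  if (any(base_concentrations < 0))
    stop("base_concentrations must be non-negative")
  structure(list(n_preterm = as.integer(n_preterm),
                 n_term = as.integer(n_term),
                 group_effects = group_effects,
                 base_concentrations = base_concentrations,
                 shift_jitter_sd = shift_jitter_sd,
                 dilution_range = as.numeric(dilution_range),
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 grid = grid, seed = as.integer(seed)),
            class = "CohortConfig")
}

.config_grid <- function(config) {
  seq(config$grid[1], config$grid[2], length.out = config$grid[3])
}

# Lorentzian line with unit peak height: g^2 / ((x - c)^2 + g^2)
.lorentz <- function(x, center, hwhm) {
  hwhm^2 / ((x - center)^2 + hwhm^2)
}

#' Simulate one urine spectrum
#'
#' Draws, from the current RNG stream, one chemical-shift jitter per
#' metabolite, a dilution factor, and additive noise, then evaluates
#' intensity(ppm) = dilution * sum over lines of conc * amp *
#' Lorentzian(ppm; center + offset + jitter, HWHM) + baseline + noise,
#' clipped at zero.  Concentration is \code{base * effect} for the
#' preterm group and \code{base} for term.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param group \code{"preterm"} or \code{"term"}.
#' @param library list of \code{MetabolitePeak}s.
#' @return numeric intensity vector on the config grid.
#' @export
simulateSpectrum <- function(config, group = c("preterm", "term"),
                             library = defaultMetaboliteLibrary()) {
  group <- match.arg(group)
  if (length(library) == 0L) stop("metabolite library is empty")
  ppm <- .config_grid(config)
  signal <- numeric(length(ppm))
  for (pk in library) {
    base <- config$base_concentrations[pk$name]
    if (is.na(base)) base <- 1
    eff <- config$group_effects[pk$name]
    if (is.na(eff)) eff <- 1
    conc <- if (group == "preterm") base * eff else base
    jit <- stats::rnorm(1L, 0, config$shift_jitter_sd)
    if (conc == 0) next
    for (j in seq_along(pk$relative_amplitudes)) {
      ctr <- pk$center_ppm + pk$line_offsets_ppm[j] + jit
      signal <- signal + conc * pk$relative_amplitudes[j] *
        .lorentz(ppm, ctr, pk$linewidth_ppm)
    }
  }
  # one uniform deviate regardless of the range width, so cohorts with
  # the same seed but different dilution ranges stay draw-for-draw paired
  dil <- config$dilution_range[1] +
    diff(config$dilution_range) * stats::runif(1L)
  base_bump <- if (config$baseline_amplitude > 0) {
    config$baseline_amplitude * exp(-(ppm - 5)^2 / (2 * 2^2))
  } else 0
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(length(ppm), 0, config$noise_sd)
  } else 0
  pmax(dil * signal + base_bump + noise, 0)
}

#' Simulate a preterm/term cohort
#'
#' Seeds the RNG from \code{config$seed} (preterm samples first), so the
#' same configuration always yields a bit-identical cohort.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param library list of \code{MetabolitePeak}s.
#' @return An \linkS4class{NMRExperiment} with \code{colData(x)$group}.
#' @examples
#' cfg <- cohortConfig(n_preterm = 3, n_term = 2, grid = c(0.5, 9.5, 901))
#' simulateCohort(cfg)
#' @export
simulateCohort <- function(config, library = defaultMetaboliteLibrary()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_preterm + config$n_term
  groups <- rep(c("preterm", "term"), c(config$n_preterm, config$n_term))
  ppm <- .config_grid(config)
  m <- matrix(0, length(ppm), n)
  for (i in seq_len(n))
    m[, i] <- simulateSpectrum(config, groups[i], library)
  colnames(m) <- sprintf("%s_%03d", ifelse(groups == "preterm", "PT", "T"),
                         seq_len(n))
  NMRExperiment(m, ppm,
                sampleData = data.frame(group = groups,
                                        row.names = colnames(m)))
}

#' Write a simulated (or any) cohort to disk
#'
#' Emits the spectra-matrix text format of
#' \code{\link{writeSpectraMatrix}} plus a two-column sample table
#' (\code{sample_id}, \code{group}).
#'
#' @param x an \linkS4class{NMRExperiment} with a \code{group} column.
#' @param spectra_path,samples_path output file paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(x, spectra_path, samples_path) {
  writeSpectraMatrix(x, spectra_path)
  g <- sampleGroups(x)
  if (is.null(g)) stop("cohort has no 'group' column to write")
  utils::write.table(
    data.frame(sample_id = colnames(x), group = as.character(g)),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(spectra_path, samples_path))
}
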