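test_that("default metabolite library covers the discriminating signals", {
  lib <- defaultMetaboliteLibrary()
  expect_true("fumarate" %in% names(lib))
  expect_equal(lib$fumarate$center_ppm, 6.8)
  expect_equal(lib$citrate$center_ppm, 3.13)
  expect_equal(lib$creatinine_ch2$center_ppm, 4.28)
  # hippurate multiplet stays inside its reported 7.6-7.8 ppm window
  hip <- lib$hippurate$center_ppm + lib$hippurate$line_offsets_ppm
  expect_gte(min(hip), 7.6)
  expect_lte(max(hip), 7.8)
  # every line of every peak lies in the binnable range
  for (pk in lib) {
    pos <- pk$center_ppm + pk$line_offsets_ppm
    expect_true(all(pos >= 0.5 & pos <= 9.5), label = pk$name)
    expect_true(all(pk$relative_amplitudes > 0))
    expect_gt(pk$linewidth_ppm, 0)
  }
  # at least 3 non-discriminating background metabolites
  disc <- c("citrate", "creatinine_ch2", "fumarate", "hippurate")
  expect_gte(length(setdiff(names(lib), c(disc, "creatinine_ch3"))), 3)
})

test_that("metabolitePeak enforces its invariants", {
  expect_error(metabolitePeak("x", 3, linewidth_ppm = 0), "linewidth")
  expect_error(metabolitePeak("x", 3, relative_amplitudes = c(1, -1),
                              line_offsets_ppm = c(0, 0.01)),
               "relative_amplitudes")
  expect_error(metabolitePeak("x", 9.6), "outside")
})

test_that("all-zero concentrations with no noise give the zero spectrum", {
  lib <- defaultMetaboliteLibrary()
  conc0 <- setNames(rep(0, length(lib)), names(lib))
  cfg <- smallConfig(base_concentrations = conc0, noise_sd = 0,
                     baseline_amplitude = 0, seed = 3)
  x <- simulateCohort(cfg)
  expect_equal(max(abs(spectraMatrix(x))), 0)
})

test_that("cohorts are bit-identical under the same config and seed", {
  cfg <- smallConfig(seed = 11)
  x1 <- simulateCohort(cfg)
  x2 <- simulateCohort(cfg)
  expect_identical(spectraMatrix(x1), spectraMatrix(x2))
  expect_identical(colData(x1)$group, colData(x2)$group)
})

test_that("a unit Lorentzian integrates to its closed form within 1%", {
  gam <- 0.002
  lib <- list(metabolitePeak("probe", 5.0, linewidth_ppm = gam))
  cfg <- cohortConfig(n_preterm = 1, n_term = 1,
                      base_concentrations = c(probe = 1),
                      group_effects = c(probe = 1),
                      shift_jitter_sd = 0, dilution_range = c(1, 1),
                      noise_sd = 0, seed = 1)
  x <- simulateCohort(cfg, library = lib)
  ppm <- ppmGrid(x)
  y <- spectraMatrix(x)[, 1]
  numeric_int <- sum((y[-1] + y[-length(y)]) / 2 * diff(ppm))
  # peak-height-1 Lorentzian: integral = gamma * atan((x - c)/gamma)
  exact <- gam * (atan((9.5 - 5) / gam) - atan((0.5 - 5) / gam))
  expect_lt(abs(numeric_int - exact) / exact, 0.01)
})

test_that("default cohort has 49 preterm and 18 term samples", {
  cfg <- cohortConfig()
  expect_identical(cfg$n_preterm + cfg$n_term, 67L)
  x <- simulateCohort(smallConfig(n_preterm = 49, n_term = 18, seed = 2))
  expect_identical(ncol(x), 67L)
  expect_identical(sum(sampleGroups(x) == "preterm"), 49L)
})

test_that("null group effects leave the two group means indistinguishable", {
  lib <- defaultMetaboliteLibrary()
  eff1 <- setNames(rep(1, length(lib)), names(lib))
  cfg <- cohortConfig(n_preterm = 150, n_term = 150, group_effects = eff1,
                      grid = c(0.5, 9.5, 4501), seed = 5)
  m <- spectraMatrix(simulateCohort(cfg))
  g <- rep(c(TRUE, FALSE), c(150, 150))
  dm <- rowMeans(m[, g]) - rowMeans(m[, !g])
  se <- sqrt(apply(m[, g], 1, var) / 150 + apply(m[, !g], 1, var) / 150)
  z <- abs(dm) / pmax(se, 1e-12)
  # 6-sigma pointwise bound over 4501 grid points
  expect_lt(max(z), 6)
})

test_that("a planted citrate effect raises the preterm mean at 3.13 ppm", {
  lib <- defaultMetaboliteLibrary()
  eff <- setNames(rep(1, length(lib)), names(lib))
  eff["citrate"] <- 1.5
  hits <- vapply(1:20, function(s) {
    cfg <- cohortConfig(n_preterm = 30, n_term = 30, group_effects = eff,
                        grid = c(0.5, 9.5, 4501), seed = 100 + s)
    x <- simulateCohort(cfg)
    i <- which.min(abs(ppmGrid(x) - 3.13))
    g <- sampleGroups(x) == "preterm"
    mean(spectraMatrix(x)[i, g]) > mean(spectraMatrix(x)[i, !g])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a larger effect ratio gives a larger standardized bin difference", {
  lib <- list(metabolitePeak("fumarate", 6.8))
  spec <- binSpec(6.5, 7.0, 0.0025, excluded_regions = list())
  sdiff <- function(effect, seed) {
    cfg <- cohortConfig(n_preterm = 25, n_term = 25,
                        group_effects = c(fumarate = effect),
                        base_concentrations = c(fumarate = 0.4),
                        grid = c(6.5, 7.0, 2001), seed = seed)
    bs <- binSpectra(simulateCohort(cfg, library = lib), spec)
    # pooled intensity of the bins covering the jittered 6.8-ppm line
    j <- which(abs(binCenters(bs) - 6.8) < 0.0075)
    v <- rowSums(binMatrix(bs)[, j, drop = FALSE])
    g <- rep(c(TRUE, FALSE), c(25, 25))
    abs(mean(v[g]) - mean(v[!g])) / sd(v)
  }
  avg <- vapply(c(1.0, 1.5, 2.0), function(e)
    mean(vapply(1:5, function(s) sdiff(e, 200 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(avg) > 0))
})

test_that("writeCohort emits a readable spectra matrix and sample table", {
  cfg <- smallConfig(n_preterm = 3, n_term = 2, grid = c(0.5, 9.5, 901),
                     seed = 4)
  x <- simulateCohort(cfg)
  sp <- tempfile(fileext = ".tsv"); st <- tempfile(fileext = ".tsv")
  writeCohort(x, sp, st)
  x2 <- attachSampleTable(readSpectraMatrix(sp), readSampleTable(st))
  expect_identical(colnames(x2), colnames(x))
  expect_identical(as.character(sampleGroups(x2)),
                   as.character(sampleGroups(x)))
  expect_lt(max(abs(spectraMatrix(x2) - spectraMatrix(x))), 1e-7)
})
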