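make_matrix_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("a well-formed spectra matrix reads into the right shape", {
  path <- make_matrix_file(c(
    "ppm\ta\tb\tc",
    "1.0\t1\t2\t3", "1.1\t4\t5\t6", "1.2\t7\t8\t9",
    "1.3\t1\t1\t1", "1.4\t0\t2\t4"))
  x <- readSpectraMatrix(path)
  expect_s4_class(x, "NMRExperiment")
  expect_identical(dim(x), c(5L, 3L))
  expect_identical(colnames(x), c("a", "b", "c"))
  expect_equal(ppmGrid(x), seq(1.0, 1.4, by = 0.1))
  expect_equal(spectraMatrix(x)[2, ], c(a = 4, b = 5, c = 6))
})

test_that("comma-delimited input is autodetected", {
  path <- make_matrix_file(c("ppm,s1", "1.0,1", "1.1,2", "1.2,3"))
  expect_equal(unname(spectraMatrix(readSpectraMatrix(path))[, 1]),
               c(1, 2, 3))
})

test_that("malformed spectra matrices are rejected with row context", {
  dup <- make_matrix_file(c("ppm\ta", "1.0\t1", "1.0\t2", "1.2\t3"))
  expect_error(readSpectraMatrix(dup), "duplicated ppm value at row 2")
  nonuni <- make_matrix_file(c("ppm\ta", "1.0\t1", "1.1\t2", "1.35\t3",
                               "1.45\t4"))
  expect_error(readSpectraMatrix(nonuni), "not uniform")
  nonmono <- make_matrix_file(c("ppm\ta", "1.0\t1", "1.2\t2", "1.1\t3"))
  expect_error(readSpectraMatrix(nonmono), "increasing|uniform")
  ragged <- make_matrix_file(c("ppm\ta\tb", "1.0\t1\t2", "1.1\t3"))
  expect_error(readSpectraMatrix(ragged))
  missing_cell <- make_matrix_file(c("ppm\ta\tb", "1.0\t1\t2",
                                     "1.1\t\t3", "1.2\t4\t5"))
  expect_error(readSpectraMatrix(missing_cell), "missing")
})

test_that("a descending ppm column is normalized to ascending", {
  path <- make_matrix_file(c("ppm\ta", "1.2\t30", "1.1\t20", "1.0\t10"))
  x <- readSpectraMatrix(path)
  expect_equal(ppmGrid(x), c(1.0, 1.1, 1.2))
  expect_equal(unname(spectraMatrix(x)[, 1]), c(10, 20, 30))
})

test_that("write then read round-trips a spectra matrix", {
  set.seed(21)
  ppm <- seq(0.5, 9.5, length.out = 401)
  m <- matrix(abs(rnorm(401 * 3)), 401, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  x <- NMRExperiment(m, ppm)
  path <- tempfile(fileext = ".tsv")
  writeSpectraMatrix(x, path)
  x2 <- readSpectraMatrix(path)
  expect_identical(ppmGrid(x2), ppm)        # full double precision
  expect_lt(max(abs(spectraMatrix(x2) - m) / pmax(abs(m), 1e-12)), 1e-8)
  expect_identical(colnames(x2), colnames(x))
})

jcamp_fixture <- function(yfactor = 0.5) {
  c("##TITLE=synthetic jcamp fixture",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##FIRSTX=4.0",
    "##LASTX=1.0",
    "##NPOINTS=4",
    sprintf("##YFACTOR=%g", yfactor),
    "##XYDATA=(X++(Y..Y))",
    "4.0 10 20",
    "2.0 30 40",
    "##END=")
}

test_that("JCAMP-DX reading reverses descending grids and applies YFACTOR", {
  path <- tempfile(fileext = ".jdx")
  writeLines(jcamp_fixture(), path)
  x <- readJCAMPDX(path)
  expect_identical(dim(x), c(4L, 1L))
  expect_identical(colnames(x), "synthetic jcamp fixture")
  expect_equal(ppmGrid(x), 1:4)
  # manual reversal oracle: raw y (10,20,30,40) on 4..1 ppm, halved
  expect_equal(unname(spectraMatrix(x)[, 1]), rev(c(10, 20, 30, 40)) * 0.5)
})

test_that("JCAMP-DX files missing required records are rejected by name", {
  bad <- jcamp_fixture()[-7]   # drop NPOINTS
  path <- tempfile(fileext = ".jdx")
  writeLines(bad, path)
  expect_error(readJCAMPDX(path), "NPOINTS")
})

test_that("sample tables are trimmed, validated and joined by id", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\tpreterm ", "s2\tterm",
               "s3\tpreterm"), path)
  tab <- readSampleTable(path)
  expect_identical(levels(tab$group), c("preterm", "term"))
  expect_identical(as.character(tab$group), c("preterm", "term", "preterm"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\tpre-term"), bad)
  expect_error(readSampleTable(bad), "unknown group label")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\tterm", "s1\tterm"), dup)
  expect_error(readSampleTable(dup), "duplicate")

  ppm <- seq(1, 2, length.out = 5)
  m <- matrix(1, 5, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  x <- attachSampleTable(NMRExperiment(m, ppm), tab)
  expect_identical(as.character(sampleGroups(x)),
                   c("preterm", "term", "preterm"))
  # orphans on either side are fatal and named
  expect_error(attachSampleTable(NMRExperiment(m[, 1:2], ppm), tab), "s3")
})

test_that("reports carry the six Table-style metric columns per model", {
  sep <- separableFeatures()
  res <- loocv(sep$x, sep$y, model = "1NN", seed = 1)
  out_json <- tempfile(fileext = ".json")
  out_tsv <- tempfile(fileext = ".tsv")
  writeReport(list(metrics = res$metrics), out_json, out_tsv)
  tab <- read.delim(out_tsv)
  expect_true(all(c("Accuracy", "F1", "FPR", "FNR", "TPR", "TNR") %in%
                    colnames(tab)))
  expect_identical(nrow(tab), 1L)
  js <- jsonlite::read_json(out_json)
  expect_identical(js$metrics[[1]]$model, "1NN")
})
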