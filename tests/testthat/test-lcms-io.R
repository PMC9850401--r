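test_that("mzML write/read round-trips spectra through mzR", {
  run <- simulateRun(c(arabinan = 800),
                     config = simConfig(seed = 3))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(run, path)
  back <- readRun(path)
  expect_identical(nScans(back), nScans(run))
  h1 <- scanHeader(run); h2 <- scanHeader(back)
  expect_identical(h2$msLevel, h1$msLevel)
  expect_equal(h2$rt, h1$rt, tolerance = 1e-9)
  i2 <- which(h1$msLevel == 2L)
  expect_gt(length(i2), 0)
  expect_equal(h2$precursorMz[i2], h1$precursorMz[i2], tolerance = 1e-7)
  expect_equal(h2$collisionEnergy[i2], h1$collisionEnergy[i2],
               tolerance = 1e-3)
  for (i in c(1L, 50L, i2[1])) {
    expect_equal(peaksOf(back, i), peaksOf(run, i), tolerance = 1e-9)
  }
  # the EIC seen through the file equals the in-memory EIC
  mz <- groundTruth(run)$mz_observed[1]
  expect_equal(extractEIC(back, mz)@intensity,
               extractEIC(run, mz)@intensity, tolerance = 1e-9)
})

test_that("malformed mzML is a parse error", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines(c("<?xml version=\"1.0\"?>", "<mzML><run><spectrumList>"),
             path)
  expect_error(readRun(path), "parse")
  expect_error(readRun("no/such/file.mzML"), "not found")
})

test_that("MGF blocks read and write per the Mascot format", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=a", "PEPMASS=529.1739", "CHARGE=1+",
    "RTINSECONDS=120", "185.0420 50", "367.1211 100", "END IONS",
    "BEGIN IONS", "TITLE=b", "PEPMASS=691.2267", "RTINSECONDS=240",
    "200.1 10", "END IONS",
    "BEGIN IONS", "TITLE=c", "PEPMASS=853.2795", "300.5 7", "END IONS"),
    path)
  run <- readRun(path)
  expect_identical(nScans(run), 3L)
  h <- scanHeader(run)
  expect_true(all(h$msLevel == 2L))
  expect_equal(h$precursorMz, c(529.1739, 691.2267, 853.2795))
  expect_equal(h$rt[1:2], c(2, 4))
  expect_equal(peaksOf(run, 1)[, "intensity"], c(50, 100))

  sim <- simulateRun(c(chitin = 500), config = simConfig(seed = 5))
  out <- withr::local_tempfile(fileext = ".mgf")
  writeMGF(sim, out)
  back <- readRun(out)
  hs <- scanHeader(sim)
  expect_identical(nScans(back), sum(hs$msLevel == 2L))
  expect_equal(scanHeader(back)$precursorMz,
               hs$precursorMz[hs$msLevel == 2L], tolerance = 1e-5)

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "oops", "END IONS"), bad)
  expect_error(readRun(bad), "block 1")
  trunc <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "100 1"), trunc)
  expect_error(readRun(trunc), "unbalanced")
})

test_that("EIC extraction sums the tolerance window per MS1 scan", {
  run <- simulateRun(c(arabinan = 1000),
                     config = quietConfig(9, noiseFrac = 0, isotopes = FALSE,
                                          massErrorPpm = 0))
  gt <- groundTruth(run)
  eic <- extractEIC(run, gt$mz[1], 15)
  expected <- gt$true_area[1] * dnorm(eic@rt, gt$rt[1], 0.1)
  expected[abs(eic@rt - gt$rt[1]) > 4 * 0.1] <- 0
  expect_equal(eic@intensity, expected, tolerance = 1e-9)
  # 50 ppm off-target with a 10 ppm window sees nothing
  off <- extractEIC(run, gt$mz[1] * (1 + 50e-6), 10)
  expect_true(all(off@intensity == 0))
  # neighbours separated by much more than the window do not bleed in
  eic2 <- extractEIC(run, gt$mz[2], 15)
  expect_equal(sum(eic2@intensity > 0 & eic@intensity > 0), 0L)
  ms2only <- readRun(withr::local_tempfile(fileext = ".mgf", lines = c(
    "BEGIN IONS", "PEPMASS=500", "100 1", "END IONS")))
  expect_error(extractEIC(ms2only, 500), "MS1")
})
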