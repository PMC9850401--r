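test_that("simulation is seeded-deterministic and linear in concentration", {
  cfg <- quietConfig(61)
  r1 <- simulateRun(c(arabinan = 500), config = cfg)
  r2 <- simulateRun(c(arabinan = 500), config = cfg)
  expect_identical(groundTruth(r1), groundTruth(r2))
  expect_identical(peaksOf(r1, 100), peaksOf(r2, 100))
  r3 <- simulateRun(c(arabinan = 1000), config = cfg)
  expect_equal(groundTruth(r3)$true_area, 2 * groundTruth(r1)$true_area)
  expect_error(simulateRun(numeric()), "non-empty")
  expect_error(simulateRun(c(arabinan = -1)), ">= 0")
  expect_error(simulateRun(c(nougat = 10)), "nougat")
})

test_that("noiseless EICs integrate to the programmed areas", {
  run <- simulateRun(c(galactan = 1200),
                     config = quietConfig(62, noiseFrac = 0,
                                          areaNoiseCv = 0))
  gt <- groundTruth(run)
  for (i in seq_len(nrow(gt))) {
    eic <- extractEIC(run, gt$mz_observed[i], 15)
    pk <- detectPeaks(eic)
    expect_identical(nrow(pk), 1L)
    expect_equal(pk$area, gt$true_area[i], tolerance = 0.02)
    expect_equal(pk$apex_rt, gt$rt[i], tolerance = 1 / 0.63 / 60)
  }
})

test_that("calibration series emit the dilution design", {
  ser <- simulateCalibrationSeries(c("arabinan", "chitin"),
                                   levels = 2000 / 2^(0:5),
                                   config = quietConfig(63),
                                   polys = smallDefs())
  expect_identical(length(ser$runs), 6L)
  expect_setequal(unique(ser$design$concentration_ugml),
                  c(2000, 1000, 500, 250, 125, 62.5))
  expect_identical(nrow(ser$design), 12L)
  expect_identical(names(ser$runs), sprintf("cal_L%d", 1:6))
  gt <- groundTruth(ser$runs[["cal_L3"]])
  expect_true(all(gt$conc == 500))
  expect_error(simulateCalibrationSeries("arabinan", levels = c(1, 2, 4, 8)),
               "five")
  expect_error(simulateCalibrationSeries("arabinan",
                                         levels = c(0, 1, 2, 4, 8)),
               "positive")
})

test_that("data-dependent MS2 honours dynamic exclusion", {
  run <- simulateRun(c(arabinan = 1500, chitin = 800),
                     config = simConfig(seed = 64))
  h <- scanHeader(run)
  ms2 <- h[h$msLevel == 2L, ]
  expect_gt(nrow(ms2), 0)
  # collision energy follows the linear function of precursor m/z
  expect_equal(ms2$collisionEnergy, 1.45 * ms2$precursorMz - 3.5,
               tolerance = 1e-9)
  # no precursor is re-selected within the 30 s exclusion window
  grp <- cumsum(c(TRUE, diff(sort(ms2$precursorMz)) > 0.01))
  for (mzv in unique(round(ms2$precursorMz, 3))) {
    rts <- sort(ms2$rt[abs(ms2$precursorMz - mzv) < 0.005])
    if (length(rts) > 1L) {
      expect_true(all(diff(rts) > 30 / 60 - 1e-9))
    }
  }
})

test_that("simulated MS2 spectra support composition scoring", {
  run <- simulateRun(c(chitin = 1000), config = simConfig(seed = 65))
  h <- scanHeader(run)
  i <- which(h$msLevel == 2L)[1]
  sp <- peaksOf(run, i)
  gt <- groundTruth(run)
  truth <- gt$composition[which.min(abs(gt$mz_observed -
                                          h$precursorMz[i]))]
  right <- scoreMsms(sp[, 1], sp[, 2], parseComposition(truth), "sodium")
  wrong <- scoreMsms(sp[, 1], sp[, 2], parseComposition("Hex4-red"),
                     "sodium")
  expect_gt(right, 0.9)
  expect_lt(wrong, 0.6)
  expect_gt(right, wrong)
})
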