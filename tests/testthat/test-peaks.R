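test_that("a synthetic Gaussian integrates to its closed-form area", {
  eic <- gaussianEIC(area = 2e6, apex = 10, sigma = 0.1)
  pk <- detectPeaks(eic)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$area, 2e6, tolerance = 0.02)
  expect_equal(pk$apex_rt, 10, tolerance = 1 / 0.63 / 60)
  expect_true(pk$rt_start < pk$apex_rt && pk$apex_rt < pk$rt_end)
  expect_equal(pk$snr, 1e6) # noiseless baseline hits the cap
})

test_that("flat noise yields no peaks and scaling leaves peaks invariant", {
  noise <- gaussianEIC(area = 0, baseline = 100, noiseSd = 10, seed = 21)
  expect_identical(nrow(detectPeaks(noise, minSnr = 3)), 0L)

  eic <- gaussianEIC(area = 1e6, apex = 8, sigma = 0.15, baseline = 50,
                     noiseSd = 5, seed = 22)
  pk1 <- detectPeaks(eic)
  scaled <- new("EIC", targetMz = eic@targetMz, tolerancePpm = 15,
                rt = eic@rt, intensity = eic@intensity * 1000)
  pk2 <- detectPeaks(scaled)
  expect_identical(nrow(pk2), nrow(pk1))
  expect_equal(pk2$apex_rt, pk1$apex_rt)
  expect_equal(pk2$area, pk1$area * 1000, tolerance = 1e-9)
  expect_equal(pk2$snr, pk1$snr, tolerance = 1e-9)
})

test_that("nearby Gaussians resolve into non-overlapping peaks", {
  dt <- 1 / 0.63 / 60
  rt <- seq(0, 20, by = dt)
  y <- 1e6 * dnorm(rt, 9, 0.2) + 8e5 * dnorm(rt, 11, 0.2)
  eic <- new("EIC", targetMz = 500, tolerancePpm = 15, rt = rt,
             intensity = y)
  pk <- detectPeaks(eic)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$apex_rt, c(9, 11), tolerance = dt)
  expect_lt(pk$rt_end[1], pk$rt_start[2] + 1e-12)
  expect_equal(sum(pk$area), 1.8e6, tolerance = 0.02)
})

test_that("S/N estimation recovers the injected noise scale", {
  # peak of known height 30 over Gaussian noise sigma 10: mean S/N
  # across seeds approaches 3, and doubling the noise halves it
  snrs <- snrs2 <- numeric(60)
  for (s in seq_along(snrs)) {
    e1 <- gaussianEIC(area = 0, baseline = 100, noiseSd = 10,
                      seed = 300 + s)
    peak <- data.frame(apex_rt = 10, rt_start = 9.7, rt_end = 10.3,
                       area = 1, height = 30)
    snrs[s] <- estimateSnr(e1, peak)
    e2 <- gaussianEIC(area = 0, baseline = 100, noiseSd = 20,
                      seed = 300 + s)
    snrs2[s] <- estimateSnr(e2, peak)
  }
  expect_equal(mean(snrs), 3, tolerance = 0.15)
  expect_equal(mean(snrs / snrs2), 2, tolerance = 0.15)

  quiet <- gaussianEIC(area = 1e6, apex = 10, sigma = 0.1)
  pk <- detectPeaks(quiet)
  expect_equal(estimateSnr(quiet, pk[1, ]), 1e6)
  # a peak whose exclusion spans swallow the whole flank is an error
  expect_error(
    estimateSnr(quiet, pk[1, ],
                exclude = data.frame(rt_start = 0, rt_end = 20)),
    "baseline")
  expect_error(
    estimateSnr(quiet, data.frame(rt_start = -5, rt_end = 2, height = 1)),
    "outside")
})
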