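test_that("top-3 selection takes the most abundant unique entries", {
  e <- do.call(rbind, lapply(3:13, function(d)
    libraryEntryRow("arabinan", sprintf("Pnt%d-red", d), rt = 4.5 + 0.8 * d,
                    mean_area = 1e6 * 0.75^(d - 3))))
  lib <- makeLibrary(e)
  top <- selectTop3(lib, "arabinan")
  expect_identical(top$composition, c("Pnt3-red", "Pnt4-red", "Pnt5-red"))

  three <- makeLibrary(e[1:3, ])
  expect_identical(selectTop3(three, "arabinan")$composition,
                   e$composition[1:3])
  expect_error(selectTop3(makeLibrary(e[1:2, ]), "arabinan"), "fewer")
  # non-unique entries are excluded unless asked otherwise
  e2 <- e; e2$unique[1:9] <- FALSE
  expect_error(selectTop3(makeLibrary(e2), "arabinan"),
               "restrictUnique = FALSE")
  expect_identical(
    selectTop3(makeLibrary(e2), "arabinan",
               restrictUnique = FALSE)$composition,
    c("Pnt3-red", "Pnt4-red", "Pnt5-red"))
  # deterministic tie-break: equal areas go to the lower DP
  e3 <- e; e3$mean_area <- 1
  expect_identical(selectTop3(makeLibrary(e3), "arabinan")$composition,
                   c("Pnt3-red", "Pnt4-red", "Pnt5-red"))
})

test_that("zero-intercept fit matches its closed form and lm oracle", {
  x <- c(62.5, 125, 250, 500, 1000, 2000)
  fit <- fitCalibration(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r2, 1)
  expect_error(fitCalibration(x[1:4], 2 * x[1:4]), "five")
  expect_error(fitCalibration(x, rep(0, 6)), "zero")
  expect_error(fitCalibration(c(x[-1], 125), 2 * c(x[-1], 125)),
               "distinct")
  # independent route: stats::lm through the origin
  set.seed(50)
  for (i in 1:20) {
    y <- 2 * x * (1 + rnorm(6, 0, 0.05))
    fit <- fitCalibration(x, y)
    lmfit <- lm(y ~ x + 0)
    expect_equal(fit$slope, unname(coef(lmfit)), tolerance = 1e-12)
    expect_equal(fit$r2, summary(lmfit)$r.squared, tolerance = 1e-12)
  }
  # slope recovery under 1% proportional noise across seeds
  slopes <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    fitCalibration(x, 2 * x * (1 + rnorm(6, 0, 0.01)))$slope
  }, numeric(1))
  expect_equal(mean(slopes), 2, tolerance = 0.02)
  expect_true(all(abs(slopes - 2) / 2 < 0.05))
})

test_that("quantification inverts the curve and respects the MDL", {
  lv <- data.frame(conc = c(62.5, 125, 250, 500, 1000, 2000))
  lv$area <- 300 * lv$conc
  lv$snr <- c(2, 4, 9, 20, 45, 90)
  top3 <- data.frame(composition = c("Pnt3-red", "Pnt4-red", "Pnt5-red"))
  cv <- calibrationCurve("arabinan", top3, lv)
  expect_equal(cv@slope, 300)
  expect_equal(cv@r2, 1)
  expect_equal(cv@mdlUgml, 125) # lowest level with S/N > 3
  expect_equal(cv@snrAtMdl, 4)
  q <- quantifySignal(300 * 100, cv)
  expect_equal(q$conc_ugml, 100)
  expect_true(q$below_mdl)
  q2 <- quantifySignal(300 * 500, cv, dryLoadingMgPerMl = 25,
                       moistureFraction = 0.1)
  expect_false(q2$below_mdl)
  expect_equal(q2$conc_dry_pct, 2)
  expect_equal(q2$conc_fresh_g_per_100g, 1.8)
  q0 <- quantifySignal(0, cv)
  expect_equal(q0$conc_ugml, 0)
  expect_true(q0$below_mdl)

  expect_equal(computeMdl(c(50, 100, 200), c(1, 4, 9))$mdl_ugml, 100)
  expect_error(computeMdl(c(50, 100), c(1, 2)), "S/N")
  lv$snr <- rep(2, 6)
  expect_error(calibrationCurve("arabinan", top3, lv), "S/N")
})

test_that("unit conversion follows the dry-loading arithmetic", {
  expect_equal(convertUnits(0)$dry_pct, 0)
  u <- convertUnits(500, dryLoadingMgPerMl = 25, moistureFraction = 0.6)
  expect_equal(u$dry_pct, 2)
  expect_equal(u$fresh_g_per_100g, 0.8)
  expect_error(convertUnits(10, dryLoadingMgPerMl = 0), "positive")
  expect_error(convertUnits(10, moistureFraction = 1), "moisture")
})

test_that("bias and CV statistics match their definitions", {
  v <- validationStats(c(110, 110, 110), 100)
  expect_equal(v$bias_pct, 10)
  expect_equal(v$cv_pct, 0)
  v2 <- validationStats(c(90, 100, 110), 100)
  expect_equal(v2$bias_pct, 0)
  expect_equal(v2$cv_pct, 10)
  expect_identical(v2$n_replicates, 3L)
  expect_warning(v1 <- validationStats(105, 100), "single replicate")
  expect_true(is.na(v1$cv_pct))
  expect_equal(v1$bias_pct, 5)
  expect_error(validationStats(c(1, 2), 0), "positive")
})

test_that("relative quantitation is a scale-invariant partition", {
  asg <- data.frame(polysaccharide = c("starch", "starch", "xylan",
                                       "UNASSIGNED"),
                    area = c(60, 20, 15, 5))
  f <- relativeQuant(asg)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(f[["starch"]], 0.8)
  expect_equal(f[["xylan"]], 0.15)
  expect_equal(f[["UNASSIGNED"]], 0.05)
  f2 <- relativeQuant(transform(asg, area = area * 1e6))
  expect_equal(f2, f, tolerance = 1e-12)
  one <- data.frame(polysaccharide = "mannan", area = 7)
  expect_equal(relativeQuant(one)[["mannan"]], 1)
  expect_equal(relativeQuant(data.frame(
    polysaccharide = c("a", "b"), area = c(3, 3)))[["a"]], 0.5)
  expect_error(relativeQuant(data.frame(polysaccharide = "a", area = 0)),
               "zero")
})
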