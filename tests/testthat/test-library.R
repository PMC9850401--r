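test_that("a starch standard yields its complete unique oligomer series", {
  run <- simulateRun(c(starch = 2000), config = simConfig(seed = 31))
  lib <- buildLibrary(list(starch = run))
  e <- libraryEntries(lib)
  expect_identical(nrow(e), 19L) # DP 3..21
  expect_setequal(e$composition, paste0("Hex", 3:21, "-red"))
  expect_true(all(e$unique))
  expect_true(all(e$adduct == "sodium"))
  gt <- groundTruth(run)
  m <- merge(e, gt, by = "composition")
  expect_equal(m$rt.x, m$rt.y, tolerance = 0.05)
  expect_equal(m$mean_area, m$area, tolerance = 0.05)
})

test_that("shared compositions collide only when retention times do", {
  # two hexose polymers, RTs at least 3 tolerances apart -> all unique
  cfg <- simConfig(seed = 32)
  runs <- list(
    starch = simulateRun(c(starch = 2000), config = cfg),
    cellulose = simulateRun(c(cellulose = 2000),
                            config = simConfig(seed = 33)))
  lib <- buildLibrary(runs)
  expect_true(all(libraryEntries(lib)$unique))

  # the same series at identical RTs is flagged non-unique throughout
  defs <- simPolysaccharides()
  defs$shadow <- defs$cellulose
  defs$shadow$name <- "shadow"
  runs2 <- list(
    cellulose = simulateRun(c(cellulose = 2000), defs,
                            config = simConfig(seed = 34)),
    shadow = simulateRun(c(shadow = 2000), defs,
                         config = simConfig(seed = 35)))
  lib2 <- buildLibrary(runs2)
  expect_true(all(!libraryEntries(lib2)$unique))
  expect_error(
    buildLibrary(list(blank = simulateRun(c(starch = 0),
                                          config = quietConfig(36)))),
    "blank")
})

test_that("library serialization round-trips and flags corrupt input", {
  set.seed(40)
  n <- 60
  comps <- sprintf("Hex%d-red", sample(3:21, n, replace = TRUE))
  e <- do.call(rbind, lapply(seq_len(n), function(i)
    libraryEntryRow(sample(c("starch", "xylan", "mannan"), 1), comps[i],
                    rt = round(runif(1, 5, 25), 4) + i * 1e-3,
                    mean_area = round(runif(1, 1e4, 1e7), 2),
                    unique = sample(c(TRUE, FALSE), 1))))
  lib <- makeLibrary(e)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLibrary(lib, tsv)
  back <- readLibrary(tsv)
  expect_equal(libraryEntries(back), libraryEntries(lib),
               tolerance = 1e-12)
  json <- withr::local_tempfile(fileext = ".json")
  writeLibrary(lib, json)
  expect_equal(libraryEntries(readLibrary(json))$mz,
               libraryEntries(lib)$mz, tolerance = 1e-12)

  empty <- makeLibrary(e[0, ])
  tsv0 <- withr::local_tempfile(fileext = ".tsv")
  writeLibrary(empty, tsv0)
  expect_identical(length(readLines(tsv0)), 1L)
  expect_identical(length(readLibrary(tsv0)), 0L)

  lines <- readLines(tsv)
  lines[5] <- sub("^([^\t]*)\t[^\t]*", "\\1\tNotAGlycan", lines[5])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(readLibrary(bad), "line 5")
  hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("polysaccharide", "poly", lines), hdr)
  expect_error(readLibrary(hdr), "header")
})

test_that("peak-to-polysaccharide matching follows the RT rules", {
  e <- rbind(libraryEntryRow("starch", "Hex5-red", rt = 9.25,
                             mean_area = 2e6),
             libraryEntryRow("cellulose", "Hex5-red", rt = 11.25,
                             mean_area = 5e5),
             libraryEntryRow("arabinan", "Pnt3-red", rt = 6.9,
                             mean_area = 3e6))
  lib <- makeLibrary(e)
  mk <- function(comp, rt) {
    data.frame(channel_mz = mzOf(parseComposition(comp)),
               composition = comp, adduct = "sodium",
               theoretical_mz = mzOf(parseComposition(comp)),
               ppm_error = 0, apex_rt = rt, rt_start = rt - 0.2,
               rt_end = rt + 0.2, area = 1e5, height = 1e4, snr = 10,
               msms_score = NA_real_, stringsAsFactors = FALSE)
  }
  pk <- rbind(mk("Hex5-red", 9.35), mk("Hex5-red", 13.5),
              mk("Pnt3-red", 7.0))
  asg <- matchPeaks(pk, lib, rtTolerance = 0.5)
  expect_identical(asg$polysaccharide, c("starch", "UNASSIGNED",
                                         "arabinan"))
  expect_equal(asg$rt_delta, c(0.1, NA, 0.1), tolerance = 1e-9)
  # equidistant between two polysaccharides: larger library area wins
  expect_warning(
    tie <- matchPeaks(mk("Hex5-red", 10.25), lib, rtTolerance = 1.5),
    "equidistant")
  expect_identical(tie$polysaccharide, "starch")
  # permutation invariance
  perm <- c(3, 1, 2)
  asg2 <- matchPeaks(pk[perm, ], lib, rtTolerance = 0.5)
  expect_identical(asg2$polysaccharide, asg$polysaccharide[perm])
})

test_that("standards re-assign to themselves with nothing unassigned", {
  defs <- smallDefs()
  runs <- list(
    arabinan = simulateRun(c(arabinan = 2000), defs,
                           config = simConfig(seed = 37)),
    chitin = simulateRun(c(chitin = 2000), defs,
                         config = simConfig(seed = 38)))
  lib <- buildLibrary(runs)
  for (p in names(runs)) {
    pk <- annotateRun(runs[[p]])
    asg <- matchPeaks(pk, lib)
    expect_true(all(asg$polysaccharide == p))
  }
  mix <- simulateRun(c(arabinan = 900, chitin = 400), defs,
                     config = simConfig(seed = 39))
  asg <- matchPeaks(annotateRun(mix), lib)
  expect_false("UNASSIGNED" %in% asg$polysaccharide)
})
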