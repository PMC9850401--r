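#' Built-in simulated polysaccharide definitions
#'
#' The nine polysaccharides the pipeline supports, as oligomer-series
#' generators for the run simulator: residue class of the
#' depolymerization products, DP range (starch reaches DP 21, galactan
#' DP 12, arabinan DP 3-15 giving 13 oligomers), a linear
#' retention-time model (PGC retention grows with DP; series of shared
#' composition are separated by distinct intercepts), a geometric
#' per-DP abundance decay (smallest oligomers most abundant), and an
#' instrument response slope (area per ug/mL) of the magnitude seen on
#' QTOF instruments.
#'
#' @return named list of definitions, each with `name`, `class`
#'   (`hex`, `pnt`, `hexnac`, `xylan`, `xyloglucan`), `dpRange`,
#'   `rtBase`, `rtPerDp` (min), `decay`, `responseSlope`.
#' @export
simPolysaccharides <- function() {
  defs <- list(
    list(name = "starch",     class = "hex",    dpRange = c(3L, 21L),
         rtBase = 5.0,  rtPerDp = 0.85, decay = 0.82, responseSlope = 34000),
    list(name = "cellulose",  class = "hex",    dpRange = c(3L, 10L),
         rtBase = 7.0,  rtPerDp = 0.85, decay = 0.80, responseSlope = 9800),
    list(name = "beta-glucan", class = "hex",   dpRange = c(3L, 12L),
         rtBase = 9.0,  rtPerDp = 0.85, decay = 0.78, responseSlope = 55000),
    list(name = "mannan",     class = "hex",    dpRange = c(3L, 10L),
         rtBase = 11.0, rtPerDp = 0.85, decay = 0.80, responseSlope = 35600),
    list(name = "galactan",   class = "hex",    dpRange = c(3L, 12L),
         rtBase = 13.0, rtPerDp = 0.85, decay = 0.80, responseSlope = 25000),
    list(name = "arabinan",   class = "pnt",    dpRange = c(3L, 15L),
         rtBase = 4.5,  rtPerDp = 0.80, decay = 0.75, responseSlope = 69700),
    list(name = "xylan",      class = "xylan",  dpRange = c(3L, 12L),
         rtBase = 7.6,  rtPerDp = 0.80, decay = 0.78, responseSlope = 51800),
    list(name = "xyloglucan", class = "xyloglucan", dpRange = c(4L, 12L),
         rtBase = 10.2, rtPerDp = 0.80, decay = 0.78, responseSlope = 26900),
    list(name = "chitin",     class = "hexnac", dpRange = c(3L, 8L),
         rtBase = 6.0,  rtPerDp = 0.90, decay = 0.75, responseSlope = 117000)
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' Simulator configuration
#'
#' Acquisition and noise parameters of the synthetic LC-MS generator.
#' Defaults mirror the acquisition the pipeline targets: 0.63 spectra/s
#' over a 45-minute gradient, data-dependent top-5 precursor selection
#' with 30 s dynamic exclusion, and a linear collision-energy function
#' `CE = ceSlope * (m/z) + ceIntercept` with slope 1.45 and intercept
#' -3.5 (stored verbatim; the simulator does not depend on its absolute
#' scale).
#'
#' @param seed RNG seed; output is deterministic per seed.
#' @param scanRate MS1 acquisition rate, spectra/s (default 0.63).
#' @param gradientMin run length in minutes (default 45).
#' @param peakSigmaMin chromatographic peak sigma, minutes (default
#'   0.1).
#' @param noiseFrac baseline noise sigma as a fraction of the run's
#'   tallest signal (default 0.005).
#' @param noiseSigma absolute baseline noise sigma in counts; when set
#'   it overrides `noiseFrac`, emulating constant instrument noise
#'   across a dilution series.
#' @param areaNoiseCv multiplicative per-oligosaccharide area noise CV
#'   (default 0; validation simulations use 0.05).
#' @param isotopes emit isotope envelopes (default `TRUE`).
#' @param massErrorPpm per-run mass calibration error sigma, ppm
#'   (default 2).
#' @param ms2 schedule data-dependent MS2 scans (default `TRUE`).
#' @param topN precursors fragmented per cycle (default 5).
#' @param exclusionSec dynamic exclusion window, seconds (default 30).
#' @param ceSlope,ceIntercept collision-energy function coefficients.
#' @param adduct,charge cationization of the simulated species.
#' @return named list of parameters.
#' @export
simConfig <- function(seed = 1L, scanRate = 0.63, gradientMin = 45,
                      peakSigmaMin = 0.1, noiseFrac = 0.005,
                      noiseSigma = NULL, areaNoiseCv = 0,
                      isotopes = TRUE, massErrorPpm = 2,
                      ms2 = TRUE, topN = 5L, exclusionSec = 30,
                      ceSlope = 1.45, ceIntercept = -3.5,
                      adduct = "sodium", charge = 1L) {
  cfg <- list(seed = as.integer(seed), scanRate = scanRate,
              gradientMin = gradientMin, peakSigmaMin = peakSigmaMin,
              noiseFrac = noiseFrac, noiseSigma = noiseSigma,
              areaNoiseCv = areaNoiseCv,
              isotopes = isTRUE(isotopes), massErrorPpm = massErrorPpm,
              ms2 = isTRUE(ms2), topN = as.integer(topN),
              exclusionSec = exclusionSec, ceSlope = ceSlope,
              ceIntercept = ceIntercept, adduct = adduct,
              charge = as.integer(charge))
  pos <- c("scanRate", "gradientMin", "peakSigmaMin")
  if (any(vapply(cfg[pos], function(v) !is.numeric(v) || v <= 0,
                 logical(1)))) {
    stop("scanRate, gradientMin and peakSigmaMin must be positive")
  }
  if (cfg$noiseFrac < 0 || cfg$areaNoiseCv < 0 || cfg$massErrorPpm < 0) {
    stop("noise parameters must be non-negative")
  }
  cfg
}

# Oligomer series of one simulated polysaccharide: composition,
# counts, DP, RT and normalized abundance weight per member.
compositionSeries <- function(def) {
  dps <- seq.int(def$dpRange[1], def$dpRange[2])
  counts <- switch(def$class,
    hex = data.frame(hex = dps, pnt = 0L, hxa = 0L, hexnac = 0L, me = 0L),
    pnt = data.frame(hex = 0L, pnt = dps, hxa = 0L, hexnac = 0L, me = 0L),
    hexnac = data.frame(hex = 0L, pnt = 0L, hxa = 0L, hexnac = dps, me = 0L),
    # xylan: pentose backbone plus occasional 4-O-methyl-glucuronic
    # acid branches on the even members
    xylan = {
      plain <- data.frame(hex = 0L, pnt = dps, hxa = 0L, hexnac = 0L,
                          me = 0L, dp = dps, wmul = 1)
      acid <- dps[dps %% 2L == 0L & dps >= 4L]
      acidic <- data.frame(hex = 0L, pnt = acid - 1L, hxa = 1L,
                           hexnac = 0L, me = 1L, dp = acid, wmul = 0.35)
      rbind(plain, acidic)
    },
    # xyloglucan: glucan backbone with xylose branches, roughly two
    # hexoses per pentose
    xyloglucan = data.frame(hex = ceiling(2 * dps / 3), pnt = 0L,
                            hxa = 0L, hexnac = 0L, me = 0L, dp = dps,
                            wmul = 1),
    stop("unknown simulated residue class: ", def$class)
  )
  if (is.null(counts$dp)) {
    counts$dp <- dps
    counts$wmul <- 1
  }
  if (def$class == "xyloglucan") {
    counts$pnt <- counts$dp - counts$hex
  }
  counts$rt <- def$rtBase + def$rtPerDp * counts$dp
  w <- def$decay^(counts$dp - def$dpRange[1]) * counts$wmul
  counts$weight <- w / sum(w)
  counts$composition <- formatCompositionCounts(
    counts$hex, counts$pnt, counts$hxa, counts$hexnac, counts$me, TRUE)
  counts
}

#' Simulate an LC-MS run of a polysaccharide mixture
#'
#' Generates an in-memory run with Gaussian elution profiles for every
#' oligosaccharide of every polysaccharide in the mixture. True peak
#' area is proportional to concentration x per-DP abundance weight x
#' response slope; the observed monoisotopic trace reproduces it up to
#' the optional multiplicative area noise. Baseline noise is additive
#' Gaussian on each monoisotopic channel; isotope envelopes (+1, +2 at
#' carbohydrate-like ratios) ride above the monoisotopic trace;
#' observed m/z carries a per-run calibration error. When `ms2` is
#' enabled, data-dependent MS2 scans follow top-N selection with
#' dynamic exclusion, carrying B/Y fragment spectra and the linear
#' collision-energy value. Fully reproducible per seed.
#'
#' @param mixture named numeric vector, polysaccharide -> ug/mL
#'   (>= 0; at least one entry).
#' @param polys polysaccharide definitions ([simPolysaccharides()]).
#' @param config [simConfig()].
#' @return an [MsRun-class]; `groundTruth(run)` holds the
#'   per-oligosaccharide truth table (`polysaccharide`, `composition`,
#'   `adduct`, `mz`, `mz_observed`, `rt`, `true_area`, `area`, `conc`).
#' @export
simulateRun <- function(mixture, polys = simPolysaccharides(),
                        config = simConfig()) {
  if (length(mixture) == 0L || is.null(names(mixture))) {
    stop("mixture must be a non-empty named vector of concentrations")
  }
  if (any(mixture < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(mixture), names(polys))
  if (length(unknown)) {
    stop("no simulated definition for: ", paste(unknown, collapse = ", "))
  }
  set.seed(config$seed)
  masses <- residueMasses()

  truth <- do.call(rbind, lapply(names(mixture), function(p) {
    s <- compositionSeries(polys[[p]])
    s$polysaccharide <- p
    s$conc <- mixture[[p]]
    s$true_area <- s$conc * polys[[p]]$responseSlope * s$weight
    s
  }))
  truth$adduct <- config$adduct
  r <- masses$residues; md <- masses$mods
  neutral <- truth$hex * r[["Hex"]] + truth$pnt * r[["Pnt"]] +
    truth$hxa * r[["HxA"]] + truth$hexnac * r[["HexNAc"]] +
    truth$me * md[["Me"]] + masses$constants[["water"]] + md[["red"]]
  truth$mz <- (neutral + config$charge * adductMass(config$adduct, masses)) /
    config$charge
  truth$mz_observed <- truth$mz *
    (1 + stats::rnorm(nrow(truth), 0, config$massErrorPpm) * 1e-6)
  truth$area <- truth$true_area *
    pmax(1 + stats::rnorm(nrow(truth), 0, config$areaNoiseCv), 0)
  truth$nC <- 6L * truth$hex + 5L * truth$pnt + 6L * truth$hxa +
    8L * truth$hexnac + truth$me

  dtMin <- (1 / config$scanRate) / 60
  t1 <- seq(0, config$gradientMin, by = dtMin)
  nScan <- length(t1)
  sigma <- config$peakSigmaMin
  live <- which(truth$area > 0)

  # per-scan point buffers for MS1
  scanMz <- vector("list", nScan)
  scanInt <- vector("list", nScan)
  # mono-trace intensity matrix rows for DDA selection (sparse by oligo)
  monoInt <- matrix(0, nrow = length(live), ncol = 0L)
  monoIdx <- vector("list", length(live))
  monoVal <- vector("list", length(live))
  heights <- numeric(length(live))
  for (k in seq_along(live)) {
    i <- live[k]
    idx <- which(abs(t1 - truth$rt[i]) <= 4 * sigma)
    monoIdx[[k]] <- idx
    v <- truth$area[i] * stats::dnorm(t1[idx], truth$rt[i], sigma)
    monoVal[[k]] <- v
    heights[k] <- if (length(v)) max(v) else 0
  }
  sigmaN <- if (!is.null(config$noiseSigma)) config$noiseSigma else
    config$noiseFrac * max(c(heights, 0))

  isoRatios <- function(nC) {
    lam <- 0.0108 * nC
    c(1, lam, lam^2 / 2)
  }
  nIso <- if (config$isotopes) 3L else 1L
  isoSpacing <- 1.0033548 / config$charge

  for (k in seq_along(live)) {
    i <- live[k]
    idx <- monoIdx[[k]]
    if (!length(idx)) next
    v <- monoVal[[k]]
    ratios <- isoRatios(truth$nC[i])[seq_len(nIso)]
    for (j in seq_along(idx)) {
      s <- idx[j]
      scanMz[[s]] <- c(scanMz[[s]],
                       truth$mz_observed[i] + (seq_len(nIso) - 1L) * isoSpacing)
      scanInt[[s]] <- c(scanInt[[s]], v[j] * ratios)
    }
  }
  # baseline noise on every monoisotopic channel, every scan; channels
  # closer than 10 ppm (one physical detection channel) are merged so a
  # composition shared by several polysaccharides carries one baseline
  if (sigmaN > 0) {
    chans <- sort(unique(truth$mz_observed[truth$conc > 0]))
    if (length(chans) > 1L) {
      grp <- cumsum(c(TRUE, diff(chans) > chans[-length(chans)] * 10e-6))
      chans <- as.numeric(tapply(chans, grp, mean))
    }
    for (s in seq_len(nScan)) {
      nz <- pmax(stats::rnorm(length(chans), 3 * sigmaN, sigmaN), 0)
      scanMz[[s]] <- c(scanMz[[s]], chans)
      scanInt[[s]] <- c(scanInt[[s]], nz)
    }
  }

  ms1Peaks <- lapply(seq_len(nScan), function(s) {
    mzv <- scanMz[[s]]
    if (is.null(mzv)) {
      m <- matrix(numeric(), ncol = 2L)
    } else {
      o <- order(mzv)
      m <- cbind(mzv[o], scanInt[[s]][o])
    }
    colnames(m) <- c("mz", "intensity")
    m
  })
  h1 <- emptyHeader(nScan)
  h1$scan <- seq_len(nScan)
  h1$msLevel <- 1L
  h1$rt <- t1

  h2 <- emptyHeader(0L)
  ms2Peaks <- list()
  if (config$ms2 && length(live)) {
    fragCache <- new.env(parent = emptyenv())
    lastSel <- rep(-Inf, length(live))
    exclMin <- config$exclusionSec / 60
    ms2rows <- list()
    for (s in seq_len(nScan)) {
      cur <- vapply(seq_along(live), function(k) {
        j <- match(s, monoIdx[[k]])
        if (is.na(j)) 0 else monoVal[[k]][j]
      }, numeric(1))
      elig <- which(cur > max(5 * sigmaN, 1e-12) &
                      (t1[s] - lastSel) > exclMin)
      if (!length(elig)) next
      sel <- elig[order(-cur[elig])][seq_len(min(config$topN, length(elig)))]
      for (q in seq_along(sel)) {
        k <- sel[q]
        i <- live[k]
        lastSel[k] <- t1[s]
        key <- truth$composition[i]
        if (is.null(fragCache[[key]])) {
          fragCache[[key]] <- enumerateFragments(
            parseComposition(key), adduct = config$adduct,
            charge = config$charge, masses = masses)
        }
        fr <- fragCache[[key]]
        prec <- truth$mz_observed[i]
        fmz <- c(fr$mz, prec)
        fint <- c(rep(0.2 * cur[k], nrow(fr)), 0.5 * cur[k])
        o <- order(fmz)
        m <- cbind(fmz[o], fint[o])
        colnames(m) <- c("mz", "intensity")
        ms2Peaks[[length(ms2Peaks) + 1L]] <- m
        ms2rows[[length(ms2rows) + 1L]] <- data.frame(
          scan = NA_integer_, msLevel = 2L,
          rt = t1[s] + q * dtMin / (config$topN + 1),
          precursorMz = prec, precursorCharge = config$charge,
          collisionEnergy = config$ceSlope * prec + config$ceIntercept)
      }
    }
    if (length(ms2rows)) h2 <- do.call(rbind, ms2rows)
  }

  h <- rbind(h1, h2)
  pk <- c(ms1Peaks, ms2Peaks)
  o <- order(h$rt, h$msLevel)
  h <- h[o, , drop = FALSE]
  pk <- pk[o]
  h$scan <- seq_len(nrow(h))
  rownames(h) <- NULL

  truthCols <- c("polysaccharide", "composition", "adduct", "mz",
                 "mz_observed", "rt", "true_area", "area", "conc")
  gt <- truth[, truthCols]
  rownames(gt) <- NULL
  msRun(h, pk, metadata = list(source = "simulateRun", config = config,
                               groundTruth = gt))
}

#' Simulate a calibration dilution series
#'
#' One pooled-standards run per level (every polysaccharide at the
#' level's concentration), with per-run seeds derived from the base
#' seed, plus the calibration design table consumed by the quantitation
#' layer.
#'
#' @param polyNames polysaccharides to include (default all nine).
#' @param levels concentrations in ug/mL, at least 5 distinct positive
#'   values (e.g. six two-fold dilutions from 2000).
#' @param config [simConfig()]; per-run seeds are `seed + level index`.
#' @param polys definitions as in [simulateRun()].
#' @return list with `runs` (list of [MsRun-class], one per level,
#'   named `cal_L<level>`) and `design` (data.frame `polysaccharide`,
#'   `level`, `concentration_ugml`, `run_id`).
#' @export
simulateCalibrationSeries <- function(polyNames = names(simPolysaccharides()),
                                      levels = 2000 / 2^(0:5),
                                      config = simConfig(),
                                      polys = simPolysaccharides()) {
  levels <- sort(unique(as.numeric(levels)), decreasing = TRUE)
  if (length(levels) < 5L) {
    stop("a calibration series needs at least five levels")
  }
  if (any(levels <= 0)) stop("level concentrations must be positive")
  runs <- vector("list", length(levels))
  design <- list()
  for (i in seq_along(levels)) {
    cfg <- config
    cfg$seed <- config$seed + i
    mixture <- stats::setNames(rep(levels[i], length(polyNames)), polyNames)
    runs[[i]] <- simulateRun(mixture, polys = polys, config = cfg)
    design[[i]] <- data.frame(polysaccharide = polyNames, level = i,
                              concentration_ugml = levels[i],
                              run_id = sprintf("cal_L%d", i),
                              stringsAsFactors = FALSE)
  }
  names(runs) <- sprintf("cal_L%d", seq_along(levels))
  list(runs = runs, design = do.call(rbind, design))
}
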