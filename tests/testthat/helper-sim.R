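# Shared fixtures: small simulated systems built in code.

# a fast two-polysaccharide system with well-separated retention
smallDefs <- function() {
  simPolysaccharides()[c("arabinan", "chitin")]
}

quietConfig <- function(seed, ...) {
  simConfig(seed = seed, ms2 = FALSE, ...)
}

# synthetic EIC with a Gaussian peak over an optional noisy baseline
gaussianEIC <- function(area = 1e6, apex = 10, sigma = 0.1,
                        baseline = 0, noiseSd = 0, rtMax = 20,
                        dt = 1 / 0.63 / 60, seed = NULL, targetMz = 500) {
  if (!is.null(seed)) set.seed(seed)
  rt <- seq(0, rtMax, by = dt)
  y <- area * dnorm(rt, apex, sigma) + baseline
  if (noiseSd > 0) y <- pmax(y + rnorm(length(rt), 0, noiseSd), 0)
  new("EIC", targetMz = targetMz, tolerancePpm = 15, rt = rt,
      intensity = y)
}

# library constructed directly from an entries table
makeLibrary <- function(entries, tolerancePpm = 15, rtTolerance = 0.5) {
  new("FingerprintLibrary", entries = entries,
      params = list(tolerancePpm = tolerancePpm,
                    rtTolerance = rtTolerance))
}

libraryEntryRow <- function(polysaccharide, composition, rt, mean_area,
                            adduct = "sodium", unique = TRUE) {
  data.frame(polysaccharide = polysaccharide, composition = composition,
             adduct = adduct,
             mz = mzOf(parseComposition(composition), adduct),
             rt = rt, mean_area = mean_area, unique = unique,
             stringsAsFactors = FALSE)
}
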