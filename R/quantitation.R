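#' CalibrationCurve: zero-intercept external calibration
#'
#' Per-polysaccharide calibration: the quantitation signal at each
#' concentration level is the mean peak area of the polysaccharide's
#' three most abundant unique oligosaccharides (top-3 averaging), and
#' the curve is an equal-weight linear fit through the origin. The
#' method detection limit is the lowest level whose averaged-peak S/N
#' exceeds 3.
#'
#' @slot polysaccharide name
#' @slot top3 character(3), the compositions averaged
#' @slot levels data.frame: `conc` (ug/mL), `area` (mean top-3 area),
#'   `snr` (mean top-3 S/N), `n_top3` (how many of the three were
#'   measurable)
#' @slot slope area per (ug/mL)
#' @slot r2 through-origin coefficient of determination (uncentered
#'   total sum of squares)
#' @slot mdlUgml method detection limit, ug/mL
#' @slot snrAtMdl S/N at the MDL level
#' @aliases CalibrationCurve
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(polysaccharide = "character", top3 = "character",
                 levels = "data.frame", slope = "numeric", r2 = "numeric",
                 mdlUgml = "numeric", snrAtMdl = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (nrow(object@levels) < 5L) return("calibration needs >= 5 levels")
  if (object@slope <= 0) return("slope must be positive")
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  if (!is.na(object@mdlUgml) &&
      !any(abs(object@levels$conc - object@mdlUgml) < 1e-9)) {
    return("mdlUgml must equal one of the level concentrations")
  }
  TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve '%s': top3 = %s\n  slope %.4g, r2 %.4f, MDL %.4g ug/mL (S/N %.2f), %d levels\n",
              object@polysaccharide, paste(object@top3, collapse = ", "),
              object@slope, object@r2, object@mdlUgml, object@snrAtMdl,
              nrow(object@levels)))
})

#' Select the top-3 most abundant library oligosaccharides
#'
#' The three entries of one polysaccharide with the largest library
#' mean area, by default restricted to entries marked unique (shared
#' compositions cannot be attributed to one polysaccharide). The
#' selection is made on the standards' library abundances so the same
#' oligosaccharides are used across all samples and calibration levels.
#' Ties are broken deterministically by lower DP, then lexicographic
#' composition.
#'
#' @param library a [FingerprintLibrary-class].
#' @param polysaccharide name.
#' @param restrictUnique restrict to unique entries (default `TRUE`).
#' @return the 3 selected entry rows (data.frame), most abundant first.
#' @export
selectTop3 <- function(library, polysaccharide, restrictUnique = TRUE) {
  e <- libraryEntries(library)
  e <- e[e$polysaccharide == polysaccharide, , drop = FALSE]
  if (restrictUnique) e <- e[e$unique, , drop = FALSE]
  if (nrow(e) < 3L) {
    stop("fewer than 3 ", if (restrictUnique) "unique " else "",
         "library oligosaccharides for '", polysaccharide,
         "'", if (restrictUnique)
           "; consider restrictUnique = FALSE" else "")
  }
  e$dp <- vapply(e$composition, function(s) dp(parseComposition(s)),
                 integer(1))
  e <- e[order(-e$mean_area, e$dp, e$composition), , drop = FALSE]
  out <- e[1:3, setdiff(names(e), "dp"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a zero-intercept calibration line
#'
#' Equal-weight least squares through the origin:
#' `slope = sum(x*y) / sum(x^2)`;
#' `r2 = 1 - sum((y - slope*x)^2) / sum(y^2)` with the uncentered total
#' sum of squares (the through-origin convention; a centered r2 can be
#' negative through the origin and is nonstandard).
#'
#' @param conc concentrations (>= 5 distinct positive values).
#' @param area measured signals (same length).
#' @return list with `slope` and `r2`.
#' @examples
#' fitCalibration(1:5, 2 * (1:5)) # slope 2, r2 1
#' @export
fitCalibration <- function(conc, area) {
  stopifnot(length(conc) == length(area))
  ok <- !is.na(conc) & !is.na(area)
  conc <- conc[ok]; area <- area[ok]
  if (length(conc) < 5L) {
    stop("calibration requires at least five points")
  }
  if (any(conc <= 0) || anyDuplicated(conc)) {
    stop("concentrations must be distinct and positive")
  }
  if (all(area == 0)) stop("all calibration areas are zero")
  slope <- sum(conc * area) / sum(conc^2)
  r2 <- 1 - sum((area - slope * conc)^2) / sum(area^2)
  if (!is.finite(slope) || !is.finite(r2)) {
    stop("calibration fit is not finite")
  }
  list(slope = slope, r2 = max(0, min(1, r2)))
}

#' Method detection limit from per-level signal-to-noise
#'
#' The MDL is the lowest calibration concentration whose averaged peak
#' S/N exceeds 3 (strictly).
#'
#' @param conc level concentrations (ug/mL).
#' @param snr averaged top-3 peak S/N per level.
#' @param minSnr threshold (default 3).
#' @return list with `mdl_ugml` and `snr_at_mdl`.
#' @export
computeMdl <- function(conc, snr, minSnr = 3) {
  stopifnot(length(conc) == length(snr))
  ok <- which(!is.na(snr) & snr > minSnr)
  if (!length(ok)) {
    stop("no calibration level reaches S/N > ", minSnr,
         "; method detection limit undefined")
  }
  i <- ok[which.min(conc[ok])]
  list(mdl_ugml = conc[i], snr_at_mdl = snr[i])
}

#' Measure the top-3 averaged signal of one polysaccharide in a run
#'
#' Matches the annotated peaks of a sample against the library, keeps
#' the peaks assigned to `polysaccharide` whose compositions belong to
#' its top-3 set, and averages their areas. When one of the three falls
#' below detection the available values are averaged and `n_top3`
#' records how many contributed.
#'
#' @param peaks annotated peak table from [annotateRun()], or an
#'   [MsRun-class] (annotated on the fly).
#' @param library a [FingerprintLibrary-class].
#' @param polysaccharide name.
#' @param top3 optional precomputed [selectTop3()] result.
#' @param rtTolerance minutes (default: library build tolerance).
#' @param ... passed to [annotateRun()] when `peaks` is a run.
#' @return list with `area` (mean of available top-3 areas; 0 when none
#'   detected), `snr` (mean S/N of the contributing peaks, `NA` when
#'   none), `n_top3`.
#' @export
measureTop3 <- function(peaks, library, polysaccharide, top3 = NULL,
                        rtTolerance = NULL, ...) {
  if (is(peaks, "MsRun")) peaks <- annotateRun(peaks, ...)
  if (is.null(top3)) top3 <- selectTop3(library, polysaccharide)
  asg <- matchPeaks(peaks, library, rtTolerance = rtTolerance)
  asg <- asg[asg$polysaccharide == polysaccharide &
               asg$composition %in% top3$composition &
               asg$adduct %in% top3$adduct, , drop = FALSE]
  # one peak per top-3 composition: the best RT match
  vals <- lapply(seq_len(nrow(top3)), function(k) {
    s <- asg[asg$composition == top3$composition[k], , drop = FALSE]
    if (!nrow(s)) return(NULL)
    s[which.min(abs(s$rt_delta)), c("area", "snr")]
  })
  vals <- do.call(rbind, vals)
  if (is.null(vals) || !nrow(vals)) {
    return(list(area = 0, snr = NA_real_, n_top3 = 0L))
  }
  list(area = mean(vals$area), snr = mean(vals$snr),
       n_top3 = nrow(vals))
}

#' Build a calibration curve from measured levels
#'
#' @param polysaccharide name.
#' @param top3 [selectTop3()] result (3 entry rows).
#' @param levels data.frame with `conc`, `area`, `snr` (and optionally
#'   `n_top3`) per calibration level.
#' @param minSnr S/N threshold for the MDL (default 3).
#' @return a [CalibrationCurve-class]. If no level reaches S/N > 3 the
#'   MDL is an error (the curve cannot declare a detection limit).
#' @export
calibrationCurve <- function(polysaccharide, top3, levels, minSnr = 3) {
  fit <- fitCalibration(levels$conc, levels$area)
  mdl <- computeMdl(levels$conc, levels$snr, minSnr = minSnr)
  if (is.null(levels$n_top3)) levels$n_top3 <- NA_integer_
  new("CalibrationCurve", polysaccharide = polysaccharide,
      top3 = top3$composition, levels = levels,
      slope = fit$slope, r2 = fit$r2,
      mdlUgml = mdl$mdl_ugml, snrAtMdl = mdl$snr_at_mdl)
}

#' Quantify a sample signal against a calibration curve
#'
#' Inverts the zero-intercept curve (`conc = area / slope`) and
#' converts to dry-basis and fresh-basis units. Concentrations below
#' the MDL are reported with `below_mdl = TRUE` rather than censored.
#'
#' @param area measured top-3 averaged peak area.
#' @param curve a [CalibrationCurve-class].
#' @param dryLoadingMgPerMl sample dry matter loading (mg dry matter
#'   per mL reacted), default 25.
#' @param moistureFraction fresh-sample moisture fraction in `[0, 1)`.
#' @return one-row data.frame: `polysaccharide`, `conc_ugml`,
#'   `conc_dry_pct`, `conc_fresh_g_per_100g`, `below_mdl`.
#' @export
quantifySignal <- function(area, curve, dryLoadingMgPerMl = 25,
                           moistureFraction = 0) {
  stopifnot(is(curve, "CalibrationCurve"), area >= 0)
  conc <- area / curve@slope
  u <- convertUnits(conc, dryLoadingMgPerMl, moistureFraction)
  data.frame(polysaccharide = curve@polysaccharide, conc_ugml = conc,
             conc_dry_pct = u$dry_pct,
             conc_fresh_g_per_100g = u$fresh_g_per_100g,
             below_mdl = conc < curve@mdlUgml,
             stringsAsFactors = FALSE)
}

#' Convert a solution concentration to dry and fresh sample bases
#'
#' `dry % = conc_ugml / (dryLoading * 1000) * 100` (ug analyte per mg
#' dry matter, as percent by weight) and
#' `fresh g/100 g = dry % * (1 - moisture)`.
#'
#' @param concUgml concentration in ug/mL.
#' @param dryLoadingMgPerMl dry matter loading, mg/mL (> 0; default 25,
#'   the loading connecting ug/mL and % wt/wt dry in the reference
#'   method).
#' @param moistureFraction moisture fraction of the fresh sample,
#'   `0 <= m < 1`.
#' @return list with `dry_pct` and `fresh_g_per_100g`.
#' @examples
#' convertUnits(96, 25)$dry_pct # 0.384
#' @export
convertUnits <- function(concUgml, dryLoadingMgPerMl = 25,
                         moistureFraction = 0) {
  if (!is.numeric(dryLoadingMgPerMl) || dryLoadingMgPerMl <= 0) {
    stop("dry matter loading must be positive")
  }
  if (moistureFraction < 0 || moistureFraction >= 1) {
    stop("moisture fraction must lie in [0, 1)")
  }
  stopifnot(all(concUgml >= 0))
  dry <- concUgml / (dryLoadingMgPerMl * 1000) * 100
  list(dry_pct = dry, fresh_g_per_100g = dry * (1 - moistureFraction))
}

#' Relative quantitation from peak-area fractions
#'
#' Fraction of the total annotated oligosaccharide peak area assigned
#' to each polysaccharide; peaks not matched to any library
#' polysaccharide contribute to `"UNASSIGNED"`. Fractions sum to 1 and
#' are invariant to uniform area scaling.
#'
#' @param assignments data.frame from [matchPeaks()] (needs
#'   `polysaccharide` and `area`).
#' @return named numeric vector of fractions.
#' @export
relativeQuant <- function(assignments) {
  stopifnot(nrow(assignments) >= 1L,
            all(c("polysaccharide", "area") %in% names(assignments)))
  tot <- sum(assignments$area)
  if (tot <= 0) stop("total assigned peak area is zero")
  f <- tapply(assignments$area, assignments$polysaccharide, sum) / tot
  f <- f[order(-f)]
  structure(as.numeric(f), names = names(f))
}

#' Accuracy and precision of replicate measurements
#'
#' Accuracy as percent bias of the replicate mean against the expected
#' concentration; precision as percent coefficient of variation
#' (sample standard deviation over mean) across method replicates.
#'
#' @param measured numeric vector of replicate measured concentrations.
#' @param expected expected (nominal) concentration, > 0.
#' @return list with `bias_pct`, `cv_pct` (`NA` with a warning for a
#'   single replicate), `n_replicates`.
#' @examples
#' validationStats(c(90, 100, 110), 100) # bias 0, cv 10
#' @export
validationStats <- function(measured, expected) {
  if (!is.numeric(expected) || length(expected) != 1L || expected <= 0) {
    stop("expected concentration must be a positive scalar")
  }
  stopifnot(length(measured) >= 1L)
  m <- mean(measured)
  bias <- (m - expected) / expected * 100
  if (length(measured) >= 2L) {
    cv <- stats::sd(measured) / m * 100
  } else {
    warning("coefficient of variation undefined for a single replicate")
    cv <- NA_real_
  }
  list(bias_pct = bias, cv_pct = cv, n_replicates = length(measured))
}

#' Calibration report table
#'
#' One row per fitted curve with r2, slope, MDL in ug/mL and dry-basis
#' percent, and S/N at the MDL.
#'
#' @param curves list of [CalibrationCurve-class] objects.
#' @param dryLoadingMgPerMl dry matter loading used for the dual-unit
#'   MDL column.
#' @return data.frame.
#' @export
curveReport <- function(curves, dryLoadingMgPerMl = 25) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(polysaccharide = cv@polysaccharide,
               r2 = cv@r2, slope = cv@slope,
               mdl_ugml = cv@mdlUgml,
               mdl_dry_pct = convertUnits(cv@mdlUgml,
                                          dryLoadingMgPerMl)$dry_pct,
               snr_at_mdl = cv@snrAtMdl,
               top3 = paste(cv@top3, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
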