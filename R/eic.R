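#' EIC: extracted ion chromatogram
#'
#' Intensity versus retention time for a narrow m/z window across the
#' MS1 scans of a run.
#'
#' @slot targetMz target m/z (Th)
#' @slot tolerancePpm extraction half-window in ppm
#' @slot rt numeric, strictly increasing, minutes
#' @slot intensity numeric, non-negative
#' @aliases EIC
#' @exportClass EIC
setClass("EIC",
  representation(targetMz = "numeric", tolerancePpm = "numeric",
                 rt = "numeric", intensity = "numeric"))

setValidity("EIC", function(object) {
  if (length(object@rt) != length(object@intensity)) {
    return("rt and intensity lengths differ")
  }
  if (length(object@rt) > 1L && any(diff(object@rt) <= 0)) {
    return("rt must be strictly increasing")
  }
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  TRUE
})

setMethod("show", "EIC", function(object) {
  cat(sprintf("EIC m/z %.4f (+/- %g ppm): %d points, RT %.2f-%.2f min, max %.3g\n",
              object@targetMz, object@tolerancePpm, length(object@rt),
              min(object@rt), max(object@rt), max(c(object@intensity, 0))))
})

# All MS1 points of a run as one long table (scan index, rt, mz,
# intensity), sorted by m/z for windowed lookups.
ms1Points <- function(run) {
  h <- scanHeader(run)
  idx <- which(h$msLevel == 1L)
  if (!length(idx)) stop("run contains no MS1 scans")
  np <- vapply(idx, function(i) nrow(peaksOf(run, i)), integer(1))
  mz <- numeric(sum(np)); int <- numeric(sum(np))
  pos <- 0L
  for (i in seq_along(idx)) {
    if (np[i] == 0L) next
    p <- peaksOf(run, idx[i])
    mz[pos + seq_len(np[i])] <- p[, 1L]
    int[pos + seq_len(np[i])] <- p[, 2L]
    pos <- pos + np[i]
  }
  list(scanIdx = rep(seq_along(idx), np), rt = h$rt[idx],
       mz = mz, intensity = int, ord = order(mz))
}

# Vectorized multi-target extraction sharing one point table.
extractEICsFromPoints <- function(pts, targetMzs, tolerancePpm) {
  mzs <- pts$mz[pts$ord]
  ints <- pts$intensity[pts$ord]
  scans <- pts$scanIdx[pts$ord]
  nScan <- length(pts$rt)
  lapply(targetMzs, function(t) {
    tol <- t * tolerancePpm * 1e-6
    lo <- findInterval(t - tol, mzs) + 1L
    hi <- findInterval(t + tol, mzs)
    y <- numeric(nScan)
    if (hi >= lo) {
      sel <- lo:hi
      agg <- rowsum(ints[sel], scans[sel])
      y[as.integer(rownames(agg))] <- agg[, 1L]
    }
    new("EIC", targetMz = t, tolerancePpm = tolerancePpm,
        rt = pts$rt, intensity = y)
  })
}

#' Extract an ion chromatogram
#'
#' Per MS1 scan, the intensity is the sum of all points within
#' `targetMz * (1 +/- tolerancePpm * 1e-6)`; scans with no point in the
#' window contribute zero.
#'
#' @param run an [MsRun-class] with MS1 scans.
#' @param targetMz target m/z (Th).
#' @param tolerancePpm half-window in ppm.
#' @param rtWindow optional `c(min, max)` retention-time restriction in
#'   minutes.
#' @return an [EIC-class].
#' @export
extractEIC <- function(run, targetMz, tolerancePpm = 15, rtWindow = NULL) {
  stopifnot(is.numeric(targetMz), length(targetMz) == 1L, targetMz > 0,
            tolerancePpm > 0)
  pts <- ms1Points(run)
  eic <- extractEICsFromPoints(pts, targetMz, tolerancePpm)[[1]]
  if (!is.null(rtWindow)) {
    keep <- eic@rt >= rtWindow[1] & eic@rt <= rtWindow[2]
    eic <- new("EIC", targetMz = eic@targetMz,
               tolerancePpm = eic@tolerancePpm,
               rt = eic@rt[keep], intensity = eic@intensity[keep])
  }
  eic
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

emptyPeakTable <- function() {
  data.frame(apex_rt = numeric(), rt_start = numeric(), rt_end = numeric(),
             area = numeric(), height = numeric(), snr = numeric())
}

#' Detect and integrate chromatographic peaks in an EIC
#'
#' Deterministic automated integration. The baseline level is the
#' median intensity and the noise scale is the MAD (scaled to be
#' consistent with a Gaussian sigma). Candidate peak regions are
#' contiguous runs above baseline + 1 sigma containing at least
#' `minPoints` samples and an apex above baseline + `minSnr` sigma;
#' regions with several well-separated maxima (valley below half the
#' smaller apex, above baseline) are split at the valley minimum.
#' Areas are baseline-subtracted trapezoidal integrals between the
#' region boundaries; the signal-to-noise ratio of each peak is
#' estimated with [estimateSnr()] on peak-free flanking windows, and
#' peaks below `minSnr` are dropped. Peaks are returned sorted by apex
#' retention time with non-overlapping boundaries.
#'
#' @param eic an [EIC-class] with at least `minPoints` samples.
#' @param minSnr minimum signal-to-noise ratio to report (default 3).
#' @param minPoints minimum samples across a peak (default 5).
#' @param maxSnr cap for the noiseless case (default 1e6).
#' @return data.frame with columns `apex_rt`, `rt_start`, `rt_end`,
#'   `area`, `height`, `snr`; zero rows when nothing qualifies.
#' @export
detectPeaks <- function(eic, minSnr = 3, minPoints = 5, maxSnr = 1e6) {
  y <- eic@intensity
  x <- eic@rt
  n <- length(y)
  if (n < minPoints) stop("EIC has fewer than minPoints samples")
  if (all(y <= 0)) return(emptyPeakTable())
  # peak geometry (regions, apexes, valleys) is decided on a lightly
  # smoothed trace so single-sample noise excursions neither split nor
  # truncate peaks; integration uses the raw trace
  w <- 5L
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  b <- stats::median(ys)
  sigma <- stats::mad(y)
  if (sigma == 0) {
    eps <- 1e-9 * max(y)
    thrLow <- b + eps
    thrHigh <- b + eps
  } else {
    thrLow <- b + 0.5 * sigma
    thrHigh <- b + minSnr * sigma
  }
  above <- ys > thrLow
  r <- rle(above)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  regions <- cbind(startIdx[r$values], endIdx[r$values])
  if (!nrow(regions)) return(emptyPeakTable())
  keep <- (regions[, 2L] - regions[, 1L] + 1L) >= minPoints
  regions <- regions[keep, , drop = FALSE]
  if (!nrow(regions)) return(emptyPeakTable())

  splitRegion <- function(lo, hi) {
    yy <- ys[lo:hi]
    m <- length(yy)
    isMax <- rep(FALSE, m)
    if (m >= 3L) {
      isMax[2:(m - 1L)] <- yy[2:(m - 1L)] >= yy[1:(m - 2L)] &
        yy[2:(m - 1L)] > yy[3:m]
    }
    apexes <- which(isMax & yy > thrHigh)
    if (!length(apexes)) apexes <- which.max(yy)
    if (length(apexes) > 1L) {
      merged <- apexes[1]
      for (a in apexes[-1]) {
        prev <- merged[length(merged)]
        valley <- min(yy[prev:a])
        if ((valley - b) < 0.5 * (min(yy[prev], yy[a]) - b)) {
          merged <- c(merged, a)
        } else if (yy[a] > yy[prev]) {
          merged[length(merged)] <- a
        }
      }
      apexes <- merged
    }
    if (length(apexes) == 1L) {
      return(cbind(lo, hi, lo + apexes - 1L))
    }
    bounds <- vapply(seq_len(length(apexes) - 1L), function(k) {
      seg <- apexes[k]:apexes[k + 1L]
      seg[which.min(yy[seg])]
    }, integer(1))
    lows <- c(1L, bounds)
    highs <- c(bounds, m)
    cbind(lo + lows - 1L, lo + highs - 1L, lo + apexes - 1L)
  }

  parts <- do.call(rbind, lapply(seq_len(nrow(regions)), function(k)
    splitRegion(regions[k, 1L], regions[k, 2L])))
  parts <- parts[ys[parts[, 3L]] > thrHigh, , drop = FALSE]
  if (!nrow(parts)) return(emptyPeakTable())

  allSpans <- data.frame(rt_start = x[parts[, 1L]], rt_end = x[parts[, 2L]])
  pk <- do.call(rbind, lapply(seq_len(nrow(parts)), function(k) {
    lo <- parts[k, 1L]; hi <- parts[k, 2L]; ap <- parts[k, 3L]
    area <- trapz(x[lo:hi], pmax(y[lo:hi] - b, 0))
    height <- y[ap] - b
    if (area <= 0 || height <= 0) return(NULL)
    peak <- data.frame(apex_rt = x[ap], rt_start = x[lo], rt_end = x[hi],
                       area = area, height = height, snr = NA_real_)
    peak$snr <- tryCatch(
      estimateSnr(eic, peak, exclude = allSpans, maxSnr = maxSnr),
      error = function(e) maxSnr)
    peak
  }))
  if (is.null(pk)) return(emptyPeakTable())
  pk <- pk[pk$snr >= minSnr, , drop = FALSE]
  pk <- pk[order(pk$apex_rt), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Estimate the signal-to-noise ratio of a chromatographic peak
#'
#' Noise is `1.4826 * MAD` of the intensities in flanking baseline
#' windows of width `flankMin` minutes on either side of the peak,
#' after removing samples inside any span listed in `exclude` (e.g.
#' other detected peaks). S/N is the peak height divided by that noise
#' scale, capped at `maxSnr` when the baseline is exactly quiet.
#'
#' @param eic an [EIC-class].
#' @param peak one-row data.frame with `rt_start`, `rt_end`, `height`
#'   (as produced by [detectPeaks()]).
#' @param exclude optional data.frame of `rt_start`/`rt_end` spans to
#'   drop from the baseline windows.
#' @param flankMin baseline window width, minutes (default 1).
#' @param maxSnr value reported when the estimated noise is zero.
#' @return dimensionless S/N.
#' @export
estimateSnr <- function(eic, peak, exclude = NULL, flankMin = 1,
                        maxSnr = 1e6) {
  x <- eic@rt
  y <- eic@intensity
  if (peak$rt_start < min(x) - 1e-9 || peak$rt_end > max(x) + 1e-9) {
    stop("peak lies outside the EIC retention-time range")
  }
  inFlank <- (x >= peak$rt_start - flankMin & x < peak$rt_start) |
    (x > peak$rt_end & x <= peak$rt_end + flankMin)
  if (!is.null(exclude) && nrow(exclude)) {
    for (k in seq_len(nrow(exclude))) {
      inFlank <- inFlank &
        !(x >= exclude$rt_start[k] & x <= exclude$rt_end[k])
    }
  }
  base <- y[inFlank]
  if (!length(base)) {
    stop("no baseline samples available in the flanking windows")
  }
  noise <- stats::mad(base)
  if (noise == 0) return(maxSnr)
  min(peak$height / noise, maxSnr)
}
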