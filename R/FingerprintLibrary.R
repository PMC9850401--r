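#' FingerprintLibrary: oligosaccharide fingerprints of polysaccharides
#'
#' Catalogue of (polysaccharide, composition, adduct, m/z, retention
#' time, mean area) records built from depolymerized polysaccharide
#' standards. An entry is `unique` when no other polysaccharide has an
#' entry at the same m/z (within ppm tolerance) and retention time
#' (within RT tolerance); only unique entries identify their parent
#' polysaccharide unambiguously (starch and cellulose share Hex-series
#' compositions and differ only in retention on porous graphitized
#' carbon).
#'
#' @slot entries data.frame with columns `polysaccharide`,
#'   `composition`, `adduct`, `mz`, `rt`, `mean_area`, `unique`
#' @slot params list with the matching tolerances used at build time
#' @aliases FingerprintLibrary
#' @exportClass FingerprintLibrary
setClass("FingerprintLibrary",
  representation(entries = "data.frame", params = "list"),
  prototype(params = list(tolerancePpm = 15, rtTolerance = 0.5)))

libraryColumns <- c("polysaccharide", "composition", "adduct", "mz", "rt",
                    "mean_area", "unique")

setValidity("FingerprintLibrary", function(object) {
  e <- object@entries
  if (!all(libraryColumns %in% names(e))) {
    return(paste("entries must contain:", paste(libraryColumns, collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(e$rt <= 0)) return("entry rt must be > 0")
    if (any(e$mean_area <= 0)) return("entry mean_area must be > 0")
    key <- paste(e$polysaccharide, e$composition, e$adduct,
                 round(e$rt, 6))
    if (anyDuplicated(key)) {
      return("duplicate (composition, rt) entry within a polysaccharide")
    }
  }
  TRUE
})

setMethod("show", "FingerprintLibrary", function(object) {
  e <- object@entries
  cat(sprintf("FingerprintLibrary: %d entries, %d polysaccharides, %d unique\n",
              nrow(e), length(unique(e$polysaccharide)), sum(e$unique)))
})

#' @rdname libraryEntries
#' @export
setGeneric("libraryEntries", function(x) standardGeneric("libraryEntries"))
#' Entries of a fingerprint library
#' @param x a [FingerprintLibrary-class].
#' @return the entries data.frame.
#' @export
setMethod("libraryEntries", "FingerprintLibrary", function(x) x@entries)

#' @export
setMethod("length", "FingerprintLibrary", function(x) nrow(x@entries))

#' Annotate all oligosaccharide peaks of a run
#'
#' Front end joining the annotation and chromatography layers. MS1
#' point clouds are collapsed into m/z channels (gap-based grouping at
#' the ppm tolerance), isotopologue channels (+1.00336/z above a more
#' intense channel) are removed so that only monoisotopic traces are
#' quantified, channels are annotated with [annotatePrecursor()], and
#' each annotatable channel's EIC is integrated with [detectPeaks()].
#' When the run carries MS2 scans, each peak is given the
#' fragment-coverage score of the MS2 spectrum acquired nearest its
#' apex ([scoreMsms()]); peaks without an MS2 scan score `NA`.
#'
#' @param run an [MsRun-class].
#' @param tolerancePpm m/z tolerance (ppm) for channels, annotation and
#'   EIC extraction.
#' @param bounds,adducts,reduced,masses see [annotatePrecursor()].
#' @param minSnr,minPoints see [detectPeaks()].
#' @param msmsScoreMin drop peaks whose MS2 score is below this (peaks
#'   with no MS2 spectrum are kept); default 0 keeps everything.
#' @return data.frame with one row per annotated chromatographic peak:
#'   `channel_mz`, `composition`, `adduct`, `theoretical_mz`,
#'   `ppm_error`, `apex_rt`, `rt_start`, `rt_end`, `area`, `height`,
#'   `snr`, `msms_score`.
#' @export
annotateRun <- function(run, tolerancePpm = 15,
                        bounds = annotationBounds(),
                        adducts = c("sodium", "proton", "ammonium"),
                        reduced = TRUE, minSnr = 3, minPoints = 5,
                        msmsScoreMin = 0, masses = residueMasses()) {
  pts <- ms1Points(run)
  ch <- mzChannels(pts, tolerancePpm)
  ch <- deisotopeChannels(ch, tolerancePpm)
  red <- if (is.na(reduced)) c(TRUE, FALSE) else as.logical(reduced)
  grid <- do.call(rbind, lapply(red, function(r)
    compositionGrid(bounds, reduced = r, masses = masses)))
  ann <- lapply(ch$mz, function(m) {
    cand <- annotatePrecursor(m, charge = 1L, tolerancePpm = tolerancePpm,
                              bounds = bounds, adducts = adducts,
                              masses = masses, grid = grid)
    if (nrow(cand)) utils::head(cand, 8L) else NULL
  })
  keep <- !vapply(ann, is.null, logical(1))
  if (!any(keep)) return(emptyAnnotatedPeaks())
  ch <- ch[keep, , drop = FALSE]
  ann <- ann[keep]
  eics <- extractEICsFromPoints(pts, ch$mz, tolerancePpm)
  h <- scanHeader(run)
  ms2 <- which(h$msLevel == 2L & !is.na(h$precursorMz))
  out <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    pk <- detectPeaks(eics[[i]], minSnr = minSnr, minPoints = minPoints)
    if (!nrow(pk)) next
    cand <- ann[[i]]
    pk$channel_mz <- ch$mz[i]
    # best-ppm candidate by default; a fragment spectrum acquired on
    # the peak re-ranks the candidates (composition-level tandem MS is
    # what disambiguates isobaric-within-tolerance candidates)
    pk$composition <- cand$composition[1L]
    pk$adduct <- cand$adduct[1L]
    pk$theoretical_mz <- cand$theoretical_mz[1L]
    pk$ppm_error <- cand$ppm_error[1L]
    pk$msms_score <- NA_real_
    if (length(ms2)) {
      near <- ms2[abs(h$precursorMz[ms2] - ch$mz[i]) / ch$mz[i] * 1e6 <=
                    tolerancePpm]
      for (k in seq_len(nrow(pk))) {
        inPk <- near[h$rt[near] >= pk$rt_start[k] &
                       h$rt[near] <= pk$rt_end[k]]
        if (!length(inPk)) next
        best <- inPk[which.min(abs(h$rt[inPk] - pk$apex_rt[k]))]
        sp <- peaksOf(run, best)
        if (!nrow(sp)) next
        scores <- vapply(seq_len(nrow(cand)), function(cc) {
          comp <- parseComposition(cand$composition[cc])
          if (dp(comp) < 2L) return(0)
          scoreMsms(sp[, 1L], sp[, 2L], comp, adduct = cand$adduct[cc],
                    charge = 1L, tolerancePpm = tolerancePpm,
                    masses = masses)
        }, numeric(1))
        pick <- order(-scores, abs(cand$ppm_error), cand$n_classes,
                      cand$dp)[1L]
        pk$composition[k] <- cand$composition[pick]
        pk$adduct[k] <- cand$adduct[pick]
        pk$theoretical_mz[k] <- cand$theoretical_mz[pick]
        pk$ppm_error[k] <- cand$ppm_error[pick]
        pk$msms_score[k] <- scores[pick]
      }
    }
    out[[i]] <- pk
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(emptyAnnotatedPeaks())
  res <- res[is.na(res$msms_score) | res$msms_score >= msmsScoreMin, ,
             drop = FALSE]
  cols <- c("channel_mz", "composition", "adduct", "theoretical_mz",
            "ppm_error", "apex_rt", "rt_start", "rt_end", "area",
            "height", "snr", "msms_score")
  res <- res[order(res$channel_mz, res$apex_rt), cols, drop = FALSE]
  rownames(res) <- NULL
  res
}

emptyAnnotatedPeaks <- function() {
  data.frame(channel_mz = numeric(), composition = character(),
             adduct = character(), theoretical_mz = numeric(),
             ppm_error = numeric(), apex_rt = numeric(),
             rt_start = numeric(), rt_end = numeric(), area = numeric(),
             height = numeric(), snr = numeric(), msms_score = numeric(),
             stringsAsFactors = FALSE)
}

# Collapse the MS1 point cloud into m/z channels: consecutive sorted
# m/z values are grouped while gaps stay below the ppm tolerance;
# channel m/z is the intensity-weighted mean.
mzChannels <- function(pts, tolerancePpm) {
  mzs <- pts$mz[pts$ord]
  ints <- pts$intensity[pts$ord]
  if (!length(mzs)) return(data.frame(mz = numeric(), maxInt = numeric()))
  newGrp <- c(TRUE, diff(mzs) > mzs[-length(mzs)] * tolerancePpm * 1e-6)
  grp <- cumsum(newGrp)
  w <- rowsum(ints, grp)[, 1L]
  wm <- rowsum(ints * mzs, grp)[, 1L]
  mx <- vapply(split(ints, grp), max, numeric(1))
  mz <- ifelse(w > 0, wm / w,
               vapply(split(mzs, grp), stats::median, numeric(1)))
  data.frame(mz = mz, maxInt = mx)[order(mz), , drop = FALSE]
}

# Drop channels sitting one to three isotope spacings above another
# channel of comparable or greater intensity (monoisotopic-trace
# policy, singly charged). The ratio floor accommodates
# high-carbon-number oligosaccharides whose +1 isotopologue exceeds
# the monoisotopic peak.
deisotopeChannels <- function(ch, tolerancePpm, spacing = 1.0033548,
                              ratioFloor = 0.4) {
  if (nrow(ch) < 2L) return(ch)
  drop <- logical(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    for (k in 1:3) {
      ref <- ch$mz[i] - k * spacing
      j <- which(abs(ch$mz - ref) <= ch$mz * tolerancePpm * 1e-6)
      if (length(j) && any(ch$maxInt[j] > ratioFloor * ch$maxInt[i])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  ch[!drop, , drop = FALSE]
}

#' Build a fingerprint library from polysaccharide standard runs
#'
#' Each standard run is annotated with [annotateRun()]; the qualifying
#' peaks of a polysaccharide's replicate runs are pooled by
#' (composition, adduct) and clustered in retention time at
#' `rtTolerance`, giving one library entry per cluster with
#' area-weighted mean retention time and per-run mean area. After
#' pooling, entries of different polysaccharides that collide in both
#' m/z (within `tolerancePpm`) and retention time (within
#' `rtTolerance`) are flagged `unique = FALSE`.
#'
#' @param standardRuns named list (names are polysaccharide names);
#'   each element an [MsRun-class], a file path, or a list of those
#'   (replicate runs).
#' @param tolerancePpm m/z tolerance in ppm.
#' @param rtTolerance retention-time tolerance in minutes (default 0.5,
#'   about twice a typical PGC peak width).
#' @param ... further arguments to [annotateRun()].
#' @return a [FingerprintLibrary-class].
#' @export
buildLibrary <- function(standardRuns, tolerancePpm = 15, rtTolerance = 0.5,
                         ...) {
  stopifnot(is.list(standardRuns), length(standardRuns) >= 1L,
            !is.null(names(standardRuns)), all(nzchar(names(standardRuns))))
  entries <- vector("list", length(standardRuns))
  for (p in seq_along(standardRuns)) {
    poly <- names(standardRuns)[p]
    reps <- standardRuns[[p]]
    if (!is.list(reps) || is(reps, "MsRun")) reps <- list(reps)
    nRep <- length(reps)
    pk <- do.call(rbind, lapply(reps, function(rn) {
      if (is.character(rn)) rn <- readRun(rn)
      annotateRun(rn, tolerancePpm = tolerancePpm, ...)
    }))
    if (is.null(pk) || !nrow(pk)) {
      stop("no qualifying oligosaccharide peaks for polysaccharide '",
           poly, "'")
    }
    key <- split(seq_len(nrow(pk)), paste(pk$composition, pk$adduct))
    ent <- do.call(rbind, lapply(key, function(idx) {
      sub <- pk[idx, , drop = FALSE]
      sub <- sub[order(sub$apex_rt), , drop = FALSE]
      cl <- cumsum(c(TRUE, diff(sub$apex_rt) > rtTolerance))
      do.call(rbind, lapply(split(seq_len(nrow(sub)), cl), function(ii) {
        s <- sub[ii, , drop = FALSE]
        data.frame(polysaccharide = poly,
                   composition = s$composition[1],
                   adduct = s$adduct[1],
                   mz = stats::weighted.mean(s$theoretical_mz, s$area),
                   rt = stats::weighted.mean(s$apex_rt, s$area),
                   mean_area = sum(s$area) / nRep,
                   unique = TRUE, stringsAsFactors = FALSE)
      }))
    }))
    entries[[p]] <- ent
  }
  e <- do.call(rbind, entries)
  rownames(e) <- NULL
  # cross-polysaccharide collision marking
  if (nrow(e) > 1L) {
    for (i in seq_len(nrow(e) - 1L)) {
      j <- (i + 1L):nrow(e)
      hit <- j[e$polysaccharide[j] != e$polysaccharide[i] &
                 abs(e$mz[j] - e$mz[i]) <= e$mz[i] * tolerancePpm * 1e-6 &
                 abs(e$rt[j] - e$rt[i]) <= rtTolerance]
      if (length(hit)) {
        e$unique[c(i, hit)] <- FALSE
      }
    }
  }
  new("FingerprintLibrary", entries = e,
      params = list(tolerancePpm = tolerancePpm, rtTolerance = rtTolerance))
}

#' Assign annotated sample peaks to polysaccharides
#'
#' Each annotated peak is matched against library entries with the same
#' composition and adduct; it is assigned to the entry with the
#' smallest absolute retention-time difference within `rtTolerance`.
#' Exact ties between entries of different polysaccharides go to the
#' entry with the larger library mean area, with a warning. Peaks that
#' match no entry are labelled `"UNASSIGNED"` (annotated
#' oligosaccharides not traceable to a library polysaccharide). Every
#' input peak yields exactly one assignment row; the result is
#' independent of input row order (rows are returned in input order).
#'
#' @param peaks data.frame from [annotateRun()].
#' @param library a [FingerprintLibrary-class].
#' @param rtTolerance minutes; defaults to the library's build-time
#'   tolerance.
#' @return `peaks` with added columns `polysaccharide`, `rt_delta`,
#'   `library_rt`.
#' @export
matchPeaks <- function(peaks, library, rtTolerance = NULL) {
  stopifnot(is(library, "FingerprintLibrary"))
  e <- libraryEntries(library)
  if (!nrow(e)) stop("fingerprint library is empty")
  if (is.null(rtTolerance)) rtTolerance <- library@params$rtTolerance
  peaks$polysaccharide <- "UNASSIGNED"
  peaks$rt_delta <- NA_real_
  peaks$library_rt <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    cand <- which(e$composition == peaks$composition[i] &
                    e$adduct == peaks$adduct[i])
    if (!length(cand)) next
    delta <- peaks$apex_rt[i] - e$rt[cand]
    ok <- abs(delta) <= rtTolerance
    if (!any(ok)) next
    cand <- cand[ok]; delta <- delta[ok]
    best <- which(abs(abs(delta) - min(abs(delta))) < 1e-9)
    if (length(best) > 1L) {
      pick <- best[which.max(e$mean_area[cand[best]])]
      if (length(unique(e$polysaccharide[cand[best]])) > 1L) {
        warning("peak at RT ", format(peaks$apex_rt[i], digits = 4),
                " (", peaks$composition[i], ") is equidistant between ",
                "entries of ",
                paste(unique(e$polysaccharide[cand[best]]), collapse = ", "),
                "; assigned to the more abundant library entry")
      }
    } else {
      pick <- best
    }
    peaks$polysaccharide[i] <- e$polysaccharide[cand[pick]]
    peaks$rt_delta[i] <- delta[pick]
    peaks$library_rt[i] <- e$rt[cand[pick]]
  }
  peaks
}

#' Write / read a fingerprint library
#'
#' TSV with the fixed header `polysaccharide composition adduct mz rt
#' mean_area unique`, or JSON with the identical schema (chosen by file
#' extension). Round-trips exactly.
#'
#' @param library a [FingerprintLibrary-class].
#' @param path file path ending in `.tsv` or `.json`.
#' @return `writeLibrary`: `path` invisibly; `readLibrary`: the
#'   library.
#' @export
writeLibrary <- function(library, path) {
  e <- libraryEntries(library)[, libraryColumns, drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(params = library@params, entries = e), path,
                         digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    e <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
    if (!nrow(e)) e <- emptyLibraryEntries()
    if (!identical(sort(names(e)), sort(libraryColumns))) {
      stop("library JSON schema mismatch in ", path)
    }
    params <- obj$params
  } else {
    hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    if (!identical(hdr, libraryColumns)) {
      stop("library header mismatch in ", path, " (line 1)")
    }
    e <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric", "numeric",
                                          "numeric", "logical"))
    params <- list(tolerancePpm = 15, rtTolerance = 0.5)
  }
  for (i in seq_len(nrow(e))) {
    tryCatch(parseComposition(e$composition[i]), error = function(err) {
      stop("unparseable composition at ", path, " line ", i + 1L, ": ",
           conditionMessage(err))
    })
    if (is.na(e$unique[i]) || is.na(e$mz[i]) || is.na(e$rt[i]) ||
        is.na(e$mean_area[i])) {
      stop("corrupted library row at ", path, " line ", i + 1L)
    }
  }
  new("FingerprintLibrary", entries = e, params = as.list(params))
}

emptyLibraryEntries <- function() {
  data.frame(polysaccharide = character(), composition = character(),
             adduct = character(), mz = numeric(), rt = numeric(),
             mean_area = numeric(), unique = logical(),
             stringsAsFactors = FALSE)
}
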