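#' MsRun: an LC-MS run held in memory
#'
#' Container for the spectra of one LC-MS acquisition. The header is a
#' data.frame with one row per spectrum (`scan`, `msLevel`, `rt` in
#' minutes, `precursorMz`, `precursorCharge`, `collisionEnergy`; the
#' precursor columns are `NA` for MS1 scans); `peaks` holds one
#' two-column matrix (`mz`, `intensity`) per spectrum, m/z sorted
#' ascending. `metadata` carries provenance and, for simulated runs,
#' the ground-truth table.
#'
#' @slot header data.frame as described above
#' @slot peaks list of numeric matrices
#' @slot metadata list
#' @aliases MsRun
#' @exportClass MsRun
setClass("MsRun",
  representation(header = "data.frame", peaks = "list", metadata = "list"),
  prototype(metadata = list())
)

setValidity("MsRun", function(object) {
  h <- object@header
  need <- c("scan", "msLevel", "rt", "precursorMz", "precursorCharge",
            "collisionEnergy")
  if (!all(need %in% names(h))) {
    return(paste("header must contain:", paste(need, collapse = ", ")))
  }
  if (nrow(h) != length(object@peaks)) {
    return("header rows and peaks list length differ")
  }
  if (nrow(h) && (anyNA(h$rt) || any(h$rt < 0))) {
    return("retention times must be non-negative")
  }
  for (i in seq_along(object@peaks)) {
    p <- object@peaks[[i]]
    if (!is.matrix(p) || ncol(p) != 2L) {
      return(sprintf("peaks[[%d]] is not a two-column matrix", i))
    }
    if (nrow(p) > 1L && is.unsorted(p[, 1L])) {
      return(sprintf("peaks[[%d]] m/z not sorted ascending", i))
    }
  }
  TRUE
})

msRun <- function(header, peaks, metadata = list()) {
  new("MsRun", header = header, peaks = peaks, metadata = metadata)
}

#' @rdname MsRun-accessors
#' @export
setGeneric("nScans", function(x) standardGeneric("nScans"))
#' Accessors for MsRun
#'
#' @param x an [MsRun-class].
#' @param i spectrum index.
#' @return `nScans`: number of spectra; `scanHeader`: the header
#'   data.frame; `peaksOf`: the m/z-intensity matrix of spectrum `i`;
#'   `groundTruth`: the simulator truth table or `NULL`.
#' @name MsRun-accessors
#' @export
setMethod("nScans", "MsRun", function(x) nrow(x@header))

#' @rdname MsRun-accessors
#' @export
setGeneric("scanHeader", function(x) standardGeneric("scanHeader"))
#' @rdname MsRun-accessors
#' @export
setMethod("scanHeader", "MsRun", function(x) x@header)

#' @rdname MsRun-accessors
#' @export
setGeneric("peaksOf", function(x, i) standardGeneric("peaksOf"))
#' @rdname MsRun-accessors
#' @export
setMethod("peaksOf", "MsRun", function(x, i) x@peaks[[i]])

#' @rdname MsRun-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname MsRun-accessors
#' @export
setMethod("groundTruth", "MsRun", function(x) x@metadata$groundTruth)

setMethod("show", "MsRun", function(object) {
  h <- object@header
  cat(sprintf("MsRun: %d spectra (%d MS1, %d MS2), RT %.2f-%.2f min\n",
              nrow(h), sum(h$msLevel == 1L), sum(h$msLevel == 2L),
              if (nrow(h)) min(h$rt) else NA, if (nrow(h)) max(h$rt) else NA))
  if (!is.null(object@metadata$source)) {
    cat("  source:", object@metadata$source, "\n")
  }
  if (!is.null(groundTruth(object))) {
    cat("  ground truth:", nrow(groundTruth(object)), "oligosaccharides\n")
  }
})

emptyHeader <- function(n = 0L) {
  data.frame(scan = integer(n), msLevel = integer(n), rt = numeric(n),
             precursorMz = rep(NA_real_, n),
             precursorCharge = rep(NA_integer_, n),
             collisionEnergy = rep(NA_real_, n))
}

#' Read an LC-MS run from mzML or MGF
#'
#' mzML files (standard 1.1.0) are read through `mzR`; retention times
#' are converted from seconds to minutes. MGF files yield MS2-only
#' records per the Mascot Generic Format conventions (BEGIN IONS /
#' END IONS blocks with PEPMASS, RTINSECONDS, CHARGE).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mzML"` or `"mgf"`.
#' @return an [MsRun-class].
#' @export
readRun <- function(path, format = c("auto", "mzML", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzML", mgf = "mgf",
                     stop("cannot infer format from extension: ", path))
  }
  if (format == "mzML") readMzML(path) else readMGF(path)
}

readMzML <- function(path) {
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("failed to parse mzML '", path,
                                          "': ", conditionMessage(e)))
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  n <- nrow(hd)
  pk <- if (n) mzR::peaks(fh) else list()
  if (n == 1L && is.matrix(pk)) pk <- list(pk)
  pk <- lapply(seq_len(n), function(i) {
    p <- pk[[i]]
    if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
    colnames(p) <- c("mz", "intensity")
    p[order(p[, 1L]), , drop = FALSE]
  })
  h <- emptyHeader(n)
  if (n) {
    h$scan <- hd$seqNum
    h$msLevel <- as.integer(hd$msLevel)
    h$rt <- hd$retentionTime / 60
    pm <- hd$precursorMZ
    pm[h$msLevel == 1L | pm == 0] <- NA_real_
    h$precursorMz <- pm
    pc <- as.integer(hd$precursorCharge)
    pc[h$msLevel == 1L | pc == 0L] <- NA_integer_
    h$precursorCharge <- pc
    ce <- hd$collisionEnergy
    ce[h$msLevel == 1L | ce == 0] <- NA_real_
    h$collisionEnergy <- ce
  }
  msRun(h, pk, metadata = list(source = path, format = "mzML"))
}

readMGF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) ||
      (length(starts) && any(ends < starts))) {
    stop("malformed MGF '", path, "': unbalanced BEGIN/END IONS near block ",
         length(ends) + 1L)
  }
  n <- length(starts)
  h <- emptyHeader(n)
  pk <- vector("list", n)
  for (b in seq_len(n)) {
    blk <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", blk, fixed = TRUE)
    meta <- blk[kv]
    getv <- function(key) {
      hit <- grep(paste0("^", key, "="), meta, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    pep <- getv("PEPMASS")
    rts <- getv("RTINSECONDS")
    chg <- getv("CHARGE")
    dat <- blk[!kv & nzchar(trimws(blk))]
    m <- do.call(rbind, lapply(dat, function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
      if (length(v) < 2L || anyNA(v[1:2])) {
        stop("malformed MGF '", path, "': bad peak line in block ", b,
             ": '", ln, "'")
      }
      v[1:2]
    }))
    if (is.null(m)) m <- matrix(numeric(), ncol = 2L)
    colnames(m) <- c("mz", "intensity")
    h$scan[b] <- b
    h$msLevel[b] <- 2L
    h$rt[b] <- if (is.na(rts)) 0 else as.numeric(rts) / 60
    h$precursorMz[b] <- if (is.na(pep)) NA_real_ else
      as.numeric(strsplit(pep, "[ \t]+")[[1]][1])
    h$precursorCharge[b] <- if (is.na(chg)) NA_integer_ else
      as.integer(sub("\\+$", "", chg))
    pk[[b]] <- m[order(m[, 1L]), , drop = FALSE]
  }
  msRun(h, pk, metadata = list(source = path, format = "mgf"))
}

#' Write the MS2 scans of a run as MGF
#'
#' @param run an [MsRun-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(run, path) {
  h <- scanHeader(run)
  idx <- which(h$msLevel == 2L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in idx) {
    p <- peaksOf(run, i)
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=scan=%d", h$scan[i]),
      sprintf("PEPMASS=%.6f", h$precursorMz[i]),
      sprintf("CHARGE=%d+",
              ifelse(is.na(h$precursorCharge[i]), 1L, h$precursorCharge[i])),
      sprintf("RTINSECONDS=%.4f", h$rt[i] * 60),
      sprintf("%.6f %.6f", p[, 1L], p[, 2L]),
      "END IONS", ""), con)
  }
  invisible(path)
}
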