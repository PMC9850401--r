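#' Combinatorial bounds for composition enumeration
#'
#' Limits on the exhaustive composition search used by
#' [annotatePrecursor()]. Defaults reflect positive-mode PGC glycomics
#' of plant and fungal polysaccharide depolymerization products: DP up
#' to 25 (starch series reach DP 21), at most 3 hexuronic acids with
#' O-methyl count bounded by the hexuronic acid count, and
#' N-acetylhexosamine occurring only as a homo-series (chitin-type
#' oligomers), which keeps the search space well under 1e5 candidates.
#'
#' @param maxDp maximum degree of polymerization.
#' @param maxHex,maxPnt,maxHxa,maxHexNAc per-class count caps.
#' @param hexnacExclusive if `TRUE`, compositions containing HexNAc may
#'   contain no other residue class.
#' @return a named list of bounds.
#' @export
annotationBounds <- function(maxDp = 25L, maxHex = 25L, maxPnt = 25L,
                             maxHxa = 3L, maxHexNAc = 25L,
                             hexnacExclusive = TRUE) {
  b <- list(maxDp = as.integer(maxDp), maxHex = as.integer(maxHex),
            maxPnt = as.integer(maxPnt), maxHxa = as.integer(maxHxa),
            maxHexNAc = as.integer(maxHexNAc),
            hexnacExclusive = isTRUE(hexnacExclusive))
  if (any(unlist(b[1:5]) < 0L) || anyNA(unlist(b[1:5]))) {
    stop("bounds must be finite and non-negative")
  }
  b
}

# Enumerate every composition within bounds as a data.frame with
# precomputed neutral masses. Used by annotatePrecursor and by the
# simulator-facing annotation front end; cost is a few ms.
compositionGrid <- function(bounds = annotationBounds(), reduced = TRUE,
                            masses = residueMasses()) {
  g <- expand.grid(
    hex = 0:min(bounds$maxHex, bounds$maxDp),
    pnt = 0:min(bounds$maxPnt, bounds$maxDp),
    hxa = 0:min(bounds$maxHxa, bounds$maxDp),
    me  = 0:bounds$maxHxa,
    KEEP.OUT.ATTRS = FALSE
  )
  g$hexnac <- 0L
  g <- g[g$me <= g$hxa, , drop = FALSE]
  gn <- data.frame(hex = 0L, pnt = 0L, hxa = 0L, me = 0L,
                   hexnac = seq_len(min(bounds$maxHexNAc, bounds$maxDp)))
  if (!bounds$hexnacExclusive && bounds$maxHexNAc > 0L) {
    gx <- g
    gmix <- do.call(rbind, lapply(seq_len(min(bounds$maxHexNAc, bounds$maxDp)),
                                  function(k) { gx$hexnac <- k; gx }))
    g <- rbind(g, gmix)
  }
  g <- rbind(g, gn[, names(g)])
  g$dp <- g$hex + g$pnt + g$hxa + g$hexnac
  g <- g[g$dp >= 1L & g$dp <= bounds$maxDp, , drop = FALSE]
  r <- masses$residues; m <- masses$mods
  g$neutral <- g$hex * r[["Hex"]] + g$pnt * r[["Pnt"]] +
    g$hxa * r[["HxA"]] + g$hexnac * r[["HexNAc"]] + g$me * m[["Me"]] +
    masses$constants[["water"]] + if (reduced) m[["red"]] else 0
  g$nClasses <- (g$hex > 0L) + (g$pnt > 0L) + (g$hxa > 0L) + (g$hexnac > 0L)
  g$reduced <- reduced
  rownames(g) <- NULL
  g
}

#' Annotate a precursor m/z with candidate compositions
#'
#' Exhaustively enumerates every composition within `bounds` combined
#' with every adduct in `adducts` and keeps candidates whose theoretical
#' m/z lies within `tolerancePpm` of the observed value. Candidates are
#' ordered by absolute ppm error, ties broken by fewer residue classes,
#' then by lower DP.
#'
#' @param mz observed precursor m/z (Th), positive.
#' @param charge positive integer charge state (default 1; singly
#'   charged species dominate positive-mode PGC oligosaccharide data).
#' @param tolerancePpm mass tolerance in ppm (default 15, QTOF-class).
#' @param bounds from [annotationBounds()].
#' @param adducts subset of `c("sodium","proton","ammonium")`; sodium
#'   first by convention for positive-mode PGC glycomics.
#' @param reduced logical; annotate against reduced (alditol)
#'   compositions (`TRUE`, the default for borohydride-reduced
#'   workflows), non-reduced (`FALSE`), or both (`NA`).
#' @param masses mass table from [residueMasses()].
#' @param grid optional precomputed [compositionGrid()] (internal reuse).
#' @return a data.frame with columns `composition`, `adduct`, `charge`,
#'   `theoretical_mz`, `ppm_error`, `dp`, `n_classes`; zero rows when
#'   nothing matches.
#' @examples
#' annotatePrecursor(529.1739, tolerancePpm = 10)[1, ]
#' @export
annotatePrecursor <- function(mz, charge = 1L, tolerancePpm = 15,
                              bounds = annotationBounds(),
                              adducts = c("sodium", "proton", "ammonium"),
                              reduced = TRUE, masses = residueMasses(),
                              grid = NULL) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0, tolerancePpm > 0)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  if (is.null(grid)) {
    red <- if (is.na(reduced)) c(TRUE, FALSE) else as.logical(reduced)
    grid <- do.call(rbind, lapply(red, function(r)
      compositionGrid(bounds, reduced = r, masses = masses)))
  }
  out <- vector("list", length(adducts))
  for (i in seq_along(adducts)) {
    am <- adductMass(adducts[[i]], masses)
    theo <- (grid$neutral + charge * am) / charge
    ppm <- (mz - theo) / theo * 1e6
    keep <- which(abs(ppm) <= tolerancePpm)
    if (length(keep)) {
      out[[i]] <- data.frame(
        composition = formatCompositionCounts(
          grid$hex[keep], grid$pnt[keep], grid$hxa[keep],
          grid$hexnac[keep], grid$me[keep], grid$reduced[keep]),
        adduct = adducts[[i]], charge = charge,
        theoretical_mz = theo[keep], ppm_error = ppm[keep],
        dp = grid$dp[keep], n_classes = grid$nClasses[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(composition = character(), adduct = character(),
                      charge = integer(), theoretical_mz = numeric(),
                      ppm_error = numeric(), dp = integer(),
                      n_classes = integer(), stringsAsFactors = FALSE)
  }
  ord <- order(abs(res$ppm_error), res$n_classes, res$dp, res$composition)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate composition-level glycosidic fragments
#'
#' All B- and Y-type fragments reachable by removing one or more
#' residues from a composition. Y ions retain the reducing/alditol end
#' (residue sum + water, + H2 when the parent is reduced); B ions are
#' the complementary non-reducing pieces (residue sum only, never
#' reduced). O-methyl groups travel with hexuronic acid residues, so a
#' fragment with `h` hexuronic acids can carry 0..min(me, h) methyls.
#' Cross-ring (A/X) ions are out of scope.
#'
#' @param comp a [GlycanComposition-class] with DP >= 2.
#' @param adduct,charge cationization (as in [mzOf()]).
#' @param masses mass table.
#' @return data.frame with columns `composition`, `ion_type` ("B"/"Y"),
#'   `mz`, unique rows, ordered by m/z.
#' @export
enumerateFragments <- function(comp, adduct = "sodium", charge = 1L,
                               masses = residueMasses()) {
  validObject(comp)
  if (dp(comp) < 2L) stop("fragment enumeration needs DP >= 2")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  g <- expand.grid(hex = 0:comp@hex, pnt = 0:comp@pnt, hxa = 0:comp@hxa,
                   hexnac = 0:comp@hexnac, me = 0:comp@me,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$me <= g$hxa, , drop = FALSE]
  subdp <- g$hex + g$pnt + g$hxa + g$hexnac
  g <- g[subdp >= 1L & subdp < dp(comp), , drop = FALSE]
  r <- masses$residues; m <- masses$mods
  ressum <- g$hex * r[["Hex"]] + g$pnt * r[["Pnt"]] + g$hxa * r[["HxA"]] +
    g$hexnac * r[["HexNAc"]] + g$me * m[["Me"]]
  am <- adductMass(adduct, masses)
  yNeutral <- ressum + masses$constants[["water"]] +
    if (comp@reduced) m[["red"]] else 0
  bNeutral <- ressum
  frag <- rbind(
    data.frame(
      composition = formatCompositionCounts(g$hex, g$pnt, g$hxa, g$hexnac,
                                            g$me, comp@reduced),
      ion_type = "Y", mz = (yNeutral + charge * am) / charge,
      stringsAsFactors = FALSE),
    data.frame(
      composition = formatCompositionCounts(g$hex, g$pnt, g$hxa, g$hexnac,
                                            g$me, FALSE),
      ion_type = "B", mz = (bNeutral + charge * am) / charge,
      stringsAsFactors = FALSE)
  )
  frag <- unique(frag)
  frag <- frag[order(frag$mz, frag$ion_type), , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

#' Fragment-coverage score of an MS2 spectrum against a composition
#'
#' Intensity-weighted fraction of the tandem spectrum explained by the
#' theoretical B/Y fragment set of `comp`: summed intensity of peaks
#' matching any theoretical fragment (or the precursor itself) within
#' `tolerancePpm`, divided by total spectrum intensity. Deterministic;
#' in `[0, 1]`.
#'
#' @param mz,intensity numeric vectors of the MS2 peak list (non-empty).
#' @param comp a [GlycanComposition-class].
#' @param adduct,charge precursor cationization.
#' @param tolerancePpm fragment match tolerance in ppm.
#' @param masses mass table.
#' @return score in `[0, 1]`.
#' @export
scoreMsms <- function(mz, intensity, comp, adduct = "sodium", charge = 1L,
                      tolerancePpm = 15, masses = residueMasses()) {
  if (length(mz) == 0L || length(intensity) == 0L) {
    stop("empty MS2 spectrum")
  }
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  total <- sum(intensity)
  if (total <= 0) stop("MS2 spectrum has zero total intensity")
  theo <- enumerateFragments(comp, adduct, charge, masses)$mz
  theo <- c(theo, mzOf(comp, adduct, charge, masses))
  matched <- vapply(mz, function(x)
    any(abs(x - theo) / theo * 1e6 <= tolerancePpm), logical(1))
  sum(intensity[matched]) / total
}
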