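#' @import methods
NULL

#' GlycanComposition: counts of monosaccharide residue classes
#'
#' The unit of annotation: how many hexose (`hex`), pentose (`pnt`),
#' hexuronic acid (`hxa`) and N-acetylhexosamine (`hexnac`) residues an
#' oligosaccharide contains, how many O-methyl groups ride on the
#' hexuronic acids (`me`), and whether the reducing end has been
#' converted to an alditol (`reduced`; borohydride reduction adds H2).
#'
#' Validity: all counts non-negative, degree of polymerization
#' (hex+pnt+hxa+hexnac) at least 1, and `me <= hxa` because the O-methyl
#' decoration sits on hexuronic acid (4-O-methyl-glucuronic acid in
#' xylans).
#'
#' @slot hex,pnt,hxa,hexnac integer residue counts
#' @slot me integer O-methyl count
#' @slot reduced logical, alditol end
#' @aliases GlycanComposition
#' @exportClass GlycanComposition
setClass("GlycanComposition",
  representation(hex = "integer", pnt = "integer", hxa = "integer",
                 hexnac = "integer", me = "integer", reduced = "logical"),
  prototype(hex = 0L, pnt = 0L, hxa = 0L, hexnac = 0L, me = 0L,
            reduced = FALSE)
)

setValidity("GlycanComposition", function(object) {
  cnt <- c(object@hex, object@pnt, object@hxa, object@hexnac, object@me)
  if (anyNA(cnt) || any(cnt < 0L)) {
    return("residue and modification counts must be non-negative")
  }
  if (sum(object@hex, object@pnt, object@hxa, object@hexnac) < 1L) {
    return("degree of polymerization must be >= 1")
  }
  if (object@me > object@hxa) {
    return("me > hxa: O-methyl groups must sit on hexuronic acid residues")
  }
  if (length(object@reduced) != 1L || is.na(object@reduced)) {
    return("reduced must be TRUE or FALSE")
  }
  TRUE
})

#' Create a glycan composition
#'
#' @param hex,pnt,hxa,hexnac residue counts (hexose, pentose, hexuronic
#'   acid, N-acetylhexosamine).
#' @param me number of O-methyl groups (must not exceed `hxa`).
#' @param reduced logical; `TRUE` for an alditol (reduced) end.
#' @return a [GlycanComposition-class] object.
#' @examples
#' glycanComposition(hex = 3, reduced = TRUE)
#' parseComposition("Pnt4HxA1Me1-red")
#' @export
glycanComposition <- function(hex = 0, pnt = 0, hxa = 0, hexnac = 0,
                              me = 0, reduced = FALSE) {
  new("GlycanComposition", hex = as.integer(hex), pnt = as.integer(pnt),
      hxa = as.integer(hxa), hexnac = as.integer(hexnac),
      me = as.integer(me), reduced = as.logical(reduced))
}

#' @describeIn glycanComposition parse the canonical text form
#'   (`Hex<n>Pnt<n>HxA<n>HexNAc<n>Me<n>` with optional `-red` suffix;
#'   omitted tokens mean zero; case-sensitive).
#' @param text composition string, e.g. `"Hex3"` or `"Pnt4HxA1Me1-red"`.
#' @export
parseComposition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- text
  reduced <- grepl("-red$", s)
  s <- sub("-red$", "", s)
  counts <- c(Hex = 0L, Pnt = 0L, HxA = 0L, HexNAc = 0L, Me = 0L)
  # HexNAc must be consumed before Hex (shared prefix)
  pat <- "^(HexNAc|Hex|Pnt|HxA|Me)([0-9]+)"
  seen <- character()
  while (nzchar(s)) {
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (!length(m)) stop("cannot parse composition: '", text, "'")
    tok <- m[2]
    if (tok %in% seen) stop("duplicated token '", tok, "' in '", text, "'")
    seen <- c(seen, tok)
    counts[[tok]] <- as.integer(m[3])
    s <- substring(s, nchar(m[1]) + 1L)
  }
  glycanComposition(hex = counts[["Hex"]], pnt = counts[["Pnt"]],
                    hxa = counts[["HxA"]], hexnac = counts[["HexNAc"]],
                    me = counts[["Me"]], reduced = reduced)
}

#' @rdname dp
#' @export
setGeneric("dp", function(x) standardGeneric("dp"))

#' Degree of polymerization
#'
#' Number of monosaccharide residues (hex + pnt + hxa + hexnac;
#' modifications do not count).
#'
#' @param x a [GlycanComposition-class].
#' @return integer DP.
#' @export
setMethod("dp", "GlycanComposition", function(x) {
  x@hex + x@pnt + x@hxa + x@hexnac
})

#' @export
setMethod("as.character", "GlycanComposition", function(x) {
  formatCompositionCounts(x@hex, x@pnt, x@hxa, x@hexnac, x@me, x@reduced)
})

# vectorized canonical formatter shared with the annotation grid
formatCompositionCounts <- function(hex, pnt, hxa, hexnac, me, reduced) {
  out <- paste0(
    ifelse(hex > 0L, paste0("Hex", hex), ""),
    ifelse(pnt > 0L, paste0("Pnt", pnt), ""),
    ifelse(hxa > 0L, paste0("HxA", hxa), ""),
    ifelse(hexnac > 0L, paste0("HexNAc", hexnac), ""),
    ifelse(me > 0L, paste0("Me", me), "")
  )
  paste0(out, ifelse(reduced, "-red", ""))
}

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition:", as.character(object),
      sprintf("(DP %d, %.5f Da)\n", dp(object), neutralMass(object)))
})

#' @rdname neutralMass
#' @export
setGeneric("neutralMass", function(comp, masses = residueMasses())
  standardGeneric("neutralMass"))

#' Neutral monoisotopic mass of a composition
#'
#' Residue-sum mass arithmetic: sum of residue masses plus one water,
#' plus H2 if the end is reduced, plus CH2 per O-methyl group.
#'
#' @param comp a [GlycanComposition-class].
#' @param masses mass table from [residueMasses()].
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutralMass(glycanComposition(hex = 1)) # glucose, 180.0634
#' @export
setMethod("neutralMass", "GlycanComposition", function(comp, masses) {
  validObject(comp)
  r <- masses$residues
  m <- masses$mods
  comp@hex * r[["Hex"]] + comp@pnt * r[["Pnt"]] + comp@hxa * r[["HxA"]] +
    comp@hexnac * r[["HexNAc"]] + comp@me * m[["Me"]] +
    masses$constants[["water"]] + if (comp@reduced) m[["red"]] else 0
})

#' @rdname mzOf
#' @export
setGeneric("mzOf", function(comp, adduct = "sodium", charge = 1L,
                            masses = residueMasses())
  standardGeneric("mzOf"))

#' Theoretical m/z of an adducted composition
#'
#' `(neutral mass + charge * cation mass) / charge` for singly or
#' multiply cationized species in positive mode.
#'
#' @param comp a [GlycanComposition-class].
#' @param adduct `"proton"`, `"sodium"` or `"ammonium"`.
#' @param charge positive integer charge state.
#' @param masses mass table from [residueMasses()].
#' @return m/z in Th.
#' @examples
#' mzOf(glycanComposition(hex = 3, reduced = TRUE), "sodium") # 529.1739
#' @export
setMethod("mzOf", "GlycanComposition", function(comp, adduct, charge, masses) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  (neutralMass(comp, masses) + charge * adductMass(adduct, masses)) / charge
})
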