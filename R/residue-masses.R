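#' Monoisotopic residue and adduct mass table
#'
#' Mass table used by all composition arithmetic. Residue masses are the
#' monoisotopic masses of the dehydrated monosaccharide units (free
#' monosaccharide minus water), so that the neutral mass of an
#' oligosaccharide is the residue sum plus one water. Cation masses are
#' atom masses minus one electron.
#'
#' Residue classes: `Hex` (hexose, C6H10O5), `Pnt` (pentose, C5H8O4),
#' `HxA` (hexuronic acid, C6H8O6), `HexNAc` (N-acetylhexosamine,
#' C8H13NO5). Modifications: `Me` (O-methyl, +CH2), `red` (alditol /
#' reduced end from borohydride reduction, +H2).
#'
#' @param overrides optional named list with any of `residues`, `mods`,
#'   `constants`; values replace the defaults entry-wise. May also be a
#'   path to a JSON file with the same structure.
#' @return a list with numeric vectors `residues`, `mods`, `constants`
#'   (water, proton, sodium, ammonium). All masses in Da, strictly
#'   positive.
#' @examples
#' residueMasses()$residues[["Hex"]]
#' @export
residueMasses <- function(overrides = NULL) {
  tab <- list(
    residues = c(
      Hex    = 162.05282343,
      Pnt    = 132.04225873,
      HxA    = 176.03208797,
      HexNAc = 203.07937252
    ),
    mods = c(
      Me  = 14.01565006,
      red = 2.01565006
    ),
    constants = c(
      water    = 18.01056468,
      proton   = 1.00727645,
      sodium   = 22.98922070,
      ammonium = 18.03382552
    )
  )
  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- jsonlite::fromJSON(overrides)
    }
    stopifnot(is.list(overrides))
    for (blk in intersect(names(overrides), names(tab))) {
      ov <- unlist(overrides[[blk]])
      bad <- setdiff(names(ov), names(tab[[blk]]))
      if (length(bad)) {
        stop("unknown mass table entries: ", paste(bad, collapse = ", "))
      }
      tab[[blk]][names(ov)] <- as.numeric(ov)
    }
  }
  if (any(unlist(tab) <= 0)) stop("all masses must be strictly positive")
  tab
}

#' Adduct cation mass
#'
#' @param adduct one of `"proton"`, `"sodium"`, `"ammonium"`.
#' @param masses mass table from [residueMasses()].
#' @return cation monoisotopic mass in Da.
#' @keywords internal
adductMass <- function(adduct, masses = residueMasses()) {
  if (!is.character(adduct) || length(adduct) != 1L ||
      !adduct %in% c("proton", "sodium", "ammonium")) {
    stop("unknown adduct: ", paste(adduct, collapse = ","),
         " (expected proton, sodium or ammonium)")
  }
  unname(masses$constants[[adduct]])
}
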