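# Independent oracles: masses from elemental formulas and atomic
# constants, and a brute-force composition enumerator. Deliberately
# share no code with the package internals.

.atom <- c(C = 12, H = 1.00782503207, O = 15.9949146196,
           N = 14.0030740048, e = 0.00054857991)

# neutral monoisotopic mass of an oligosaccharide from its summed
# elemental formula: residues + H2O, +H2 if reduced, +CH2 per methyl
oracleMass <- function(hex = 0, pnt = 0, hxa = 0, hexnac = 0, me = 0,
                       reduced = FALSE) {
  C <- 6 * hex + 5 * pnt + 6 * hxa + 8 * hexnac + me
  H <- 10 * hex + 8 * pnt + 8 * hxa + 13 * hexnac + 2 * me +
    2 + if (reduced) 2 else 0
  O <- 5 * hex + 4 * pnt + 6 * hxa + 5 * hexnac + 1
  N <- hexnac
  C * .atom[["C"]] + H * .atom[["H"]] + O * .atom[["O"]] + N * .atom[["N"]]
}

oracleCation <- c(
  proton   = .atom[["H"]] - .atom[["e"]],
  sodium   = 22.9897692809 - .atom[["e"]],
  ammonium = .atom[["N"]] + 4 * .atom[["H"]] - .atom[["e"]]
)

# exhaustive composition table via explicit nested loops (reduced
# species; HexNAc only as a homo-series, mirroring the default bounds)
oracleCompositionTable <- local({
  tab <- NULL
  function(maxDp = 25, maxHxa = 3) {
    if (!is.null(tab)) return(tab)
    rows <- list()
    for (h in 0:maxDp) for (p in 0:maxDp) for (a in 0:maxHxa) {
      d <- h + p + a
      if (d < 1 || d > maxDp) next
      for (m in 0:a) {
        rows[[length(rows) + 1L]] <- c(h, p, a, 0, m)
      }
    }
    for (n in 1:maxDp) rows[[length(rows) + 1L]] <- c(0, 0, 0, n, 0)
    tb <- do.call(rbind, rows)
    colnames(tb) <- c("hex", "pnt", "hxa", "hexnac", "me")
    mass <- numeric(nrow(tb))
    for (i in seq_len(nrow(tb))) {
      mass[i] <- oracleMass(tb[i, 1], tb[i, 2], tb[i, 3], tb[i, 4],
                            tb[i, 5], reduced = TRUE)
    }
    lab <- character(nrow(tb))
    for (i in seq_len(nrow(tb))) {
      s <- ""
      if (tb[i, 1] > 0) s <- paste0(s, "Hex", tb[i, 1])
      if (tb[i, 2] > 0) s <- paste0(s, "Pnt", tb[i, 2])
      if (tb[i, 3] > 0) s <- paste0(s, "HxA", tb[i, 3])
      if (tb[i, 4] > 0) s <- paste0(s, "HexNAc", tb[i, 4])
      if (tb[i, 5] > 0) s <- paste0(s, "Me", tb[i, 5])
      lab[i] <- paste0(s, "-red")
    }
    tab <<- list(counts = tb, mass = mass, label = lab)
    tab
  }
})

# all (composition, adduct) pairs whose singly charged m/z falls within
# tolerance of the query
oracleAnnotate <- function(mz, tolPpm = 15,
                           adducts = c("sodium", "proton", "ammonium")) {
  tb <- oracleCompositionTable()
  hits <- character()
  for (ad in adducts) {
    theo <- tb$mass + oracleCation[[ad]]
    sel <- abs(mz - theo) / theo * 1e6 <= tolPpm
    if (any(sel)) hits <- c(hits, paste(tb$label[sel], ad))
  }
  sort(hits)
}
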