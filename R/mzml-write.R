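# Minimal mzML 1.1.0 serializer: centroided spectra, uncompressed
# 64-bit float binary arrays, MS2 scans with selected-ion and collision
# energy metadata. Files read back identically through mzR.

b64doubles <- function(x) {
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                               size = 8L,
                                               endian = "little")),
       fixed = TRUE)
}

mzmlSpectrum <- function(i, h, p) {
  mzb <- b64doubles(p[, 1L])
  inb <- b64doubles(p[, 2L])
  prec <- ""
  if (h$msLevel == 2L && !is.na(h$precursorMz)) {
    ce <- if (is.na(h$collisionEnergy)) "" else sprintf(
      '<cvParam cvRef="MS" accession="MS:1000045" name="collision energy" value="%.4f" unitCvRef="UO" unitAccession="UO:0000266" unitName="electronvolt"/>',
      h$collisionEnergy)
    chg <- if (is.na(h$precursorCharge)) "" else sprintf(
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
      h$precursorCharge)
    prec <- sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.8f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>%s</selectedIon></selectedIonList><activation><cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/>%s</activation></precursor></precursorList>',
      h$precursorMz, chg, ce)
  }
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            i - 1L, h$scan, nrow(p)),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
            h$msLevel),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    sprintf('<cvParam cvRef="MS" accession="MS:%s" name="MS%d spectrum" value=""/>',
            if (h$msLevel == 1L) "1000579" else "1000580",
            min(h$msLevel, 2L)),
    sprintf('<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.8f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
            h$rt * 60),
    prec,
    '<binaryDataArrayList count="2">',
    sprintf('<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>',
            nchar(mzb), mzb),
    sprintf('<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>',
            nchar(inb), inb),
    '</binaryDataArrayList></spectrum>')
}

#' Write a run as minimal valid mzML
#'
#' Emits a standard-conformant mzML 1.1.0 document (centroid spectra,
#' uncompressed little-endian 64-bit float arrays) that [readRun()]
#' (through `mzR`) reads back with identical peak data; retention times
#' are stored in seconds per the standard. MS2 scans carry selected-ion
#' m/z, charge state and collision energy.
#'
#' @param run an [MsRun-class].
#' @param path output path ending in `.mzML`.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(run, path) {
  h <- scanHeader(run)
  n <- nrow(h)
  specs <- vapply(seq_len(n), function(i)
    mzmlSpectrum(i, h[i, ], peaksOf(run, i)), character(1))
  doc <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    sprintf('<softwareList count="1"><software id="glycoquant" version="%s"/></softwareList>',
            as.character(utils::packageVersion("glycoquant"))),
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="glycoquant"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    specs,
    '</spectrumList></run></mzML>')
  writeLines(doc, path)
  invisible(path)
}
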