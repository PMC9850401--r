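#' Published reference values for NIST SRM 3233
#'
#' Certificate-of-analysis carbohydrate attributes and the published
#' bottom-up LC-MS polysaccharide determinations for the fortified
#' breakfast cereal reference material (g per 100 g fresh weight),
#' shipped as a plain-text table. The polysaccharide estimate from the
#' certificate is total carbohydrates minus free sugars minus low
#' molecular weight soluble dietary fiber; the method total is the sum
#' of the seven quantified polysaccharides.
#'
#' @return data.frame with columns `source` (`COA`/`FITDOG`),
#'   `attribute`, `value`, `uncertainty`.
#' @examples
#' ref <- srm3233Reference()
#' sum(ref$value[ref$source == "FITDOG" &
#'               !grepl("printed", ref$attribute)])
#' @export
srm3233Reference <- function() {
  path <- system.file("extdata", "srm3233_reference.tsv",
                      package = "glycoquant", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
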