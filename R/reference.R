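#' Published summary statistics of the GDTCM-500 reference annotation
#'
#' The annotation schema implemented here was developed on GDTCM-500,
#' a corpus of 500 present-illness narratives from TCM electronic
#' medical records whose raw text is withheld for privacy. The
#' published corpus-level summary tables ship with the package as
#' plain-text data: per-type entity annotation counts (total 39,097),
#' per-type relation annotation counts (total 41,373), and the
#' symptom-information-utilization (TCM-SIU) comparison of annotation
#' schemes, i.e. the mean per-sentence fraction of characters covered
#' by annotation under each scheme (see [annotation_rate()]).
#'
#' @param which One of `"entities"`, `"relations"`, `"siu"`.
#' @return A data frame; counts and percentages as published.
#' @export
#' @examples
#' sum(gdtcm500_summary("entities")$annotation_count)
gdtcm500_summary <- function(which = c("entities", "relations", "siu")) {
  which <- match.arg(which)
  fn <- switch(which,
               entities = "gdtcm500_entity_counts.tsv",
               relations = "gdtcm500_relation_counts.tsv",
               siu = "gdtcm500_siu_comparison.tsv")
  path <- system.file("extdata", fn, package = "tcmnorm", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
}
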