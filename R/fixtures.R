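# Packaged published RSCU table for the CTV coat-protein study system:
# three virus subgroups (by citrus host of origin) and their three hosts.

#' Load the packaged CTV coat-protein RSCU table
#'
#' Published pooled RSCU values (2-decimal precision) for the three CTV
#' subgroups -- Ca-CTV, Cr-CTV, Cs-CTV, named for their citrus hosts of
#' origin -- and the codon-usage RSCU of the three hosts (*C. aurantifolia*,
#' *C. reticulata*, *C. sinensis*). This is the desk-scale input on which
#' the high-frequency-codon classification results are exactly reproducible.
#'
#' @return list with elements `table` (the raw data.frame), `virus` (named
#'   list of RSCU vectors Ca_CTV/Cr_CTV/Cs_CTV over the 61 sense codons) and
#'   `host` (named list C_aurantifolia/C_reticulata/C_sinensis).
#' @export
load_ctv_rscu <- function() {
  path <- system.file("extdata", "ctv_cp_rscu_published.tsv",
                      package = "cubkit", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(setequal(df$codon, SENSE_CODONS))
  as_vec <- function(col) stats::setNames(df[[col]], df$codon)[SENSE_CODONS]
  list(
    table = df,
    virus = list(Ca_CTV = as_vec("Ca_CTV"), Cr_CTV = as_vec("Cr_CTV"),
                 Cs_CTV = as_vec("Cs_CTV")),
    host = list(C_aurantifolia = as_vec("C_aurantifolia"),
                C_reticulata = as_vec("C_reticulata"),
                C_sinensis = as_vec("C_sinensis"))
  )
}

# host paired with each subgroup
CTV_SUBGROUP_HOST <- c(Ca_CTV = "C_aurantifolia", Cr_CTV = "C_reticulata",
                       Cs_CTV = "C_sinensis")

# subgroup sizes of the study dataset
CTV_SUBGROUP_SIZES <- c(Ca_CTV = 29L, Cr_CTV = 38L, Cs_CTV = 55L)

#' Reproduce the published high-frequency-codon classification
#'
#' Runs [classify_hfc()] for each subgroup against its paired host on the
#' packaged published RSCU values at the given threshold, plus the pairwise
#' conversion analyses.
#'
#' @param threshold RSCU cutoff (default 1.05).
#' @return list with `classifications` (per subgroup), `hfc_union`
#'   (virus high-frequency codons over all subgroups), and `conversions`
#'   (named list of `conversion_report`s, `<from>.<to>`).
#' @export
ctv_hfc_analysis <- function(threshold = 1.05) {
  fx <- load_ctv_rscu()
  cls <- lapply(names(fx$virus), function(sg) {
    classify_hfc(fx$virus[[sg]], fx$host[[CTV_SUBGROUP_HOST[[sg]]]],
                 threshold = threshold, virus_label = sg,
                 host_label = CTV_SUBGROUP_HOST[[sg]])
  })
  names(cls) <- names(fx$virus)
  hfc_union <- sort(unique(unlist(lapply(fx$virus, high_frequency_codons,
                                         threshold = threshold))))
  pairs <- list(c("Cr_CTV", "Cs_CTV"), c("Cr_CTV", "Ca_CTV"),
                c("Ca_CTV", "Cs_CTV"))
  conv <- lapply(pairs, function(p) conversion_analysis(cls[[p[1]]], cls[[p[2]]]))
  names(conv) <- vapply(pairs, paste, character(1), collapse = ".")
  list(classifications = cls, hfc_union = hfc_union, conversions = conv)
}
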