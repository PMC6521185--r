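# Standard genetic code (translation table 1) in the package's canonical RNA
# alphabet, plus the derived family structures every downstream statistic uses.

RNA_BASES <- c("A", "C", "G", "U")

#' All 64 RNA codons in lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(RNA_BASES, RNA_BASES, paste0))),
    RNA_BASES, paste0
  )))
}

# codon -> one-letter amino acid ("*" = stop), standard nuclear code
.genetic_code_rna <- local({
  gc <- Biostrings::GENETIC_CODE  # DNA-keyed
  names(gc) <- chartr("T", "U", names(gc))
  gc
})

STOP_CODONS <- names(.genetic_code_rna)[.genetic_code_rna == "*"]
SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

#' Translate RNA codons to one-letter amino acids
#'
#' @param codons character vector of RNA triplets.
#' @return character vector of one-letter amino-acid codes, `"*"` for stops.
#' @export
translate_codons <- function(codons) {
  aa <- unname(.genetic_code_rna[codons])
  if (anyNA(aa)) {
    stop("unknown codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  aa
}

# amino acid -> member codons (sense only)
CODON_FAMILIES <- split(SENSE_CODONS, .genetic_code_rna[SENSE_CODONS])

# family size n_i per amino acid
FAMILY_SIZES <- vapply(CODON_FAMILIES, length, integer(1))

SINGLE_CODON_AA <- names(FAMILY_SIZES)[FAMILY_SIZES == 1L]  # M, W

# 59 codons of the degenerate families (excludes Met, Trp, stops)
DEGENERATE_CODONS <- unlist(CODON_FAMILIES[FAMILY_SIZES > 1L], use.names = FALSE)

# Wright's degeneracy classes: 9 twofold, Ile threefold, 5 fourfold,
# Leu/Ser/Arg sixfold
DEGENERACY_CLASSES <- split(names(FAMILY_SIZES), FAMILY_SIZES)[c("2", "3", "4", "6")]

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC_AA <- c("F", "Y", "W")

# three-letter labels used in report tables
AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' Amino acid of each sense codon
#' @keywords internal
codon_aa <- function(codons = SENSE_CODONS) {
  translate_codons(codons)
}
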