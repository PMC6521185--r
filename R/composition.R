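# Nucleotide/position composition indices, Wright's effective number of
# codons, and protein-level Gravy/Aromo, summarised per subgroup.

#' Nucleotide and position-specific composition of a coding sequence
#'
#' All indices are computed over the sense codons of the record (terminal
#' stop and ambiguous codons excluded). Position-specific percentages
#' (`A3`...`CU3`) and the GC-by-position fractions use all sense codons,
#' including the single-codon Met and Trp families.
#'
#' @param x a `coding_sequence` or a character vector of sense codons.
#' @return named numeric vector with components `A`, `C`, `G`, `U`, `GC`,
#'   `AU` (overall percentages), `A3`, `C3`, `G3`, `U3`, `GC3p`, `GA3`,
#'   `GU3`, `AU3`, `CU3` (third-position percentages), `GC1`, `GC2`, `GC3`,
#'   `GC12` (fractions over all sense codons), `GC3s` (third-position G+C
#'   over degenerate-family codons only, the ENc-plot convention), `GU`,
#'   `AC` (overall percentages of G+U and A+C), `L_aa` and `L_sym`.
#' @export
nucleotide_composition <- function(x) {
  codons <- if (inherits(x, "coding_sequence")) sense_codons(x) else x
  if (length(codons) == 0L) stop("zero-length sequence")
  bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
  pos <- rep(1:3, times = length(codons))
  pct <- function(b, sel = rep(TRUE, length(bases))) {
    100 * sum(bases[sel] %in% b) / sum(sel)
  }
  third <- pos == 3L
  frac_gc <- function(p) sum(bases[pos == p] %in% c("G", "C")) / length(codons)
  gc1 <- frac_gc(1L); gc2 <- frac_gc(2L); gc3 <- frac_gc(3L)
  aa <- translate_codons(codons)
  syn <- !aa %in% SINGLE_CODON_AA
  gc3s <- if (any(syn)) {
    sum(substr(codons[syn], 3, 3) %in% c("G", "C")) / sum(syn)
  } else NA_real_
  c(
    A = pct("A"), C = pct("C"), G = pct("G"), U = pct("U"),
    GC = pct(c("G", "C")), AU = pct(c("A", "U")),
    GU = pct(c("G", "U")), AC = pct(c("A", "C")),
    A3 = pct("A", third), C3 = pct("C", third),
    G3 = pct("G", third), U3 = pct("U", third),
    GC3p = pct(c("G", "C"), third), GA3 = pct(c("G", "A"), third),
    GU3 = pct(c("G", "U"), third), AU3 = pct(c("A", "U"), third),
    CU3 = pct(c("C", "U"), third),
    GC1 = gc1, GC2 = gc2, GC3 = gc3, GC3s = gc3s, GC12 = (gc1 + gc2) / 2,
    L_aa = length(codons),
    L_sym = sum(!aa %in% SINGLE_CODON_AA)
  )
}

# Wright homozygosity F for one amino-acid family; NA when n < 2
family_homozygosity <- function(g) {
  n <- sum(g)
  if (n < 2) return(NA_real_)
  p <- g / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (ENc)
#'
#' ENc ranges from 20 (one codon per family, maximal bias) to 61 (all
#' synonymous codons used equally). Computed as
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` from the mean family homozygosity of each
#' degeneracy class. Families with fewer than two occurrences, or with a
#' non-positive homozygosity estimate, are excluded from their class mean.
#' If Ile (the only threefold family) yields no estimate, its class mean is
#' imputed as the average of the two- and fourfold class means; any other
#' empty class is an error. Values above 61 (possible at finite n) are
#' reported as-is with a warning.
#'
#' @param counts codon counts: named vector, or a matrix pooled by
#'   [pool_counts()].
#' @return ENc value (scalar).
#' @export
effective_number_of_codons <- function(counts) {
  g <- as_count_vector(counts)[DEGENERATE_CODONS]
  if (sum(g) < 1) stop("ENc undefined: no sense codons")
  aa <- codon_aa(DEGENERATE_CODONS)
  fam_F <- vapply(split(g, aa), family_homozygosity, numeric(1))
  fam_F[!is.na(fam_F) & fam_F <= 0] <- NA_real_
  class_mean <- vapply(DEGENERACY_CLASSES, function(members) {
    mean(fam_F[members], na.rm = TRUE)
  }, numeric(1))
  big <- c("2", "4", "6")
  if (any(is.nan(class_mean[big]))) {
    stop("ENc undefined: degeneracy class ",
         paste(big[is.nan(class_mean[big])], collapse = ", "),
         " has no usable amino-acid family (n >= 2)")
  }
  if (is.nan(class_mean[["3"]])) {
    class_mean[["3"]] <- (class_mean[["2"]] + class_mean[["4"]]) / 2
  }
  enc <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  if (enc > 61) warning("ENc ", format(enc), " exceeds 61 (not clamped)")
  unname(enc)
}

#' Gravy and Aromo of the translated product
#'
#' Gravy is the mean Kyte-Doolittle hydropathy over residues; Aromo the
#' fraction of aromatic residues (Phe, Tyr, Trp).
#'
#' @param counts codon counts (named vector or matrix).
#' @return named numeric vector `c(Gravy =, Aromo =)`.
#' @export
gravy_aromo <- function(counts) {
  g <- as_count_vector(counts)[SENSE_CODONS]
  total <- sum(g)
  if (total < 1) stop("zero residues")
  aa_counts <- rowsum(g, codon_aa(SENSE_CODONS))[, 1]
  c(Gravy = sum(aa_counts * KYTE_DOOLITTLE[names(aa_counts)]) / total,
    Aromo = sum(aa_counts[intersect(AROMATIC_AA, names(aa_counts))]) / total)
}

#' Full composition profile of one record
#'
#' Combines [nucleotide_composition()], [effective_number_of_codons()] and
#' [gravy_aromo()].
#' @param x a `coding_sequence`.
#' @return named numeric vector.
#' @export
composition_profile <- function(x) {
  stopifnot(inherits(x, "coding_sequence"))
  counts <- as_count_vector(count_codons(x))
  c(nucleotide_composition(x),
    ENc = effective_number_of_codons(counts),
    gravy_aromo(counts))
}

#' Per-subgroup mean and standard error of composition indices
#'
#' @param set a labelled `sequence_set`.
#' @return data.frame: one row per index, columns `<subgroup>_mean`,
#'   `<subgroup>_se` for each subgroup plus `overall_mean`, `overall_se` and
#'   `index`. SE is the sample standard deviation / sqrt(n); 0 for n = 1.
#' @export
composition_summary <- function(set) {
  stopifnot(inherits(set, "sequence_set"))
  prof <- t(vapply(set, composition_profile, composition_profile(set[[1]])))
  grp <- subgroups(set)
  se <- function(v) if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  groups <- c(split(seq_len(nrow(prof)), grp), list(overall = seq_len(nrow(prof))))
  out <- data.frame(index = colnames(prof))
  for (gname in names(groups)) {
    sub <- prof[groups[[gname]], , drop = FALSE]
    out[[paste0(gname, "_mean")]] <- apply(sub, 2, mean)
    out[[paste0(gname, "_se")]] <- apply(sub, 2, se)
  }
  attr(out, "n") <- vapply(groups, length, integer(1))
  out
}
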