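# Shared in-code fixtures. Everything is generated programmatically; no
# binary data.

# a small labelled sequence set built from explicit codon strings; every
# record populates the 2-, 3-, 4- and 6-fold degeneracy classes so ENc is
# defined
toy_set <- function() {
  core <- function(...) paste0("AUG", paste0(...), collapse = "")
  seqs <- c(
    a1 = core("UUUUUCUUU", "CUUCUUUUGCUA", "GCUGCUGCA", "AAAAAG",
              "GAUGAU", "AUUAUA", "GGUGGU", "UAA"),
    a2 = core("UUCUUCUUU", "CUGCUGUUGCUA", "GCAGCAGCC", "AAGAAG",
              "GACGAC", "AUCAUA", "GGAGGA", "UAG"),
    b1 = core("UUUUUUUUU", "CUUCUUCUUCUA", "GCUGCUGCU", "AAAAAA",
              "GAUGAU", "AUUAUU", "GGUGGU", "UAA"),
    b2 = core("UUUUUCUUC", "UUAUUACUGCUG", "GCGGCGGCC", "AAGAAG",
              "GACGAC", "AUAAUA", "GGCGGC", "")
  )
  set <- structure(
    lapply(names(seqs), function(id) coding_sequence(id, seqs[[id]])),
    class = "sequence_set"
  )
  names(set) <- names(seqs)
  map <- data.frame(id = names(seqs),
                    subgroup = c("A", "A", "B", "B"),
                    host = c("hA", "hA", "hB", "hB"))
  assign_groups(set, map)
}

# count vector with exactly one codon per degenerate family, n copies each
# (maximal bias; ENc = 20 when every family is present)
max_bias_counts <- function(n = 3, drop_aa = character()) {
  aa <- translate_codons(cubkit:::DEGENERATE_CODONS)
  first <- tapply(cubkit:::DEGENERATE_CODONS, aa, `[`, 1)
  first <- first[setdiff(names(first), drop_aa)]
  stats::setNames(rep(n, length(first)), unname(first))
}

# random codon count table (fixed-seed property-test input)
random_counts <- function(seed, lambda = 8) {
  set.seed(seed)
  stats::setNames(stats::rpois(61, lambda), cubkit:::SENSE_CODONS)
}

# write a sequence set to a temporary FASTA, return the path
tmp_fasta <- function(set, wrap = FALSE) {
  path <- tempfile(fileext = ".fasta")
  if (!wrap) return(write_fasta(set, path))
  lines <- unlist(lapply(set, function(s) {
    seq <- paste(s$codons, collapse = "")
    c(paste0(">", s$id),
      substring(seq, seq(1, nchar(seq), 30), pmin(seq(30, nchar(seq) + 29, 30),
                                                  nchar(seq))))
  }))
  writeLines(lines, path)
  path
}
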