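test_that("coding_sequence validates, normalizes and flags terminal stops", {
  cs <- coding_sequence("x", "ATGTTTTAA")
  expect_identical(cs$codons, c("AUG", "UUU"))
  expect_true(cs$terminal_stop)

  expect_error(coding_sequence("x", "ATGTTTTA"), "multiple of 3")
  expect_error(coding_sequence("x", "ATGTAAATG"), "internal stop")
  expect_error(coding_sequence("x", ""), "empty")

  # ambiguity codes: codon kept but masked out of sense codons
  amb <- coding_sequence("x", "AUGNNNUUU")
  expect_identical(sense_codons(amb), c("AUG", "UUU"))
  expect_identical(length(amb$codons), 3L)
})

test_that("FASTA read/write round-trips and enforces unique ids", {
  set <- toy_set()
  for (wrap in c(FALSE, TRUE)) {
    path <- tmp_fasta(set, wrap = wrap)
    back <- read_fasta(path)
    expect_identical(names(back), names(set))
    for (id in names(set)) {
      expect_identical(back[[id]]$codons, set[[id]]$codons)
    }
  }

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "AUGUUU", ">a", "AUGUUC"), dup)
  expect_error(read_fasta(dup), "duplicate record id.*a")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "empty")

  # drop_invalid demotes internal-stop records to a warning
  noisy <- tempfile(fileext = ".fasta")
  writeLines(c(">good", "ATGTTT", ">bad", "ATGTAATTT"), noisy)
  expect_error(read_fasta(noisy), "internal stop")
  expect_warning(kept <- read_fasta(noisy, drop_invalid = TRUE), "dropping")
  expect_identical(names(kept), "good")
})

test_that("group map parses, rejects duplicates, reports subgroup sizes", {
  path <- tempfile(fileext = ".tsv")
  writeLines("iso1\tCr-CTV\tC.reticulata", path)
  gm <- read_group_map(path)
  expect_identical(gm$subgroup[gm$id == "iso1"], "Cr-CTV")
  expect_identical(gm$host[gm$id == "iso1"], "C.reticulata")

  writeLines(c("iso1\tA\th", "iso1\tB\th"), path)
  expect_error(read_group_map(path), "duplicate")

  # the study's 29/38/55 partition survives a map round-trip
  sizes <- c(Cs = 55L, Cr = 38L, Ca = 29L)
  ids <- unlist(lapply(names(sizes), function(s) paste0(s, seq_len(sizes[s]))))
  writeLines(paste(ids, rep(names(sizes), sizes), "host", sep = "\t"), path)
  gm <- read_group_map(path)
  expect_identical(table(gm$subgroup)[names(sizes)],
                   table(rep(names(sizes), sizes))[names(sizes)])

  set <- toy_set()
  expect_error(
    assign_groups(set, data.frame(id = "a1", subgroup = "A", host = "h")),
    "absent from group map.*a2"
  )
})

test_that("codon usage table parsers handle all three dialects", {
  path <- tempfile(fileext = ".tsv")
  writeLines("GCU\t120", path)
  expect_warning(ref <- read_codon_usage_table(path, "plain-tsv"), "missing")
  expect_equal(ref$counts[["GCU"]], 120)
  expect_equal(ref$counts[["GCA"]], 0)

  # DNA codons and per-thousand frequencies are normalized
  writeLines(c("GCT\t12.5", "TTT\t20.0"), path)
  expect_warning(ref <- read_codon_usage_table(path, "plain-tsv"))
  expect_equal(ref$counts[["GCU"]], 12500)

  kz <- tempfile()
  writeLines("GCU 12.0( 120)  GCC 6.0( 60)", kz)
  expect_warning(ref <- read_codon_usage_table(kz, "kazusa"), "missing")
  expect_equal(ref$counts[["GCU"]], 120)
  expect_equal(ref$counts[["GCC"]], 60)

  writeLines("GCX\t5", path)
  expect_error(read_codon_usage_table(path, "plain-tsv"), "unknown codon")

  # rscu-direct: the packaged published table parses and matches print
  fx <- load_ctv_rscu()
  expect_equal(fx$host$C_reticulata[["GCU"]], 1.41)
  rpath <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(codon = names(fx$host$C_sinensis), fx$host$C_sinensis),
    rpath, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ref <- read_codon_usage_table(rpath, "rscu-direct")
  expect_equal(reference_rscu(ref), fx$host$C_sinensis)
})

test_that("codon counting is conservation-exact and pools additively", {
  cs <- coding_sequence("x", "AUGUUUUUU")
  cc <- as_counts <- count_codons(cs)
  expect_equal(unname(cc[1, c("AUG", "UUU")]), c(1L, 2L))
  expect_equal(sum(cc), 3)

  set <- toy_set()
  m <- count_codons(set)
  expect_equal(rowSums(m),
               vapply(set, function(s) length(sense_codons(s)), integer(1)))
  pooled <- count_codons(set, pooled = TRUE)
  expect_equal(pooled$subgroups["A", ], colSums(m[c("a1", "a2"), ]))
  # pooling is order-independent
  expect_equal(pool_counts(m[c(4, 1, 3, 2), ]), pool_counts(m))
})

test_that("the emulation preset pools to the exact expected codon total", {
  sim <- generate_set(ctv_preset(seed = 11))
  m <- count_codons(sim$set)
  expect_identical(nrow(m), 122L)
  expect_equal(sum(m), 122 * 223)
})
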