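test_that("RSCU closed forms, normalization and missing families", {
  ala <- c(GCU = 3, GCC = 1, GCA = 0, GCG = 0)
  r <- rscu(ala)
  expect_equal(unname(r$values[c("GCU", "GCC", "GCA", "GCG")]),
               c(3, 1, 0, 0))
  # absent amino acids carry NA, not 0
  expect_true(is.na(r$values[["UUU"]]))

  leu <- stats::setNames(rep(7, 6), cubkit:::CODON_FAMILIES[["L"]])
  expect_equal(unname(rscu(leu)$values[names(leu)]), rep(1, 6))

  met <- c(AUG = 5, UGG = 2, GCU = 1)
  expect_equal(rscu(met)$values[["AUG"]], 1)
  expect_equal(rscu(met)$values[["UGG"]], 1)

  # family-sum normalization, property over random tables
  for (seed in 1:20) {
    g <- random_counts(seed, lambda = 3)
    v <- rscu(g)$values
    aa <- translate_codons(cubkit:::SENSE_CODONS)
    sums <- tapply(v, aa, sum)
    n_i <- cubkit:::FAMILY_SIZES[names(sums)]
    present <- !is.na(sums)
    expect_equal(as.vector(sums[present]), as.vector(n_i[present]),
                 tolerance = 1e-9)
  }
})

test_that("high-frequency codon detection is inclusive and monotone", {
  v <- c(GCU = 1.05, GCC = 1.0499999, GCA = 0.9, GCG = 1.0001)
  expect_identical(high_frequency_codons(v), "GCU")

  fx <- load_ctv_rscu()
  hf_cs <- high_frequency_codons(fx$virus$Cs_CTV)
  expect_false("UUU" %in% hf_cs)     # 1.01 excluded
  expect_true("UUU" %in% high_frequency_codons(fx$virus$Cr_CTV))  # 1.14

  # monotone in threshold
  for (tab in fx$virus) {
    sets <- lapply(c(1.0, 1.05, 1.2, 1.5), function(t) {
      high_frequency_codons(tab, threshold = t)
    })
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
    }
  }
})

test_that("HFC classification follows the threshold rule on both sides", {
  fx <- load_ctv_rscu()
  cls <- classify_hfc(fx$virus$Ca_CTV, fx$host$C_aurantifolia)
  # boundary: virus 1.32 vs host 1.04 -> virus-specific
  expect_identical(as.character(cls$label[["GAA"]]), "HFC_V")
  cls_cr <- classify_hfc(fx$virus$Cr_CTV, fx$host$C_reticulata)
  # boundary: host 1.07 passes the inclusive threshold
  expect_identical(as.character(cls_cr$label[["AAG"]]), "HFC_H")

  # sub-threshold virus codons are non-HFC regardless of host
  below <- names(cls$label)[fx$virus$Ca_CTV[names(cls$label)] < 1.05]
  expect_true(all(cls$label[below] == "non-HFC"))

  # label invariants
  v <- fx$virus$Ca_CTV[names(cls$label)]
  h <- fx$host$C_aurantifolia[names(cls$label)]
  expect_true(all(v[cls$label != "non-HFC"] >= 1.05))
  expect_true(all(h[cls$label == "HFC_H"] >= 1.05))
  expect_true(all(h[cls$label == "HFC_V"] < 1.05))

  # missing host value under a virus HFC is an error naming the codon
  h2 <- fx$host$C_aurantifolia
  h2[["GCU"]] <- NA
  expect_error(classify_hfc(fx$virus$Ca_CTV, h2), "GCU")
})

test_that("conversion analysis is a disjoint label-flip report", {
  fx <- load_ctv_rscu()
  ca <- classify_hfc(fx$virus$Ca_CTV, fx$host$C_aurantifolia,
                     virus_label = "Ca")
  cr <- classify_hfc(fx$virus$Cr_CTV, fx$host$C_reticulata,
                     virus_label = "Cr")
  conv <- conversion_analysis(cr, ca)
  expect_length(intersect(conv$v_to_h, conv$h_to_v), 0)

  same <- conversion_analysis(ca, ca)
  expect_length(same$v_to_h, 0)
  expect_length(same$h_to_v, 0)

  short <- ca
  short$label <- ca$label[-1]
  expect_error(conversion_analysis(ca, short), "different codon sets")
})

test_that("CHFC: formula route equals direct counting and partitions f_j", {
  # toy: Leu only, subset {UUG} isolated via the host reference
  g <- stats::setNames(rep(0, 61), cubkit:::SENSE_CODONS)
  g[c("UUG", "CUU")] <- c(4, 2)
  host <- stats::setNames(rep(1, 61), cubkit:::SENSE_CODONS)
  host[["UUG"]] <- 1.5; host[["CUU"]] <- 0.5
  cls <- classify_hfc(rscu(g), host)
  expect_setequal(hfc_codons(cls, "HFC_H"), "UUG")
  expect_setequal(hfc_codons(cls, "HFC_V"), "CUU")
  s <- chfc(g, cls)
  leu <- s$per_aa[s$per_aa$aa == "L", ]
  expect_equal(leu$CHFC_H, 4)  # brute-force count of UUG
  expect_equal(leu$CHFC_V, 2)
  expect_equal(leu$f_j, 6)

  # property: partition and percentage identities on random inputs
  for (seed in 1:10) {
    g <- random_counts(seed, lambda = 6)
    hostR <- stats::setNames(stats::runif(61, 0.5, 1.5),
                             cubkit:::SENSE_CODONS)
    cls <- classify_hfc(rscu(g), hostR)
    s <- chfc(g, cls)
    expect_equal(s$per_aa$CHFC_H + s$per_aa$CHFC_V + s$per_aa$OSC,
                 s$per_aa$f_j)
    expect_equal(sum(s$overall), 100, tolerance = 1e-9)
  }

  # all codons of an amino acid in the subset -> CHFC = f_j
  host_all <- stats::setNames(rep(2, 61), cubkit:::SENSE_CODONS)
  g <- stats::setNames(rep(0, 61), cubkit:::SENSE_CODONS)
  g[cubkit:::CODON_FAMILIES[["A"]]] <- c(5, 3, 2, 1)
  cls <- classify_hfc(rscu(g) , host_all, threshold = 1e-6)
  s <- chfc(g, cls)
  ala <- s$per_aa[s$per_aa$aa == "A", ]
  expect_equal(ala$CHFC_H, 11)
  expect_equal(ala$CHFC_V + ala$OSC, 0)
})

test_that("RSCU report reproduces the packaged classification flags", {
  fx <- load_ctv_rscu()
  hosts <- fx$host[unname(cubkit:::CTV_SUBGROUP_HOST[names(fx$virus)])]
  rep3 <- rscu_report(fx$virus, hosts)
  expect_equal(nrow(rep3), 61)

  a <- ctv_hfc_analysis()
  for (sg in names(fx$virus)) {
    col <- rep3[[paste0(sg, "_class")]]
    names(col) <- rep3$codon
    lab <- a$classifications[[sg]]$label
    expect_identical(unname(col[names(lab)]), as.character(lab))
  }
  # no bias detected for glutamine anywhere
  gln <- rep3[rep3$aa == "Gln", grep("_class$", names(rep3))]
  expect_true(all(gln == "non-HFC"))
  # Met/Trp rows are never classified
  mw <- rep3[rep3$aa %in% c("Met", "Trp"), grep("_class$", names(rep3))]
  expect_true(all(mw == "non-HFC"))
})
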