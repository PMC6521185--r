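# cubkit — codon usage bias and virus–host codon co-adaptation

`cubkit` is an R package for analysing codon usage bias (CUB) in sets of
viral coding sequences partitioned by host of origin. It was built around a
study system of citrus tristeza virus coat-protein genes from three citrus
hosts, but every statistic is generic. For molecular evolution / plant
virology workflows it provides:

* **Composition indices** — A/C/G/U%, third-position (wobble) percentages,
  GC1/GC2/GC3/GC12, GC3s, Gravy, Aromo, with per-subgroup mean ± SE tables.
* **ENc** — Wright's effective number of codons
  (`2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6`; 20 = maximal bias, 61 = no bias) and
  the expected curve `ENc(s) = 2 + s + 29/(s² + (1−s)²)` for ENc–GC3 plots.
* **Neutrality regression** — OLS of GC12 on GC3 (slope ≈ 1: mutation
  pressure; ≈ 0: selection), plus index correlation matrices and one-way
  ANOVA of ENc across subgroups.
* **RSCU and high-frequency codons** —
  `RSCU_ij = g_ij · n_i / Σ g_ij`; codons with RSCU ≥ 1.05 (inclusive) are
  high-frequency, classified against a host codon-usage reference as
  host-coincident (**HFC_H**) or virus-specific (**HFC_V**), with
  between-subgroup conversion analysis and the **CHFC** contribution
  statistic `CHFC_j = Σ_{i∈S} RSCU_ij · f_j / n_i ≡ Σ_{i∈S} g_ij`.
* **CAI** — Sharp–Li codon adaptation index with RSCU-ratio relative
  adaptiveness `w` from host codon-usage tables.
* **Correspondence analysis** of the per-record 59-codon RSCU matrix.
* **Synthetic data** — a deterministic coding-sequence generator (target
  RSCU, mutation-pressure, or third-position-selection models) and host
  table generator, so the whole pipeline runs and is tested offline.

The published pooled RSCU table of the citrus study system (three virus
subgroups Ca-/Cr-/Cs-CTV and three hosts *C. aurantifolia*,
*C. reticulata*, *C. sinensis*) is packaged at
`inst/extdata/ctv_cp_rscu_published.tsv`. CBI and Fop are deliberately out
of scope: the source study tabulates them but never defines its
optimal-codon set.

## Worked example

Classify the Cr-CTV subgroup's high-frequency codons against its
*C. reticulata* host, straight from the packaged published table:

```r
library(cubkit)
fx  <- load_ctv_rscu()
cls <- classify_hfc(fx$virus$Cr_CTV, fx$host$C_reticulata,
                    virus_label = "Cr_CTV", host_label = "C_reticulata")
print(cls)
#> HFC classification (Cr_CTV vs C_reticulata, threshold 1.05): 13 HFC_H, 10 HFC_V
hfc_codons(cls, "HFC_H")
#>  [1] "GCU" "GAU" "UUU" "GGU" "AAG" "CUU" "UUG" "CCU" "AGA" "UCU" "ACU" "GUG"
#> [13] "GUU"
```

13 of Cr-CTV's 23 high-frequency codons are also high-frequency in its
host (host-coincident); the other 10 are virus-specific. The full
three-subgroup analysis, including which virus-specific codons of Cr-CTV
become host-coincident in the *C. sinensis* subgroup:

```r
a <- ctv_hfc_analysis()
a$conversions$Cr_CTV.Cs_CTV$v_to_h
#> [1] "UGU" "GAA" "AGU" "UAU"
```

End-to-end on synthetic data emulating the study's shape (29 + 38 + 55
records × 223 codons, codon choice targeting the published RSCU):

```r
sim <- generate_set(ctv_preset(seed = 1))
d   <- enc_gc3_data(sim$set)
sprintf("ENc mean %.2f range %.2f-%.2f; GC3s mean %.3f",
        mean(d$points$ENc), min(d$points$ENc), max(d$points$ENc),
        mean(d$points$GC3))
#> [1] "ENc mean 47.27 range 40.51-53.85; GC3s mean 0.380"
```

All records sit below the expected curve at their GC3 — the signature of
codon usage shaped by more than third-position composition. The full
pipeline (`run_pipeline()` or the `exec/cubkit` script) writes
composition, ENc–GC3, neutrality, RSCU/HFC classification, conversion,
CHFC, CAI, correspondence-analysis, correlation and ANOVA tables plus a
JSON manifest, byte-identical across reruns.

```sh
cubkit simulate --out sim --seed 9 --records 30
cubkit run --fasta sim/sequences.fasta --groups sim/groups.tsv \
           --host sim=host_counts.tsv --out results
```

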