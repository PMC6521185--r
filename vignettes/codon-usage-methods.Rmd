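---
title: "Methods: codon usage bias and virus-host codon co-adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias and virus-host codon co-adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

RNA viruses depend entirely on the host translation machinery, so the
synonymous-codon choices of a highly expressed viral gene (such as a coat
protein) carry a signal of both genome-wide mutation pressure and
host-imposed translational selection. `cubkit` packages the standard battery
of codon-usage-bias (CUB) statistics for a set of coding sequences
partitioned into subgroups by host of origin, plus a classification of each
virus high-frequency codon as host-coincident or virus-specific, and a
contribution statistic that weighs those classes by how much of the gene
they actually encode. The package ships a published reference table for a
three-host citrus study system and a synthetic coding-sequence generator,
so the whole pipeline is testable without network access.

## Statistics implemented

### RSCU

For codon $i$ of amino acid $j$ with family size $n_i$ (1-6 under the
standard genetic code),

$$\mathrm{RSCU}_{ij} = \frac{g_{ij}}{\sum_i g_{ij}}\, n_i ,$$

the observed count relative to equal within-family usage. Family values sum
to $n_i$; single-codon families (Met, Trp) are identically 1. Codons of an
amino acid absent from the input are reported as missing, never as 0 —
"never observed" and "cannot be observed" are different facts. Subgroup
RSCU is computed from counts **pooled** across member records (the CodonW
convention, and the only reading consistent with one printed value per
subgroup); per-record RSCU is retained for correspondence analysis.

### High-frequency codons, HFC_H / HFC_V, and CHFC

A codon is a *high-frequency codon* (HFC) when its RSCU is at or above a
threshold, default **1.05, inclusive**. The inclusivity is deliberate and
verified against boundary cases in the packaged table: a host value of 1.04
fails, 1.07 passes. Comparing a virus table against its host's table:

* **HFC_H** — virus RSCU ≥ threshold *and* host RSCU ≥ threshold
  (host-coincident; translationally favoured in both);
* **HFC_V** — virus RSCU ≥ threshold, host RSCU < threshold
  (virus-specific; escapes host preference);
* everything else in a degenerate family is non-HFC; Met/Trp are never
  classified.

The source study states this rule only through its table highlighting; the
rule above reproduces every one of its printed counts and membership lists,
and is flagged here as inferred. `conversion_analysis()` reports codons
whose label flips between two subgroup classifications.

The *contribution of high-frequency codons* for amino acid $j$ over a codon
subset $S$ is

$$\mathrm{CHFC}_j = \sum_{i \in S} \mathrm{RSCU}_{ij}\,\frac{f_j}{n_i}
                  = \sum_{i \in S} g_{ij},$$

an algebraic identity with the direct count. `chfc()` computes both routes
and errors if they disagree beyond 1e-6 — the identity is used as a
permanent internal self-check, not an assumption. Overall percentages
(CHFC_H, CHFC_V, COSC) divide the subset totals by all sense codons, so the
"other" share absorbs Met/Trp.

### ENc and the expected curve

Wright's effective number of codons estimates, per amino acid with $n \ge
2$ occurrences, the homozygosity $F = (n\sum_i \hat p_i^2 - 1)/(n-1)$,
averages it within degeneracy classes (9 twofold, Ile, 5 fourfold, 3
sixfold) and combines

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Numerical choices: families with $F \le 0$ (possible at small $n$) are
excluded from their class mean; an empty Ile class is imputed as
$(\bar F_2 + \bar F_4)/2$; an empty 2-, 4- or 6-fold class is an error
rather than silently rescaled — coat-protein-length sequences always
populate those classes, so an empty one signals broken input. Values above
61 are *reported with a warning, never clamped*: truncation would hide the
estimator's well-known upward small-sample bias rather than fix it.

The expected curve under pure third-position compositional bias is
$\mathrm{ENc}(s) = 2 + s + 29/(s^2 + (1-s)^2)$ with $s$ = GC3. Two
conventions matter here and are kept distinct: the Table-1-style
composition block reports GC3 over **all** sense codons, while the ENc plot
uses synonymous GC3 (**GC3s**, Met/Trp excluded), the convention of ENc
plots. The envelope property "observed ENc lies at or below the curve" is a
property of the frequency limit: at 223 codons the estimator's bias
produces overshoots of 10-20 units even for sequences whose only bias is
third-position composition, so the test suite checks the envelope at 5000
codons (where the overshoot stays within 2) and treats short-sequence ENc
as an estimate, not a bound.

### Neutrality regression, correlations, ANOVA

The neutrality plot regresses GC12 (mean of first- and second-position G+C)
on GC3 by ordinary least squares; slope near 1 means one mutational process
drives all positions, slope near 0 means positions 1-2 are held by
selection. Correlations between index columns are Pearson by default
(Spearman behind a flag) with two-tailed p-values flagged at 0.05/0.01 and
no multiple-testing correction — matching the source study's reporting,
which states only "two-tailed". ENc differences across subgroups use
classical equal-variance one-way ANOVA.

### Correspondence analysis

`correspondence_analysis()` implements classical CA: scale the nonnegative
records × 59 RSCU matrix to a correspondence table, center by the
independence model, SVD the standardized residuals
$D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, and report principal coordinates and
inertia fractions. Running CA on RSCU rather than raw counts follows the
CodonW convention (raw-count mode is a flag away: pass `count_codons()`
output). Per-subgroup runs are the default (the study's axis-contribution
figures imply runs of roughly subgroup size); a pooled run is available.
Axis signs are arbitrary in the SVD, so they are fixed by making the
largest-magnitude codon coordinate positive on each axis. All-zero codon
columns (codon never used) are dropped with a warning; a table fitting the
independence model exactly has zero inertia and is reported as degenerate
rather than returning noise axes.

### CAI

Relative adaptiveness is the Sharp-Li RSCU ratio
$w_i = \mathrm{RSCU}_i / \max_{i' \in \text{family}} \mathrm{RSCU}_{i'}$
computed from a count-backed host reference; zero host counts get a
pseudo-count of 0.5 first, so every $w$ is strictly positive (the behaviour
of the CAIcal family of tools). CAI is the geometric mean of $w$ over a
sequence's codons, Met/Trp excluded (single-codon families carry no
information), computed on the log scale to avoid underflow on long
sequences. The study's printed CAI values cannot be reproduced without its
exact host-table snapshot, so the testable surface is ordering: sequences
generated to prefer a host's optimal codons must outscore sequences
generated against them, and they do.

## The synthetic generator

`generate_set()` draws each codon in two stages: amino acid from a fixed
composition, then codon from family-conditional frequencies given by the
model. This makes RSCU targets exactly invertible — the conditional
frequency of codon $i$ is simply $\mathrm{RSCU}_i / n_i$. Three models:

* **target-rscu** — per-subgroup published or user RSCU tables (validated
  for family-sum normalization);
* **mutation-pressure** — one per-record GC bias $\beta$ applied to all
  three positions through nucleotide-level codon weights (stops excluded);
  recovers a neutrality slope near 1;
* **third-position-selection** — fixed amino-acid usage, $\beta$ applied to
  the wobble base only; recovers a slope near 0.

The coat-protein emulation preset (`ctv_preset()`) fixes the study's stated
world: 29 + 38 + 55 records in three host-labelled subgroups, 223
translatable codons each, codon choice targeting the three published
subgroup RSCU columns. The amino-acid composition was calibrated **once**,
by constrained least squares from a typical globular-protein composition,
so that the implied nucleotide composition matches the published regime
(AU = 55.7%, mean GC3 = 0.385 inside the published 0.36-0.41 band); the
result is frozen as a package constant and is not a tuning knob.

What the generator does *not* emulate: real isolates are phylogenetically
correlated near-copies of each other, so their between-record variance in
GC3 or ENc is far smaller than that of independent multinomial draws; the
preset's per-record GC3 therefore spreads roughly ±0.03 around the band
rather than sitting inside it record-by-record. No indels, recombination or
alignment error are simulated. A green test on synthetic data establishes
that the statistics recover known generating parameters — not that the
generator reproduces every moment of the real dataset.

## Determinism and formatting

Generation is a pure function of (spec, seed) through R's default
Mersenne-Twister stream. Pipeline TSV outputs are written at 6 significant
digits with fixed formatting, so repeated runs on identical inputs are
byte-identical; the JSON manifest records version, seed, threshold and a
config fingerprint.

## Known limitations

* CBI and Fop appear in the source study's table but its optimal-codon set
  is never defined, so both are deliberately out of scope.
* The published continuous-valued results (composition means, correlation
  table, neutrality slope -0.058, CAI 0.816/0.778/0.755, COA axis
  percentages) require the original 122 GenBank sequences and the authors'
  host-table snapshot; the package reproduces the machinery and checks it
  by property, parameter recovery, and the exactly reproducible
  classification counts instead.
* Wright's ENc estimator is biased upward at gene-length samples; compare
  ENc values only between sequences of similar length.
* The HFC_H/HFC_V rule is inferred from the published table's highlighting
  (it reproduces all printed counts); treat the labels as that study's
  operational definition, not a mechanistic statement.
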