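Package: cubkit
Title: Codon Usage Bias Analysis for Viral Coding Sequences
Version: 0.9.0
Authors@R:
    person("CUB", "Maintainers", email = "cubkit@example.org", role = c("aut", "cre"))
Description: Tools for quantifying codon usage bias in sets of viral coding
    sequences and for measuring virus-host codon co-adaptation. Implements
    nucleotide and position-specific composition indices, Wright's effective
    number of codons (ENc) with the ENc-GC3 expected curve, neutrality
    (GC12 vs GC3) regression, relative synonymous codon usage (RSCU),
    high-frequency codon classification against host codon-usage references
    (host-coincident HFC_H vs virus-specific HFC_V), the contribution of
    high-frequency codons (CHFC) summary statistic, the codon adaptation
    index (CAI), and correspondence analysis of per-record RSCU matrices.
    Ships a deterministic synthetic coding-sequence generator with
    controllable codon-choice models (target RSCU, genome-wide mutation
    pressure, third-position selection) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
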