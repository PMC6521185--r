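# RSCU, high-frequency-codon detection and host-vs-virus classification,
# between-subgroup conversion analysis, and the CHFC contribution statistic.

#' Relative synonymous codon usage
#'
#' For codon i of amino acid j with family size `n_i`,
#' `RSCU_ij = g_ij * n_i / sum_i g_ij`: the observed count relative to the
#' expectation under equal within-family usage. Family values sum to `n_i`.
#' Single-codon families (Met, Trp) give 1 when present. Codons of an amino
#' acid absent from the input carry `NA`, not 0.
#'
#' @param counts codon counts (named vector or a count matrix, pooled).
#' @return an `rscu_table`: list with `values` (named numeric over the 61
#'   sense codons, `NA` for absent families), `family_sizes`, and
#'   `aa_counts` (f_j per amino acid).
#' @export
rscu <- function(counts) {
  g <- as_count_vector(counts)[SENSE_CODONS]
  aa <- codon_aa(SENSE_CODONS)
  fj <- rowsum(g, aa)[, 1]
  values <- g * FAMILY_SIZES[aa] / fj[aa]
  values[fj[aa] == 0] <- NA_real_
  structure(
    list(values = values, family_sizes = FAMILY_SIZES, aa_counts = fj),
    class = "rscu_table"
  )
}

# accept an rscu_table or a bare named vector of RSCU values
as_rscu_values <- function(x) {
  if (inherits(x, "rscu_table")) return(x$values)
  if (inherits(x, "codon_usage_reference")) return(reference_rscu(x))
  if (is.numeric(x) && !is.null(names(x))) {
    full <- stats::setNames(rep(NA_real_, length(SENSE_CODONS)), SENSE_CODONS)
    full[intersect(names(x), SENSE_CODONS)] <-
      x[intersect(names(x), SENSE_CODONS)]
    return(full)
  }
  stop("expected an rscu_table, codon_usage_reference, or named RSCU vector")
}

#' High-frequency codons of an RSCU table
#'
#' Codons with RSCU at or above `threshold` (inclusive). Single-codon
#' families (Met, Trp) and codons with missing RSCU never qualify.
#'
#' @param x an `rscu_table`, `codon_usage_reference`, or named RSCU vector.
#' @param threshold RSCU cutoff (default 1.05).
#' @return character vector of codons, in genetic-code order.
#' @export
high_frequency_codons <- function(x, threshold = 1.05) {
  v <- as_rscu_values(x)[DEGENERATE_CODONS]
  names(v)[!is.na(v) & v >= threshold]
}

#' Classify virus high-frequency codons against a host reference
#'
#' A virus codon with RSCU >= `threshold` is a high-frequency codon (HFC).
#' It is host-coincident (`HFC_H`) when the host RSCU is also at or above
#' the threshold, and virus-specific (`HFC_V`) otherwise. All remaining
#' degenerate-family codons are `non-HFC`; Met/Trp are never classified.
#'
#' @param virus_rscu virus RSCU (`rscu_table` or named vector).
#' @param host_rscu host RSCU (`rscu_table`, `codon_usage_reference`, or
#'   named vector).
#' @param threshold RSCU cutoff, inclusive (default 1.05).
#' @param virus_label,host_label labels stored on the result.
#' @return an `hfc_classification`: list with `label` (factor over the 59
#'   degenerate-family codons, levels HFC_H/HFC_V/non-HFC), `threshold`,
#'   `virus_label`, `host_label`.
#' @export
classify_hfc <- function(virus_rscu, host_rscu, threshold = 1.05,
                         virus_label = "virus", host_label = "host") {
  v <- as_rscu_values(virus_rscu)[DEGENERATE_CODONS]
  h <- as_rscu_values(host_rscu)[DEGENERATE_CODONS]
  hfc <- !is.na(v) & v >= threshold
  bad <- hfc & is.na(h)
  if (any(bad)) {
    stop("missing host RSCU for virus high-frequency codon(s): ",
         paste(names(v)[bad], collapse = ", "))
  }
  label <- rep("non-HFC", length(v))
  label[hfc & h >= threshold] <- "HFC_H"
  label[hfc & h < threshold] <- "HFC_V"
  structure(
    list(label = stats::setNames(
           factor(label, levels = c("HFC_H", "HFC_V", "non-HFC")),
           names(v)),
         threshold = threshold, virus_label = virus_label,
         host_label = host_label),
    class = "hfc_classification"
  )
}

#' Codons carrying a given HFC label
#' @param x an `hfc_classification`.
#' @param label one of `"HFC_H"`, `"HFC_V"`, `"non-HFC"`.
#' @return character vector of codons.
#' @export
hfc_codons <- function(x, label = c("HFC_H", "HFC_V", "non-HFC")) {
  stopifnot(inherits(x, "hfc_classification"))
  label <- match.arg(label)
  names(x$label)[x$label == label]
}

#' @export
print.hfc_classification <- function(x, ...) {
  cat("HFC classification (", x$virus_label, " vs ", x$host_label,
      ", threshold ", x$threshold, "): ",
      sum(x$label == "HFC_H"), " HFC_H, ",
      sum(x$label == "HFC_V"), " HFC_V\n", sep = "")
  invisible(x)
}

#' High-frequency codon conversions between two subgroup classifications
#'
#' Reports the codons whose label flips between two virus/host pairs:
#' `v_to_h` are HFC_V in `class_a` and HFC_H in `class_b`; `h_to_v` the
#' reverse. The two sets are disjoint by construction.
#'
#' @param class_a,class_b `hfc_classification` objects over the same codons.
#' @return a `conversion_report`: list with `v_to_h`, `h_to_v`, `from`, `to`.
#' @export
conversion_analysis <- function(class_a, class_b) {
  stopifnot(inherits(class_a, "hfc_classification"),
            inherits(class_b, "hfc_classification"))
  if (!identical(names(class_a$label), names(class_b$label))) {
    stop("classifications cover different codon sets")
  }
  structure(
    list(
      v_to_h = names(class_a$label)[class_a$label == "HFC_V" &
                                      class_b$label == "HFC_H"],
      h_to_v = names(class_a$label)[class_a$label == "HFC_H" &
                                      class_b$label == "HFC_V"],
      from = class_a$virus_label, to = class_b$virus_label
    ),
    class = "conversion_report"
  )
}

#' Contribution of high-frequency codons (CHFC)
#'
#' For a codon subset S of amino acid j, the contribution is
#' `sum_{i in S} RSCU_ij * f_j / n_i`, which by the RSCU definition equals
#' the directly counted occurrences `sum_{i in S} g_ij`. Both routes are
#' computed and must agree to 1e-6 (internal self-check). Per-amino-acid
#' contributions are reported for the HFC_H set, the HFC_V set, and the
#' remaining ("other synonymous") codons; overall percentages are the subset
#' totals over the total sense-codon count.
#'
#' @param counts pooled codon counts the classification was derived from.
#' @param classification an `hfc_classification`.
#' @return a `chfc_summary`: list with `per_aa` (data.frame: aa, f_j,
#'   CHFC_H, CHFC_V, OSC) and `overall` (named percentages `CHFC_H`,
#'   `CHFC_V`, `COSC`).
#' @export
chfc <- function(counts, classification) {
  stopifnot(inherits(classification, "hfc_classification"))
  g <- as_count_vector(counts)[SENSE_CODONS]
  r <- rscu(g)
  aa <- codon_aa(SENSE_CODONS)
  fj <- r$aa_counts
  total <- sum(g)
  if (total < 1) stop("empty count table")

  subset_contrib <- function(codons) {
    direct <- rowsum(g[codons], aa[match(codons, SENSE_CODONS)])
    formula_route <- rowsum(
      r$values[codons] * fj[aa[match(codons, SENSE_CODONS)]] /
        FAMILY_SIZES[aa[match(codons, SENSE_CODONS)]],
      aa[match(codons, SENSE_CODONS)])
    formula_route[is.na(formula_route)] <- 0
    if (max(abs(direct - formula_route)) > 1e-6) {
      stop("internal error: CHFC formula route disagrees with direct counts")
    }
    out <- stats::setNames(rep(0, length(fj)), names(fj))
    out[rownames(direct)] <- direct[, 1]
    out
  }

  lab <- classification$label
  set_h <- names(lab)[lab == "HFC_H"]
  set_v <- names(lab)[lab == "HFC_V"]
  set_o <- setdiff(SENSE_CODONS, c(set_h, set_v))
  ch <- subset_contrib(set_h)
  cv <- subset_contrib(set_v)
  co <- subset_contrib(set_o)
  stopifnot(all(abs(ch + cv + co - fj) < 1e-9))
  structure(
    list(
      per_aa = data.frame(aa = names(fj), f_j = unname(fj),
                          CHFC_H = unname(ch), CHFC_V = unname(cv),
                          OSC = unname(co)),
      overall = c(CHFC_H = 100 * sum(ch) / total,
                  CHFC_V = 100 * sum(cv) / total,
                  COSC = 100 * sum(co) / total)
    ),
    class = "chfc_summary"
  )
}

#' Table-3-style RSCU report
#'
#' Assembles a 61-row codon table (amino acid, codon, one RSCU column per
#' source) with per-pair HFC flags encoded as label columns.
#'
#' @param virus_tables named list of virus RSCU sources (one per subgroup).
#' @param host_tables named list of host RSCU sources, parallel to
#'   `virus_tables` (the i-th host is the reference for the i-th subgroup).
#' @param threshold RSCU cutoff.
#' @return data.frame with columns `aa`, `codon`, `<source>` RSCU columns,
#'   and `<subgroup>_class` label columns.
#' @export
rscu_report <- function(virus_tables, host_tables, threshold = 1.05) {
  stopifnot(length(virus_tables) == length(host_tables))
  codons <- SENSE_CODONS
  ord <- order(match(codon_aa(codons), names(AA_THREE_LETTER)))
  codons <- codons[ord]
  out <- data.frame(aa = AA_THREE_LETTER[codon_aa(codons)], codon = codons,
                    row.names = NULL)
  for (nm in names(virus_tables)) {
    out[[nm]] <- as_rscu_values(virus_tables[[nm]])[codons]
  }
  for (nm in names(host_tables)) {
    out[[nm]] <- as_rscu_values(host_tables[[nm]])[codons]
  }
  for (i in seq_along(virus_tables)) {
    cls <- classify_hfc(virus_tables[[i]], host_tables[[i]],
                        threshold = threshold,
                        virus_label = names(virus_tables)[i],
                        host_label = names(host_tables)[i])
    lab <- as.character(cls$label[codons])
    lab[is.na(lab)] <- "non-HFC"
    out[[paste0(names(virus_tables)[i], "_class")]] <- lab
  }
  out
}
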