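# Codon adaptation index against a host codon-usage reference
# (Sharp-Li formulation, RSCU-ratio relative adaptiveness).

#' Relative adaptiveness of codons under a host reference
#'
#' `w_i = RSCU_i / max(RSCU within the family)`, so the most-used codon of
#' every family has w = 1. Host codons with zero counts receive a
#' pseudo-count of 0.5 before RSCU is computed, keeping every w strictly
#' positive. Met, Trp and stop codons are excluded.
#'
#' @param host_reference a `codon_usage_reference` with counts, or a named
#'   count vector over sense codons.
#' @param pseudo_count value substituted for zero host counts (default 0.5).
#' @return a `relative_adaptiveness`: list with `w` (named over the 59
#'   degenerate-family codons, all in (0, 1]) and `reference_label`.
#' @export
relative_adaptiveness <- function(host_reference, pseudo_count = 0.5) {
  label <- "host"
  if (inherits(host_reference, "codon_usage_reference")) {
    if (is.null(host_reference$counts)) {
      stop("relative adaptiveness needs a count-backed reference ",
           "(rscu-direct references carry no counts)")
    }
    label <- host_reference$source_label
    counts <- host_reference$counts
  } else {
    counts <- host_reference
  }
  g <- as_count_vector(counts)[DEGENERATE_CODONS]
  aa <- codon_aa(DEGENERATE_CODONS)
  absent <- tapply(g, aa, sum) == 0
  if (any(absent)) {
    stop("host reference has no counts for amino acid(s): ",
         paste(names(absent)[absent], collapse = ", "))
  }
  g[g == 0] <- pseudo_count
  r <- g * FAMILY_SIZES[aa] / tapply(g, aa, sum)[aa]
  w <- r / tapply(r, aa, max)[aa]
  structure(list(w = stats::setNames(unname(w), DEGENERATE_CODONS),
                 reference_label = label),
            class = "relative_adaptiveness")
}

#' Codon adaptation index of a sequence
#'
#' Geometric mean of the relative adaptiveness w over the sequence's codons,
#' computed on the log scale to avoid underflow. Met, Trp and stop codons
#' are excluded from the mean.
#'
#' @param x a `coding_sequence`, a character vector of codons, or a named
#'   codon count vector/matrix.
#' @param w a `relative_adaptiveness`.
#' @return CAI value in (0, 1].
#' @export
cai <- function(x, w) {
  stopifnot(inherits(w, "relative_adaptiveness"))
  counts <- if (inherits(x, "coding_sequence")) {
    as_count_vector(count_codons(x))
  } else if (is.character(x)) {
    as_count_vector(table(factor(x, levels = all_codons())))
  } else {
    as_count_vector(x)
  }
  g <- counts[DEGENERATE_CODONS]
  n <- sum(g)
  if (n < 1) stop("no codons eligible for CAI")
  exp(sum(g * log(w$w)) / n)
}

#' Per-record CAI with subgroup summaries
#'
#' @param set a labelled `sequence_set`.
#' @param w_by_host named list of `relative_adaptiveness` objects keyed by
#'   host label; each record is scored against its own host's reference.
#' @return list with `records` (data.frame id, subgroup, host, CAI) and
#'   `subgroup_summary` (data.frame subgroup, n, mean, se).
#' @export
cai_by_subgroup <- function(set, w_by_host) {
  stopifnot(inherits(set, "sequence_set"))
  hosts <- vapply(set, `[[`, character(1), "host")
  missing <- setdiff(unique(hosts), names(w_by_host))
  if (length(missing)) {
    stop("no relative-adaptiveness table for host(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- vapply(seq_along(set), function(i) cai(set[[i]], w_by_host[[hosts[i]]]),
                 numeric(1))
  rec <- data.frame(id = names(set), subgroup = subgroups(set), host = hosts,
                    CAI = vals, row.names = NULL)
  agg <- do.call(rbind, lapply(split(rec$CAI, rec$subgroup), function(v) {
    data.frame(n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }))
  agg <- data.frame(subgroup = rownames(agg), agg, row.names = NULL)
  list(records = rec, subgroup_summary = agg)
}
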