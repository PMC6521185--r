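# ENc-GC3 expected curve, neutrality (GC12 ~ GC3) regression, index
# correlation matrix, and one-way ANOVA of ENc across subgroups.

#' Expected ENc under pure GC3 compositional bias
#'
#' Wright's standard curve `ENc(s) = 2 + s + 29 / (s^2 + (1 - s)^2)` for
#' third-position G+C content s: the ENc a gene would show if codon usage
#' were determined by GC3 alone.
#'
#' @param s GC3 fraction(s), strictly inside (0, 1).
#' @return expected ENc value(s).
#' @export
expected_enc <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    stop("s must lie strictly inside (0, 1)")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENc-GC3 plot data
#'
#' Per-record (GC3, ENc) pairs with the expected curve sampled on a GC3
#' grid. GC3 here is the synonymous third-position G+C (`GC3s`, Met/Trp
#' excluded), the convention of ENc plots.
#'
#' @param set a `sequence_set`.
#' @param grid GC3 grid for the expected curve (default 0.01..0.99).
#' @return list with `points` (data.frame id, subgroup, GC3, ENc, expected)
#'   and `curve` (data.frame GC3, expected).
#' @export
enc_gc3_data <- function(set, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(set, "sequence_set"))
  counts <- count_codons(set)
  gc3 <- vapply(set, function(s) nucleotide_composition(s)[["GC3s"]],
                numeric(1))
  enc <- apply(counts, 1, effective_number_of_codons)
  pts <- data.frame(id = names(set), subgroup = subgroups(set),
                    GC3 = unname(gc3), ENc = unname(enc), row.names = NULL)
  pts$expected <- ifelse(pts$GC3 > 0 & pts$GC3 < 1,
                         expected_enc(pmin(pmax(pts$GC3, 1e-9), 1 - 1e-9)),
                         NA)
  list(points = pts, curve = data.frame(GC3 = grid, expected = expected_enc(grid)))
}

#' Neutrality regression (GC12 on GC3)
#'
#' Ordinary least squares of GC12 on GC3 with the Pearson correlation and
#' its two-tailed p-value. A slope near 1 indicates genome-wide mutation
#' pressure acting on all codon positions; a slope near 0 indicates
#' selection constraining positions 1-2.
#'
#' @param gc12,gc3 equal-length numeric vectors (fractions), n >= 3.
#' @return a `neutrality_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `pearson_r`, `p_value`, `n`.
#' @export
neutrality_regression <- function(gc12, gc3) {
  stopifnot(length(gc12) == length(gc3))
  if (length(gc3) < 3) stop("need at least 3 records")
  if (stats::sd(gc3) == 0) stop("slope undefined: zero variance in GC3")
  fit <- stats::lm(gc12 ~ gc3)
  degenerate_y <- stats::sd(gc12) == 0
  ct <- if (degenerate_y) {
    list(estimate = 0, p.value = 1)
  } else {
    stats::cor.test(gc12, gc3)
  }
  structure(
    list(slope = if (degenerate_y) 0 else unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (degenerate_y) 0 else summary(fit)$r.squared,
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         n = length(gc3)),
    class = "neutrality_fit"
  )
}

#' Pairwise correlation matrix with significance flags
#'
#' Pearson (default) or Spearman correlations between codon-usage index
#' columns, with two-tailed p-values and significance flags at the 0.05 and
#' 0.01 levels. No multiple-testing correction is applied. Constant columns
#' yield `NA` correlations.
#'
#' @param index_table numeric data.frame or matrix, records x indices.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with matrices `r`, `p`, and character matrix `flag`
#'   (`""`, `"*"`, `"**"`).
#' @export
correlation_matrix <- function(index_table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(index_table)
  if (nrow(m) < 3) stop("need at least 3 records")
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
      ct <- suppressWarnings(stats::cor.test(m[, i], m[, j], method = method))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  flag <- matrix("", k, k, dimnames = dimnames(r))
  flag[!is.na(p) & p < 0.05] <- "*"
  flag[!is.na(p) & p < 0.01] <- "**"
  diag(flag) <- ""
  list(r = r, p = p, flag = flag)
}

#' Codon-usage index table for correlation analysis
#'
#' One row per record: CAI (optional), ENc, GC1, GC2, GC12, GC3, A, C, U, G,
#' GU, AC, GU3, AU3.
#'
#' @param set a `sequence_set`.
#' @param cai_values optional named numeric of per-record CAI.
#' @return numeric data.frame.
#' @export
index_table <- function(set, cai_values = NULL) {
  stopifnot(inherits(set, "sequence_set"))
  prof <- t(vapply(set, composition_profile, composition_profile(set[[1]])))
  cols <- c("ENc", "GC1", "GC2", "GC12", "GC3", "A", "C", "U", "G",
            "GU", "AC", "GU3", "AU3")
  out <- as.data.frame(prof[, cols, drop = FALSE])
  if (!is.null(cai_values)) {
    out <- cbind(CAI = unname(cai_values[rownames(prof)]), out)
  }
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (equal variances).
#'
#' @param values numeric vector.
#' @param group_labels parallel vector of group labels; >= 2 groups, each
#'   with n >= 2.
#' @return list with `F`, `p`, `df`, and `group_means`.
#' @export
one_way_anova <- function(values, group_labels) {
  stopifnot(length(values) == length(group_labels))
  g <- factor(group_labels)
  n_per <- table(g)
  if (length(n_per) < 2) stop("need at least 2 groups")
  if (any(n_per < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter),
       group_means = tapply(values, g, mean))
}
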