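# Correspondence analysis of the per-record RSCU matrix (records x 59
# degenerate-family codons), following the chi-square-metric SVD of the
# standardized residuals.

#' Build the records-by-codons RSCU matrix
#'
#' One row per record, one column per degenerate-family codon (59; Met, Trp
#' and stops excluded). RSCU values missing because an amino acid is absent
#' from a record are imputed as 0 with a warning.
#'
#' @param set a `sequence_set` with at least 3 records.
#' @return numeric matrix, rownames = record ids.
#' @export
build_rscu_matrix <- function(set) {
  stopifnot(inherits(set, "sequence_set"))
  if (length(set) < 3) stop("need at least 3 records")
  counts <- count_codons(set)
  m <- t(apply(counts, 1, function(g) rscu(g)$values[DEGENERATE_CODONS]))
  colnames(m) <- DEGENERATE_CODONS
  if (anyNA(m)) {
    warning(sum(is.na(m)), " missing RSCU value(s) (absent amino acids) ",
            "imputed as 0")
    m[is.na(m)] <- 0
  }
  m
}

#' Classical correspondence analysis
#'
#' Treats the non-negative input as a correspondence table: scales to grand
#' total 1, centers by the independence model, and decomposes the
#' standardized residuals `diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c))` by
#' SVD. Axis inertias are the squared singular values; coordinates are
#' principal (mass-weighted mean squared coordinates reproduce each axis's
#' inertia). All-zero columns are dropped with a warning. Axis signs are
#' fixed by making the largest-magnitude column (codon) coordinate positive
#' on every axis.
#'
#' @param x non-negative matrix with no all-zero rows.
#' @param n_axes number of axes to retain (default all non-trivial).
#' @return a `coa_result`: list with `inertia` (per-axis), `inertia_fraction`,
#'   `total_inertia`, `row_coords`, `col_coords`, `row_mass`, `col_mass`.
#' @export
correspondence_analysis <- function(x, n_axes = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entries in correspondence table")
  if (any(rowSums(x) == 0)) stop("all-zero row(s) in correspondence table")
  zero_col <- colSums(x) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " all-zero column(s): ",
            paste(colnames(x)[zero_col], collapse = ", "))
    x <- x[, !zero_col, drop = FALSE]
  }
  P <- x / sum(x)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  if (!any(keep)) {
    stop("degenerate table: independence model fits exactly (zero inertia)")
  }
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # principal coordinates
  F_ <- diag(1 / sqrt(r)) %*% U %*% diag(d, nrow = length(d))
  G_ <- diag(1 / sqrt(cm)) %*% V %*% diag(d, nrow = length(d))
  # sign convention: largest |column coordinate| positive per axis
  for (k in seq_along(d)) {
    j <- which.max(abs(G_[, k]))
    if (G_[j, k] < 0) {
      G_[, k] <- -G_[, k]
      F_[, k] <- -F_[, k]
    }
  }
  if (!is.null(n_axes)) {
    if (n_axes > length(d)) stop("requested ", n_axes, " axes, only ",
                                 length(d), " available")
    d <- d[seq_len(n_axes)]
    F_ <- F_[, seq_len(n_axes), drop = FALSE]
    G_ <- G_[, seq_len(n_axes), drop = FALSE]
  }
  dimnames(F_) <- list(rownames(x), paste0("Axis", seq_along(d)))
  dimnames(G_) <- list(colnames(x), paste0("Axis", seq_along(d)))
  inertia <- d^2
  structure(
    list(inertia = inertia, inertia_fraction = inertia / sum(sv$d[keep]^2),
         total_inertia = sum(sv$d[keep]^2),
         row_coords = F_, col_coords = G_, row_mass = r, col_mass = cm),
    class = "coa_result"
  )
}

#' Axis contribution report
#'
#' Percent inertia explained by the first `k` axes, with codon coordinates
#' labelled by their third (ending) nucleotide for RSCU-matrix runs.
#'
#' @param result a `coa_result`.
#' @param k number of axes to report (default 2).
#' @return list with `axis_percent` (named numeric, length k) and `codons`
#'   (data.frame codon, ending, coordinates on the k axes; `NULL` when the
#'   columns are not codons).
#' @export
axis_contribution_report <- function(result, k = 2) {
  stopifnot(inherits(result, "coa_result"))
  n_avail <- length(result$inertia)
  if (k > n_avail) {
    if (k == 2 && n_avail == 1) {
      # degenerate single-axis case: report Axis 2 as 0
      pct <- c(100 * result$inertia_fraction[1], 0)
      names(pct) <- c("Axis1", "Axis2")
      return(list(axis_percent = pct, codons = NULL))
    }
    stop("requested ", k, " axes, only ", n_avail, " available")
  }
  pct <- 100 * result$inertia_fraction[seq_len(k)]
  names(pct) <- paste0("Axis", seq_len(k))
  codons <- NULL
  cn <- rownames(result$col_coords)
  if (!is.null(cn) && all(grepl("^[ACGU]{3}$", cn))) {
    codons <- data.frame(codon = cn, ending = substr(cn, 3, 3),
                         result$col_coords[, seq_len(k), drop = FALSE],
                         row.names = NULL)
  }
  list(axis_percent = pct, codons = codons)
}
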