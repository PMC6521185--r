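# Deterministic synthetic coding-sequence generator. Three codon-choice
# models: target-rscu (family-conditional frequencies implied by an RSCU
# table), mutation-pressure (one GC bias applied to all three positions),
# and third-position-selection (fixed amino-acid usage, biased wobble base).

#' Specify a synthetic sequence set
#'
#' @param n_records named integer vector: records per subgroup (names are
#'   the subgroup labels).
#' @param n_codons translatable codons per record (default 223, the
#'   coat-protein length the generator emulates).
#' @param hosts named character vector mapping subgroup -> host label
#'   (default: subgroup label itself).
#' @param aa_freq named amino-acid frequency vector over the 20 one-letter
#'   codes (default uniform). Ignored by the mutation-pressure model, which
#'   draws codons directly.
#' @param model codon-choice model: one of
#'   `model_target_rscu(rscu_by_subgroup)`,
#'   `model_mutation_pressure(beta_range)`,
#'   `model_third_position_selection(beta_range)`.
#' @param terminal_stop append a stop codon to each record (default TRUE).
#' @param start_codon force the first amino acid to Met (default TRUE).
#' @param seed integer seed; same spec + same seed gives byte-identical
#'   output.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_records, n_codons = 223, hosts = NULL,
                           aa_freq = NULL, model = model_mutation_pressure(),
                           terminal_stop = TRUE, start_codon = TRUE,
                           seed = 1L) {
  if (is.null(names(n_records)) || any(names(n_records) == "")) {
    stop("n_records must be named by subgroup")
  }
  if (any(n_records < 1)) stop("every subgroup needs at least one record")
  if (n_codons < 2) stop("n_codons must be at least 2")
  if (is.null(hosts)) hosts <- stats::setNames(names(n_records), names(n_records))
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / 20, 20), names(AA_THREE_LETTER))
  }
  if (!setequal(names(aa_freq), names(AA_THREE_LETTER))) {
    stop("aa_freq must cover exactly the 20 amino acids")
  }
  aa_freq <- aa_freq[names(AA_THREE_LETTER)] / sum(aa_freq)
  structure(
    list(n_records = n_records, n_codons = n_codons, hosts = hosts,
         aa_freq = aa_freq, model = model, terminal_stop = terminal_stop,
         start_codon = start_codon, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @param rscu_by_subgroup named list (one entry per subgroup) of RSCU
#'   vectors/tables; within-family codon probabilities are `RSCU / n_i`.
#' @export
model_target_rscu <- function(rscu_by_subgroup) {
  probs <- lapply(rscu_by_subgroup, function(tab) {
    v <- as_rscu_values(tab)
    if (anyNA(v)) stop("target RSCU table has missing families")
    aa <- codon_aa(SENSE_CODONS)
    fam_sum <- tapply(v, aa, sum)
    if (any(abs(fam_sum - FAMILY_SIZES[names(fam_sum)]) > 0.25)) {
      stop("target RSCU violates family-sum normalization for: ",
           paste(names(fam_sum)[abs(fam_sum - FAMILY_SIZES[names(fam_sum)]) > 0.25],
                 collapse = ", "))
    }
    p <- v / fam_sum[aa]   # renormalized within family (tolerates rounding)
    stats::setNames(as.numeric(p), SENSE_CODONS)
  })
  list(type = "target-rscu", codon_probs = probs)
}

#' @rdname synthetic_spec
#' @param beta_range range of the per-record GC bias parameter (probability
#'   that a generated base is G or C).
#' @export
model_mutation_pressure <- function(beta_range = c(0.30, 0.60)) {
  stopifnot(length(beta_range) == 2, all(beta_range > 0), all(beta_range < 1))
  list(type = "mutation-pressure", beta_range = beta_range)
}

#' @rdname synthetic_spec
#' @export
model_third_position_selection <- function(beta_range = c(0.30, 0.60)) {
  stopifnot(length(beta_range) == 2, all(beta_range > 0), all(beta_range < 1))
  list(type = "third-position-selection", beta_range = beta_range)
}

# codon probabilities over the 61 sense codons for one GC bias beta applied
# to all three positions
mutation_codon_probs <- function(beta) {
  base_w <- c(A = (1 - beta) / 2, C = beta / 2, G = beta / 2, U = (1 - beta) / 2)
  w <- vapply(SENSE_CODONS, function(cd) {
    prod(base_w[strsplit(cd, "")[[1]]])
  }, numeric(1))
  w / sum(w)
}

# within-family codon probabilities when only the third base is biased
selection_family_probs <- function(beta) {
  aa <- codon_aa(SENSE_CODONS)
  base_w <- c(A = (1 - beta) / 2, C = beta / 2, G = beta / 2, U = (1 - beta) / 2)
  w <- base_w[substr(SENSE_CODONS, 3, 3)]
  stats::setNames(as.numeric(w / tapply(w, aa, sum)[aa]), SENSE_CODONS)
}

# sample n codons for one record under the spec's model
sample_record_codons <- function(spec, subgroup, n) {
  model <- spec$model
  if (model$type == "mutation-pressure") {
    beta <- stats::runif(1, model$beta_range[1], model$beta_range[2])
    codons <- sample(SENSE_CODONS, n, replace = TRUE,
                     prob = mutation_codon_probs(beta))
    if (spec$start_codon) codons[1] <- "AUG"
    return(list(codons = codons, param = c(beta = beta)))
  }
  cond <- switch(model$type,
    "target-rscu" = {
      p <- model$codon_probs[[subgroup]]
      if (is.null(p)) stop("no target RSCU for subgroup ", subgroup)
      list(probs = p, param = NULL)
    },
    "third-position-selection" = {
      beta <- stats::runif(1, model$beta_range[1], model$beta_range[2])
      list(probs = selection_family_probs(beta), param = c(beta3 = beta))
    },
    stop("unknown model type: ", model$type)
  )
  aa_seq <- sample(names(spec$aa_freq), n, replace = TRUE, prob = spec$aa_freq)
  if (spec$start_codon) aa_seq[1] <- "M"
  aa <- codon_aa(SENSE_CODONS)
  codons <- vapply(aa_seq, function(a) {
    fam <- SENSE_CODONS[aa == a]
    p <- cond$probs[fam]
    if (sum(p) <= 0) stop("impossible spec: zero-probability family ", a)
    if (length(fam) == 1L) fam else sample(fam, 1, prob = p)
  }, character(1), USE.NAMES = FALSE)
  list(codons = codons, param = cond$param)
}

#' Generate a synthetic sequence set
#'
#' @param spec a `synthetic_spec`.
#' @return list with `set` (a labelled `sequence_set`), `group_map`
#'   (data.frame id/subgroup/host) and `truth` (generating parameters:
#'   spec fields plus per-record model draws, suitable for JSON
#'   serialization and recovery tests).
#' @export
generate_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  records <- list()
  params <- list()
  for (sg in names(spec$n_records)) {
    for (i in seq_len(spec$n_records[[sg]])) {
      id <- sprintf("%s_%03d", sg, i)
      drawn <- sample_record_codons(spec, sg, spec$n_codons)
      codons <- drawn$codons
      if (spec$terminal_stop) codons <- c(codons, "UAA")
      rec <- coding_sequence(id, paste(codons, collapse = ""),
                             subgroup = sg, host = spec$hosts[[sg]])
      records[[id]] <- rec
      if (!is.null(drawn$param)) params[[id]] <- as.list(drawn$param)
    }
  }
  set <- structure(records, class = "sequence_set")
  gm <- data.frame(id = names(set), subgroup = subgroups(set),
                   host = vapply(set, `[[`, character(1), "host"),
                   row.names = NULL)
  truth <- list(seed = spec$seed, n_codons = spec$n_codons,
                model = spec$model$type, n_records = as.list(spec$n_records),
                record_params = params)
  list(set = set, group_map = gm, truth = truth)
}

#' Generate a synthetic host codon-usage reference
#'
#' @param mode `"uniform"` (equal use of every sense codon), `"favor-set"`
#'   (codons in `favored` get `favor_weight`-fold the within-family weight
#'   of the rest, making them the family optima), or `"dirichlet"` (random
#'   within-family frequencies; needs `seed`).
#' @param favored character vector of codons for `favor-set` mode.
#' @param favor_weight weight multiplier (default 4).
#' @param total total count mass to distribute (default 1e6).
#' @param seed seed for `dirichlet` mode.
#' @param source_label label stored on the reference.
#' @return a count-backed `codon_usage_reference`.
#' @export
generate_host_table <- function(mode = c("uniform", "favor-set", "dirichlet"),
                                favored = character(), favor_weight = 4,
                                total = 1e6, seed = 1L,
                                source_label = paste0("synthetic-", mode[1])) {
  mode <- match.arg(mode)
  aa <- codon_aa(SENSE_CODONS)
  w <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (mode == "favor-set") {
    unknown <- setdiff(favored, SENSE_CODONS)
    if (length(unknown)) stop("unknown codon(s): ", paste(unknown, collapse = ", "))
    w[favored] <- favor_weight
  } else if (mode == "dirichlet") {
    set.seed(seed)
    w[] <- stats::rgamma(length(w), shape = 2, rate = 1) + 1e-3
  }
  # equal mass per amino acid, split within family by weight
  counts <- total / 20 * w / tapply(w, aa, sum)[aa]
  structure(list(source_label = source_label, dialect = "plain-tsv",
                 counts = round(stats::setNames(as.numeric(counts),
                                                SENSE_CODONS))),
            class = "codon_usage_reference")
}

# Preset amino-acid composition for the coat-protein emulation. Calibrated
# once (constrained least squares from a typical globular-protein
# composition) so that, under the published target RSCU, the expected
# nucleotide composition is AU = 55.7% and mean GC3 = 0.385 -- the published
# composition regime of the emulated dataset. Frozen; not a tuning knob.
CTV_CP_AA_FREQ <- c(
  A = 0.0890, R = 0.0651, N = 0.0217, D = 0.0558, C = 0.0454, Q = 0.0353,
  E = 0.0740, G = 0.0693, H = 0.0040, I = 0.0805, L = 0.0916, K = 0.0488,
  M = 0.0040, F = 0.0393, P = 0.0350, S = 0.0827, T = 0.0573, W = 0.0040,
  Y = 0.0374, V = 0.0601
)

#' The coat-protein emulation preset
#'
#' A `synthetic_spec` emulating the study dataset: 29 + 38 + 55 records in
#' three host-labelled subgroups, 223 translatable codons per record, codon
#' choice targeting the published per-subgroup RSCU values, and an
#' amino-acid composition calibrated once so the pooled nucleotide
#' composition is AU-rich (~56% AU) with per-record GC3 inside the
#' published 0.36-0.41 band.
#'
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
ctv_preset <- function(seed = 1L) {
  fx <- load_ctv_rscu()
  synthetic_spec(
    n_records = CTV_SUBGROUP_SIZES,
    n_codons = 223,
    hosts = CTV_SUBGROUP_HOST,
    aa_freq = CTV_CP_AA_FREQ,
    model = model_target_rscu(fx$virus),
    seed = seed
  )
}
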