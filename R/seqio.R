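# Reading, validation and codon counting for coding sequences, plus parsers
# for host codon-usage reference tables.

#' Construct a validated coding sequence
#'
#' Splits a nucleotide string into codons, normalizes T to U, detects and
#' strips a terminal stop, and rejects internal stops. Codons containing
#' ambiguity codes (N, R, Y, ...) are retained in the record but flagged so
#' that counting and every downstream statistic can exclude them.
#'
#' @param id record identifier.
#' @param sequence nucleotide string (DNA or RNA alphabet).
#' @param subgroup,host optional group labels.
#' @return an object of class `coding_sequence` with fields `id`, `subgroup`,
#'   `host`, `codons` (terminal stop removed), `terminal_stop` (logical) and
#'   `ambiguous` (logical mask over `codons`).
#' @export
coding_sequence <- function(id, sequence, subgroup = NA_character_,
                            host = NA_character_) {
  seq <- chartr("tu", "TU", toupper(gsub("\\s", "", sequence)))
  seq <- chartr("T", "U", seq)
  n <- nchar(seq)
  if (n == 0L) stop("record '", id, "': empty sequence")
  if (n %% 3L != 0L) {
    stop("record '", id, "': length not a multiple of 3 (", n, " nt)")
  }
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  ambiguous <- !grepl("^[ACGU]{3}$", codons)
  terminal_stop <- FALSE
  last <- codons[length(codons)]
  if (!ambiguous[length(codons)] && last %in% STOP_CODONS) {
    terminal_stop <- TRUE
    codons <- codons[-length(codons)]
    ambiguous <- ambiguous[-length(ambiguous)]
  }
  if (length(codons) == 0L) stop("record '", id, "': no codons besides stop")
  internal_stop <- !ambiguous & codons %in% STOP_CODONS
  if (any(internal_stop)) {
    stop("record '", id, "': internal stop codon at position ",
         paste(which(internal_stop), collapse = ", "))
  }
  structure(
    list(id = as.character(id), subgroup = subgroup, host = host,
         codons = codons, terminal_stop = terminal_stop,
         ambiguous = ambiguous),
    class = "coding_sequence"
  )
}

#' Sense codons of a record
#'
#' Unambiguous codons with the terminal stop already removed; the working
#' currency of all statistics.
#' @param x a `coding_sequence`.
#' @return character vector of RNA triplets.
#' @export
sense_codons <- function(x) {
  stopifnot(inherits(x, "coding_sequence"))
  x$codons[!x$ambiguous]
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped lines; DNA or
#'   RNA alphabet, T normalized to U).
#' @param drop_invalid if `TRUE`, records failing validation (internal stop,
#'   bad length) are dropped with a warning instead of raising an error.
#' @return a `sequence_set`: a list of `coding_sequence` objects, input order
#'   preserved, names = record ids.
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  out <- vector("list", length(raw))
  keep <- logical(length(raw))
  for (i in seq_along(raw)) {
    rec <- tryCatch(coding_sequence(ids[i], as.character(raw[[i]])),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (!drop_invalid) stop(conditionMessage(rec))
      warning("dropping ", conditionMessage(rec))
    } else {
      out[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  out <- out[keep]
  if (length(out) == 0L) stop("no valid records in ", path)
  names(out) <- vapply(out, `[[`, character(1), "id")
  structure(out, class = "sequence_set")
}

#' Write a sequence set to FASTA
#'
#' Codons are written in the RNA alphabet; a terminal stop flagged on read is
#' not restored (the stored codon list is the contract).
#' @param set a `sequence_set`.
#' @param path output file.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "sequence_set"))
  lines <- unlist(lapply(set, function(s) {
    c(paste0(">", s$id), paste(s$codons, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x), "records;",
      "codons per record:", paste(range(vapply(x, function(s) length(s$codons),
                                               integer(1))), collapse = "-"),
      "\n")
  invisible(x)
}

#' Read a record-to-(subgroup, host) map
#'
#' @param path TSV with columns `id`, `subgroup`, `host` (no header). A
#'   two-column file is accepted; `host` is then `NA`.
#' @return data.frame with columns id, subgroup, host.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) == 2L) df$V3 <- NA_character_
  if (ncol(df) != 3L) stop("group map must have 2 or 3 tab-separated columns")
  names(df) <- c("id", "subgroup", "host")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) stop("duplicate id(s) in group map: ",
                        paste(dup, collapse = ", "))
  df
}

#' Attach subgroup and host labels to a sequence set
#'
#' @param set a `sequence_set`.
#' @param map data.frame from [read_group_map()].
#' @return the labelled `sequence_set`.
#' @export
assign_groups <- function(set, map) {
  stopifnot(inherits(set, "sequence_set"))
  missing <- setdiff(names(set), map$id)
  if (length(missing)) {
    stop("id(s) in FASTA absent from group map: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(names(set), map$id)
  for (i in seq_along(set)) {
    set[[i]]$subgroup <- map$subgroup[idx[i]]
    set[[i]]$host <- map$host[idx[i]]
  }
  set
}

#' Subgroup label of every record
#' @param set a `sequence_set`.
#' @return named character vector.
#' @export
subgroups <- function(set) {
  vapply(set, `[[`, character(1), "subgroup")
}

#' Count codon occurrences
#'
#' Counts sense codons per record (terminal stops and ambiguous codons
#' excluded), optionally pooled by subgroup.
#'
#' @param set a `sequence_set` (or a single `coding_sequence`).
#' @param pooled if `TRUE`, additionally return one pooled table per subgroup.
#' @return with `pooled = FALSE` an integer matrix records x 64 (class
#'   `codon_count_matrix`); with `pooled = TRUE` a list with elements
#'   `records` (that matrix) and `subgroups` (subgroups x 64 matrix of
#'   element-wise sums).
#' @export
count_codons <- function(set, pooled = FALSE) {
  if (inherits(set, "coding_sequence")) set <- structure(list(set),
                                                         class = "sequence_set")
  stopifnot(inherits(set, "sequence_set"))
  codons64 <- all_codons()
  m <- t(vapply(set, function(s) {
    tabulate(factor(sense_codons(s), levels = codons64), nbins = 64L)
  }, integer(64)))
  colnames(m) <- codons64
  rownames(m) <- names(set)
  class(m) <- c("codon_count_matrix", class(m))
  if (!pooled) return(m)
  grp <- subgroups(set)
  pooledm <- rowsum(unclass(m), grp)
  list(records = m, subgroups = pooledm)
}

#' Pool codon count rows
#'
#' @param counts matrix with codon columns (or a single named vector).
#' @return named numeric vector of column sums (a pooled count table).
#' @export
pool_counts <- function(counts) {
  if (is.null(dim(counts))) return(counts)
  colSums(counts)
}

# coerce any accepted counts representation to a named vector over 64 codons
as_count_vector <- function(counts) {
  if (inherits(counts, "table") || length(dim(counts)) == 1L) {
    counts <- stats::setNames(as.vector(counts), names(counts))
  }
  if (!is.null(dim(counts))) counts <- pool_counts(counts)
  if (is.null(names(counts))) stop("counts must be named by codon")
  full <- stats::setNames(numeric(64), all_codons())
  unknown <- setdiff(names(counts), names(full))
  if (length(unknown)) stop("unknown codon(s): ", paste(unknown, collapse = ", "))
  full[names(counts)] <- counts
  full
}

#' Read a host codon-usage reference table
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`plain-tsv`}{`codon<TAB>count` rows; DNA or RNA codons.}
#'   \item{`kazusa`}{Kazusa-style free text, tokens `CODON freq(count)`, e.g.
#'     `GCU 12.0( 120)`; the parenthesised count is used.}
#'   \item{`rscu-direct`}{`codon<TAB>RSCU` rows (published RSCU values used
#'     directly, no counts).}
#' }
#' Missing sense codons are filled with 0 and a warning. Frequencies given
#' per thousand without counts (plain-tsv with non-integer values) are scaled
#' to pseudo-counts by a factor of 1000.
#'
#' @param path file path.
#' @param dialect one of `"plain-tsv"`, `"kazusa"`, `"rscu-direct"`.
#' @param source_label label stored on the reference.
#' @return a `codon_usage_reference`: list with `source_label`, `dialect`, and
#'   either `counts` (named over the 61 sense codons) or `rscu`.
#' @export
read_codon_usage_table <- function(path, dialect = c("plain-tsv", "kazusa",
                                                     "rscu-direct"),
                                   source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "kazusa") {
    txt <- paste(readLines(path, warn = FALSE), collapse = " ")
    m <- gregexpr("([ACGTUacgtu]{3})\\s+[0-9.]+\\(\\s*([0-9]+)\\s*\\)", txt)
    hits <- regmatches(txt, m)[[1]]
    if (length(hits) == 0L) stop("no kazusa-style entries found in ", path)
    codon <- chartr("T", "U", toupper(sub("^([ACGTUacgtu]{3}).*$", "\\1", hits)))
    value <- as.numeric(sub("^.*\\(\\s*([0-9]+)\\s*\\)$", "\\1", hits))
    tab <- data.frame(codon = codon, value = value)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 2L) stop("expected at least two tab-separated columns")
    tab <- data.frame(codon = chartr("T", "U", toupper(tab[[1]])),
                      value = as.numeric(tab[[2]]))
  }
  bad <- !grepl("^[ACGU]{3}$", tab$codon)
  if (any(bad)) stop("unknown codon token(s): ",
                     paste(unique(tab$codon[bad]), collapse = ", "))
  tab <- tab[!tab$codon %in% STOP_CODONS, , drop = FALSE]
  dup <- unique(tab$codon[duplicated(tab$codon)])
  if (length(dup)) stop("duplicate codon(s): ", paste(dup, collapse = ", "))
  values <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  present <- intersect(tab$codon, SENSE_CODONS)
  values[present] <- tab$value[match(present, tab$codon)]
  if (length(present) < length(SENSE_CODONS)) {
    warning("codon usage table missing ",
            length(SENSE_CODONS) - length(present),
            " sense codon(s); filled with 0")
  }
  if (any(values < 0)) stop("negative codon usage values")
  out <- list(source_label = source_label, dialect = dialect)
  if (dialect == "rscu-direct") {
    out$rscu <- values
  } else {
    # per-thousand frequencies (fractional) -> pseudo-counts, factor 1000
    if (any(values != round(values))) values <- values * 1000
    out$counts <- values
  }
  structure(out, class = "codon_usage_reference")
}

#' RSCU values of a codon usage reference
#'
#' For count-backed references RSCU is computed from the counts; `rscu-direct`
#' references return the stored values.
#' @param ref a `codon_usage_reference`.
#' @return named numeric over the 61 sense codons.
#' @export
reference_rscu <- function(ref) {
  stopifnot(inherits(ref, "codon_usage_reference"))
  if (!is.null(ref$rscu)) return(ref$rscu)
  r <- rscu(ref$counts)
  r$values[SENSE_CODONS]
}
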