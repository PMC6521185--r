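# End-to-end orchestration: composition -> ENc/GC3/neutrality ->
# RSCU/HFC/CHFC -> CAI -> COA -> correlations/ANOVA, with deterministic
# TSV outputs and a JSON manifest.

# fixed 6-significant-digit formatting so repeated runs are byte-identical
format_num <- function(x) {
  if (is.numeric(x)) {
    out <- sprintf("%.6g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

write_tsv_out <- function(df, path) {
  df2 <- as.data.frame(lapply(df, format_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(df2) <- names(df)
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# tiny FNV-1a hash over a string (manifest config fingerprint)
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' @param fasta path to a FASTA file (alternative: `set`).
#' @param group_map path to an id/subgroup/host TSV (required with `fasta`).
#' @param set a labelled `sequence_set` (alternative to `fasta`).
#' @param host_tables named list keyed by host label: each element a
#'   `codon_usage_reference`, a named RSCU vector, or a file path (read with
#'   `host_dialect`).
#' @param host_dialect dialect for host table paths (default `"plain-tsv"`).
#' @param threshold HFC RSCU cutoff (default 1.05).
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param coa_mode `"per-subgroup"` (default) or `"pooled"`.
#' @param out_dir output directory (created if absent).
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(fasta = NULL, group_map = NULL, set = NULL,
                       host_tables, host_dialect = "plain-tsv",
                       threshold = 1.05,
                       correlation_method = c("pearson", "spearman"),
                       coa_mode = c("per-subgroup", "pooled"),
                       out_dir = "cubkit-out", seed = 1L) {
  if (is.null(set) && is.null(fasta)) stop("provide either `set` or `fasta`")
  if (threshold <= 0) stop("threshold must be positive")
  structure(
    list(fasta = fasta, group_map = group_map, set = set,
         host_tables = host_tables, host_dialect = host_dialect,
         threshold = threshold,
         correlation_method = match.arg(correlation_method),
         coa_mode = match.arg(coa_mode),
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

resolve_host_tables <- function(config) {
  lapply(config$host_tables, function(h) {
    if (inherits(h, "codon_usage_reference")) return(h)
    if (is.character(h) && length(h) == 1L && file.exists(h)) {
      return(read_codon_usage_table(h, dialect = config$host_dialect))
    }
    if (is.numeric(h) && !is.null(names(h))) return(h)  # bare RSCU vector
    stop("unusable host table entry (not a reference, RSCU vector, ",
         "or existing file)")
  })
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes every analysis stage and writes TSV outputs plus a JSON
#' manifest to `config$out_dir`. Outputs are byte-identical across repeated
#' runs with the same config and inputs.
#'
#' @param config a `run_config`.
#' @param quiet suppress stage log lines on stderr.
#' @return (invisibly) list of in-memory stage results and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[cubkit] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    say(name, " (", sprintf("%.2fs", proc.time()[["elapsed"]] - t0), ")")
    out
  }

  set <- stage("load", {
    if (!is.null(config$set)) config$set
    else assign_groups(read_fasta(config$fasta),
                       read_group_map(config$group_map))
  })
  hosts <- vapply(set, `[[`, character(1), "host")
  host_tables <- stage("host-tables", {
    tabs <- resolve_host_tables(config)
    missing <- setdiff(unique(hosts), names(tabs))
    if (length(missing)) stop("missing host table(s) for: ",
                              paste(missing, collapse = ", "))
    tabs
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  out <- list()

  out$composition <- stage("composition", composition_summary(set))
  paths["composition"] <- write_tsv_out(
    out$composition, file.path(config$out_dir, "composition_summary.tsv"))

  out$enc_gc3 <- stage("enc-gc3", enc_gc3_data(set))
  paths["enc_gc3"] <- write_tsv_out(
    out$enc_gc3$points, file.path(config$out_dir, "enc_gc3.tsv"))

  prof <- t(vapply(set, composition_profile, composition_profile(set[[1]])))
  out$neutrality <- stage("neutrality",
                          neutrality_regression(prof[, "GC12"], prof[, "GC3"]))
  paths["neutrality"] <- write_tsv_out(
    data.frame(slope = out$neutrality$slope,
               intercept = out$neutrality$intercept,
               r_squared = out$neutrality$r_squared,
               pearson_r = out$neutrality$pearson_r,
               p_value = out$neutrality$p_value, n = out$neutrality$n),
    file.path(config$out_dir, "neutrality.tsv"))

  subgroup_of <- subgroups(set)
  host_of_subgroup <- tapply(hosts, subgroup_of, function(h) unique(h)[1])
  pooled <- count_codons(set, pooled = TRUE)$subgroups
  virus_rscu <- lapply(rownames(pooled), function(sg) rscu(pooled[sg, ]))
  names(virus_rscu) <- rownames(pooled)

  out$classifications <- stage("hfc", {
    lapply(names(virus_rscu), function(sg) {
      classify_hfc(virus_rscu[[sg]], host_tables[[host_of_subgroup[[sg]]]],
                   threshold = config$threshold, virus_label = sg,
                   host_label = host_of_subgroup[[sg]])
    }) |> stats::setNames(names(virus_rscu))
  })
  host_rscu <- lapply(host_tables[unname(host_of_subgroup)], as_rscu_values)
  names(host_rscu) <- paste0("host_", names(host_of_subgroup))
  out$rscu_report <- rscu_report(virus_rscu, host_rscu,
                                 threshold = config$threshold)
  paths["rscu"] <- write_tsv_out(
    out$rscu_report, file.path(config$out_dir, "rscu_classification.tsv"))

  if (length(out$classifications) >= 2) {
  out$conversions <- stage("conversions", {
    sgs <- names(out$classifications)
    pairs <- utils::combn(sgs, 2, simplify = FALSE)
    conv <- lapply(pairs, function(p) {
      conversion_analysis(out$classifications[[p[1]]],
                          out$classifications[[p[2]]])
    })
    names(conv) <- vapply(pairs, paste, character(1), collapse = ".")
    conv
  })
  paths["conversions"] <- {
    p <- file.path(config$out_dir, "conversions.json")
    jsonlite::write_json(lapply(out$conversions, function(cv) {
      list(from = cv$from, to = cv$to, v_to_h = cv$v_to_h, h_to_v = cv$h_to_v)
    }), p, pretty = TRUE)
    p
  }
  } else {
    say("conversions skipped: fewer than 2 subgroups")
  }

  out$chfc <- stage("chfc", {
    lapply(names(out$classifications), function(sg) {
      chfc(pooled[sg, ], out$classifications[[sg]])
    }) |> stats::setNames(names(out$classifications))
  })
  chfc_overall <- do.call(rbind, lapply(names(out$chfc), function(sg) {
    data.frame(subgroup = sg, t(out$chfc[[sg]]$overall))
  }))
  paths["chfc"] <- write_tsv_out(
    chfc_overall, file.path(config$out_dir, "chfc_summary.tsv"))

  count_backed <- vapply(host_tables, function(h) {
    !inherits(h, "codon_usage_reference") || !is.null(h$counts)
  }, logical(1))
  if (all(count_backed)) {
    out$cai <- stage("cai", {
      w <- lapply(host_tables, function(h) {
        relative_adaptiveness(if (inherits(h, "codon_usage_reference")) h
                              else as_count_vector(h))
      })
      cai_by_subgroup(set, w)
    })
    paths["cai"] <- write_tsv_out(
      out$cai$records, file.path(config$out_dir, "cai.tsv"))
    paths["cai_summary"] <- write_tsv_out(
      out$cai$subgroup_summary, file.path(config$out_dir, "cai_summary.tsv"))
  } else {
    say("cai skipped: host table(s) without counts (rscu-direct)")
  }

  out$coa <- stage("coa", {
    if (config$coa_mode == "per-subgroup") {
      sgs <- sort(unique(subgroup_of))
      res <- lapply(sgs, function(sg) {
        sub <- structure(unclass(set)[subgroup_of == sg],
                         class = "sequence_set")
        correspondence_analysis(suppressWarnings(build_rscu_matrix(sub)))
      })
      stats::setNames(res, sgs)
    } else {
      list(pooled = correspondence_analysis(
        suppressWarnings(build_rscu_matrix(set))))
    }
  })
  coa_rows <- do.call(rbind, lapply(names(out$coa), function(nm) {
    rep_ <- axis_contribution_report(out$coa[[nm]], k = 2)
    data.frame(run = nm, Axis1_pct = rep_$axis_percent[[1]],
               Axis2_pct = rep_$axis_percent[[2]])
  }))
  paths["coa"] <- write_tsv_out(coa_rows,
                                file.path(config$out_dir, "coa_axes.tsv"))

  out$correlations <- stage("correlations", {
    it <- index_table(set, cai_values = if (!is.null(out$cai)) {
      stats::setNames(out$cai$records$CAI, out$cai$records$id)
    } else NULL)
    correlation_matrix(it, method = config$correlation_method)
  })
  rmat <- out$correlations$r
  paths["correlations"] <- write_tsv_out(
    data.frame(index = rownames(rmat), as.data.frame(rmat),
               check.names = FALSE),
    file.path(config$out_dir, "correlation_matrix.tsv"))

  if (length(unique(subgroup_of)) >= 2) {
    out$anova <- stage("anova", {
      enc <- out$enc_gc3$points$ENc
      one_way_anova(enc, subgroup_of)
    })
    paths["anova"] <- write_tsv_out(
      data.frame(F = out$anova$F, p = out$anova$p,
                 df1 = out$anova$df[1], df2 = out$anova$df[2]),
      file.path(config$out_dir, "anova_enc.tsv"))
  } else {
    say("anova skipped: fewer than 2 subgroups")
  }

  cfg_string <- paste(config$threshold, config$correlation_method,
                      config$coa_mode, config$seed,
                      paste(sort(names(config$host_tables)), collapse = ","),
                      sep = "|")
  manifest <- list(
    package = "cubkit",
    version = as.character(utils::packageVersion("cubkit")),
    seed = config$seed,
    threshold = config$threshold,
    correlation_method = config$correlation_method,
    coa_mode = config$coa_mode,
    config_hash = fnv1a(cfg_string),
    n_records = length(set),
    outputs = as.list(basename(paths))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- file.path(config$out_dir, "manifest.json")

  invisible(c(out, list(paths = paths)))
}
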