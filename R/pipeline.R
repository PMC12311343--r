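# Single-command pipeline orchestration: annotation -> expression ->
# junction ranking -> design -> transcriptome in-silico PCR ->
# prioritization -> genome cross-check -> reports.

#' Assemble a run configuration
#'
#' @param genome,gtf,transcriptome,quant_table input file paths.
#' @param gene_list target gene ids, either a character vector or the path
#'   of a one-id-per-line text file.
#' @param outdir output directory.
#' @param expression_threshold_percentile quantile threshold for the
#'   expressed-isoform call (default 75, i.e. keep the top 25%).
#' @param mismatch_percent in-silico PCR mismatch tolerance per primer
#'   (default 20).
#' @param max_tsl transcript support level cap for design templates
#'   (default 3).
#' @param quantile_scope `"gene"` (default: quantile over the gene's own
#'   isoforms) or `"global"` (over the whole table).
#' @param max_amplicon genomic/transcriptomic product-size cap in bp.
#' @param anchor_3p exact 3'-terminal matches required of an annealing
#'   site (default 0, i.e. off).
#' @param aggregate across-sample aggregation of the expression table.
#' @param constraints a [design_constraints()] object.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, gtf, transcriptome, quant_table, gene_list,
                       outdir, expression_threshold_percentile = 75,
                       mismatch_percent = 20, max_tsl = 3L,
                       quantile_scope = c("gene", "global"),
                       max_amplicon = 3500L, anchor_3p = 0L,
                       aggregate = c("mean", "median"),
                       constraints = design_constraints()) {
  cfg <- list(genome = genome, gtf = gtf, transcriptome = transcriptome,
              quant_table = quant_table, gene_list = gene_list,
              outdir = outdir,
              expression_threshold_percentile = expression_threshold_percentile,
              mismatch_percent = mismatch_percent, max_tsl = max_tsl,
              quantile_scope = match.arg(quantile_scope),
              max_amplicon = max_amplicon, anchor_3p = anchor_3p,
              aggregate = match.arg(aggregate), constraints = constraints)
  if (cfg$expression_threshold_percentile < 0 ||
      cfg$expression_threshold_percentile > 100)
    stop("expression_threshold_percentile must be in [0,100]", call. = FALSE)
  if (cfg$mismatch_percent < 0 || cfg$mismatch_percent > 100)
    stop("mismatch_percent must be in [0,100]", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value` (`#` comments allowed); keys are the
#' arguments of [run_config()], and design-constraint overrides are given
#' as `constraint.<name> = value` (e.g. `constraint.tm_min = 57`).
#' Relative paths are resolved against the file's directory.
#'
#' @param path configuration file path.
#' @param ... overrides applied after the file is read.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  args <- as.list(vals)
  names(args) <- keys
  cons_over <- args[startsWith(keys, "constraint.")]
  args <- args[!startsWith(keys, "constraint.")]
  num <- suppressWarnings(lapply(args, as.numeric))
  args <- mapply(function(a, n) if (!is.na(n)) n else a, args, num,
                 SIMPLIFY = FALSE)
  path_keys <- c("genome", "gtf", "transcriptome", "quant_table", "outdir")
  for (k in intersect(c(path_keys, "gene_list"), names(args))) {
    v <- args[[k]]
    if (is.character(v) && !grepl("^/", v))
      args[[k]] <- file.path(dirname(path), v)
  }
  if (length(cons_over)) {
    names(cons_over) <- sub("^constraint\\.", "", names(cons_over))
    cons_over <- lapply(cons_over, function(v) {
      n <- suppressWarnings(as.numeric(v)); if (!is.na(n)) n else v
    })
    args$constraints <- do.call(design_constraints, cons_over)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

# Design every candidate pair for one gene: ranked junctions x eligible
# templates, n_return pairs each, deduplicated by (fwd, rev, template).
design_gene_pairs <- function(gene, constraints) {
  ranked <- rank_junctions(gene)
  pairs <- list()
  single <- length(gene$transcripts) == 1L
  if (!single && nrow(ranked) > 0L) {
    for (j in seq_len(nrow(ranked))) {
      jid <- ranked$junction_id[j]
      occ <- gene$junction_occ[gene$junction_occ$junction_id == jid, ,
                               drop = FALSE]
      occ <- occ[occ$transcript_id %in% gene$template_ids, , drop = FALSE]
      for (r in seq_len(nrow(occ))) {
        tx <- gene$transcripts[[occ$transcript_id[r]]]
        p <- design_pairs(tx$spliced_seq, occ$pos[r], constraints)
        if (nrow(p) == 0L) next
        p$template_transcript_id <- tx$transcript_id
        p$junction_id <- jid
        p$junction_pos <- occ$pos[r]
        pairs[[length(pairs) + 1L]] <- p
      }
    }
  }
  if (length(pairs) == 0L) {
    # single-isoform gene, no probed junction, or nothing designable on
    # junctions: unconstrained design on the first eligible template
    tid <- if (length(gene$template_ids)) gene$template_ids[1]
           else names(gene$transcripts)[1]
    tx <- gene$transcripts[[tid]]
    p <- design_free_pairs(tx$spliced_seq, constraints)
    if (nrow(p)) {
      p$template_transcript_id <- tx$transcript_id
      p$junction_id <- NA_character_
      p$junction_pos <- NA_integer_
      pairs[[length(pairs) + 1L]] <- p
    }
  }
  if (length(pairs) == 0L) return(NULL)
  all <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  all <- all[!duplicated(paste(all$fwd_seq, all$rev_seq,
                               all$template_transcript_id)), , drop = FALSE]
  all$pair_id <- sprintf("%s_cand%d", gene$gene_id, seq_len(nrow(all)))
  rownames(all) <- NULL
  all
}

# Screen, score and select one gene's designed pairs.
prioritize_gene <- function(gene, all_pairs, calls, transcriptome, cfg) {
  gene_tx <- strip_version(names(gene$transcripts))
  scored <- list()
  for (i in seq_len(nrow(all_pairs))) {
    pair <- as.list(all_pairs[i, ])
    st_f <- oligo_stats(pair$fwd_seq, cfg$constraints$oligo_conc,
                        cfg$constraints$monovalent_salt)
    st_r <- oligo_stats(pair$rev_seq, cfg$constraints$oligo_conc,
                        cfg$constraints$monovalent_salt)
    pair$fwd_self_comp <- st_f$self_comp_score
    pair$fwd_self_end <- st_f$self_end_run
    pair$fwd_hairpin <- st_f$hairpin_flag
    pair$rev_self_comp <- st_r$self_comp_score
    pair$rev_self_end <- st_r$self_end_run
    pair$rev_hairpin <- st_r$hairpin_flag
    hits <- predict_amplicons(pair, transcriptome,
                              pct = cfg$mismatch_percent,
                              max_amplicon = cfg$max_amplicon,
                              anchor_3p = cfg$anchor_3p)
    verdict <- specificity_filter(hits, gene_tx)
    sp <- list(pair = pair, hits = hits, hits_specific = hits,
               specific = verdict$specific,
               discarded_reason = verdict$discarded_reason,
               amplified_isoform_ids = verdict$amplified_isoform_ids,
               amplicon_lengths = hits$length,
               score = NA_real_, coverage_percent = NA_real_,
               amplified_expressed_ids = character(0),
               length_component = NA_real_)
    if (verdict$specific) {
      if (!length_spread_filter(hits$length)) {
        sp$discarded_reason <- "length_spread"
        sp$specific <- FALSE
      } else {
        sc <- score_pair(verdict$amplified_isoform_ids, calls, hits$length)
        if (length(sc$amplified_expressed_ids) == 0L) {
          sp$discarded_reason <- "no_expressed_target"
          sp$specific <- FALSE
        } else {
          sp[c("score", "coverage_percent", "amplified_expressed_ids",
               "length_component")] <- sc[c("score", "coverage_percent",
                                            "amplified_expressed_ids",
                                            "length_component")]
        }
      }
    }
    scored[[length(scored) + 1L]] <- sp
  }
  survivors <- Filter(function(s) s$discarded_reason == "none", scored)
  selection <- select_pairs(gene$gene_id, survivors, calls,
                            single_isoform = length(gene$transcripts) == 1L)
  # stable pair ids for the selected pairs
  for (k in seq_along(selection$selected))
    selection$selected[[k]]$pair$pair_id <-
      sprintf("%s_pair%d", gene$gene_id, k)
  list(scored = scored, selection = selection)
}

#' Run the full primer design pipeline
#'
#' Executes, per target gene: expressed-isoform classification, junction
#' prevalence ranking, junction-overlapping primer design (5 pairs per
#' junction per eligible template), mismatch-tolerant in-silico PCR
#' against the transcriptome, specificity/length-spread filtering and
#' expression-weighted scoring, pair selection (single shared-junction
#' pair, greedy multi-pair cover, or unconstrained single-isoform design),
#' and finally an in-silico PCR of the selected pairs against the genome.
#' Per-gene failures are logged and skipped; the run continues.
#'
#' Outputs written to `outdir`: `primers.tsv` (validated candidates),
#' `primers_order.tsv`, `primer_omnibus.tsv`, `genomic_mismatch.txt`
#' (empty when no genomic amplification is predicted), per-gene reports
#' under `outputs/`, and a machine-readable `manifest.json`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a `pipeline_result` (invisible): per-gene results, the three
#'   tables, genomic report lines and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  for (k in c("genome", "gtf", "transcriptome", "quant_table"))
    if (!file.exists(cfg[[k]]))
      stop("input file missing: ", k, " = ", cfg[[k]], call. = FALSE)
  gene_ids <- cfg$gene_list
  if (length(gene_ids) == 1L && file.exists(gene_ids))
    gene_ids <- readLines(gene_ids)
  gene_ids <- gene_ids[nzchar(gene_ids)]
  if (length(gene_ids) == 0L) stop("no target genes given", call. = FALSE)

  say("loading annotation and sequences")
  genes <- load_annotation(cfg$gtf, cfg$genome, cfg$transcriptome, gene_ids,
                           max_tsl = cfg$max_tsl)
  if (length(genes) == 0L) stop("no target gene found in GTF", call. = FALSE)
  expr <- parse_quant_table(cfg$quant_table, aggregate = cfg$aggregate)
  txome <- read_fasta_named(cfg$transcriptome)
  txome <- setNames(as.character(txome), names(txome))
  genome <- read_fasta_named(cfg$genome)
  genome <- setNames(as.character(genome), names(genome))

  global_cutoff <- if (cfg$quantile_scope == "global")
    unname(quantile(expr$mean_tpm, cfg$expression_threshold_percentile / 100,
                    type = 7, names = FALSE)) else NULL

  process_gene <- function(g, gid) {
    res <- list(gene_id = gid, mode = "failed", skip_reason = NULL,
                threshold_percentile = cfg$expression_threshold_percentile,
                scored = list(), genomic_lines = character(0))
    tx_ids <- strip_version(names(g$transcripts))
    tpms <- expr$mean_tpm[tx_ids]
    if (anyNA(tpms)) {
      warning("gene ", gid, ": transcript(s) absent from the ",
              "quantification table treated as 0 TPM: ",
              paste(tx_ids[is.na(tpms)], collapse = ","), call. = FALSE)
      tpms[is.na(tpms)] <- 0
    }
    names(tpms) <- tx_ids
    calls <- classify_expressed(tpms, cfg$expression_threshold_percentile)
    if (!is.null(global_cutoff)) {
      calls$gene_quantile_cutoff <- global_cutoff
      calls$expressed <- calls$mean_tpm > global_cutoff
      if (!any(calls$expressed) && any(calls$mean_tpm > 0))
        calls$expressed <- calls$mean_tpm > 0
    }
    res$calls <- calls
    res$n_expressed <- sum(calls$expressed)
    if (attr(calls, "not_expressed") %||% FALSE) {
      warning("gene ", gid, " is not expressed; skipped", call. = FALSE)
      res$skip_reason <- "not_expressed"
      return(res)
    }
    if (isTRUE(attr(g, "no_template"))) {
      res$skip_reason <- "no_eligible_template"
      return(res)
    }
    say("designing pairs for %s", gid)
    all_pairs <- design_gene_pairs(g, cfg$constraints)
    if (is.null(all_pairs)) {
      warning("gene ", gid, ": no designable pair", call. = FALSE)
      res$skip_reason <- "no_designable_pair"
      return(res)
    }
    pri <- prioritize_gene(g, all_pairs, calls, txome, cfg)
    res$scored <- pri$scored
    res$selection <- pri$selection
    res$mode <- pri$selection$mode
    sel <- pri$selection$selected
    if (length(sel)) {
      sel_df <- do.call(rbind, lapply(sel, function(s)
        data.frame(gene_id = gid, pair_id = s$pair$pair_id,
                   fwd_seq = s$pair$fwd_seq, rev_seq = s$pair$rev_seq,
                   stringsAsFactors = FALSE)))
      res$genomic_lines <- genome_check(sel_df, genome,
                                        pct = cfg$mismatch_percent,
                                        max_amplicon = cfg$max_amplicon)
    }
    res
  }

  results <- list()
  genomic_lines <- character(0)
  for (gid in names(genes)) {
    res <- tryCatch(process_gene(genes[[gid]], gid), error = function(e) {
      warning("gene ", gid, " failed: ", conditionMessage(e), call. = FALSE)
      list(gene_id = gid, mode = "failed",
           skip_reason = conditionMessage(e),
           threshold_percentile = cfg$expression_threshold_percentile,
           scored = list(), genomic_lines = character(0))
    })
    genomic_lines <- c(genomic_lines, res$genomic_lines)
    res$genomic_lines <- NULL
    results[[gid]] <- res
  }

  out <- structure(list(config = cfg, genes = results,
                        genomic_lines = genomic_lines),
                   class = "pipeline_result")

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$outdir, "outputs"), showWarnings = FALSE)
  out$candidates <- write_candidates(out, file.path(cfg$outdir, "primers.tsv"))
  out$primers_order <- write_primer_order(
    out, file.path(cfg$outdir, "primers_order.tsv"))
  out$omnibus <- write_omnibus(out,
                               file.path(cfg$outdir, "primer_omnibus.tsv"))
  writeLines(genomic_lines, file.path(cfg$outdir, "genomic_mismatch.txt"))
  for (gid in names(results)) {
    if (is.null(results[[gid]]$calls)) next
    write_gene_report(results[[gid]], txome,
                      file.path(cfg$outdir, "outputs",
                                paste0(gid, ".txt")))
  }
  manifest <- list(
    package = "isoqpcr",
    version = as.character(utils::packageVersion("isoqpcr")),
    config = cfg[setdiff(names(cfg), "constraints")],
    constraints = unclass(cfg$constraints),
    genes = lapply(results, function(r) list(
      mode = r$mode %||% "failed",
      skip_reason = r$skip_reason,
      n_pairs_designed = length(r$scored %||% list()),
      n_pairs_selected = if (is.null(r$selection)) 0L
                         else length(r$selection$selected))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  say("done: %d gene(s) processed", length(results))
  invisible(out)
}
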