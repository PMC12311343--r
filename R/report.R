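# Deterministic emission of the three result tables, the per-gene text
# report and the genomic cross-check file.

# Format one scored pair as a candidate-table row.
candidate_row <- function(gene_id, sp, n_expressed) {
  hits <- sp$hits_specific
  toks <- sprintf("%s-%d", hits$template_id, hits$length)
  toks <- toks[order(hits$template_id, hits$length)]
  data.frame(
    gene_id = gene_id,
    score = round(sp$score, 2),
    template_transcript_id = sp$pair$template_transcript_id,
    fwd_seq = sp$pair$fwd_seq,
    rev_seq = sp$pair$rev_seq,
    n_expressed_amplified = sprintf("%d/%d",
                                    length(sp$amplified_expressed_ids),
                                    n_expressed),
    coverage_percent = round(sp$coverage_percent, 2),
    amplicons = paste(toks, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Table of validated candidate pairs
#'
#' One row per selected pair, genes in input order and pairs in selection
#' order, with the columns: gene id, score, template transcript, forward
#' and reverse sequence, expressed isoforms amplified over total
#' (`"k/n"`), cumulative expression percentage, and the predicted
#' amplicons as semicolon-joined `name-length` tokens sorted by template
#' name.
#'
#' @param results a `pipeline_result`.
#' @param path optional TSV output path.
#' @return the data.frame, invisibly when written.
#' @export
write_candidates <- function(results, path = NULL) {
  rows <- list()
  for (g in results$genes) {
    if (is.null(g$selection)) next
    for (sp in g$selection$selected)
      rows[[length(rows) + 1L]] <- candidate_row(g$gene_id, sp,
                                                 g$n_expressed)
  }
  df <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else empty_candidates()
  emit_tsv(df, path)
}

#' Ready-for-order primer table
#'
#' Two rows per selected pair, named `<gene>_pair<N>_F` /
#' `<gene>_pair<N>_R`, with the synthesized 5'->3' sequences.
#'
#' @inheritParams write_candidates
#' @export
write_primer_order <- function(results, path = NULL) {
  rows <- list()
  for (g in results$genes) {
    if (is.null(g$selection)) next
    for (k in seq_along(g$selection$selected)) {
      sp <- g$selection$selected[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        oligo_name = sprintf("%s_pair%d_%s", g$gene_id, k, c("F", "R")),
        sequence = c(sp$pair$fwd_seq, sp$pair$rev_seq),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(oligo_name = character(), sequence = character())
  emit_tsv(df, path)
}

#' Omnibus table of every designed pair
#'
#' All pairs designed for all target genes, selected or not, with a
#' discard-reason column (`none` for survivors).  Ordering matches
#' [write_candidates()]: genes in input order, pairs in deterministic
#' design order.
#'
#' @inheritParams write_candidates
#' @export
write_omnibus <- function(results, path = NULL) {
  rows <- list()
  for (g in results$genes) {
    for (sp in g$scored) {
      r <- candidate_row(g$gene_id, sp, g$n_expressed)
      r$discard_reason <- sp$discarded_reason
      rows[[length(rows) + 1L]] <- r
    }
  }
  df <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else {
    d <- empty_candidates(); d$discard_reason <- character(0); d
  }
  emit_tsv(df, path)
}

empty_candidates <- function() {
  data.frame(gene_id = character(), score = numeric(),
             template_transcript_id = character(), fwd_seq = character(),
             rev_seq = character(), n_expressed_amplified = character(),
             coverage_percent = numeric(), amplicons = character(),
             stringsAsFactors = FALSE)
}

emit_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

# Coordinate-annotated hybridization display: the template window from the
# forward to the reverse footprint, with the annealing spans marked, in
# 60-column blocks.
hybridization_block <- function(template_id, template_seq, hit, pair) {
  flen <- nchar(if (hit$fwd_oligo == "fwd") pair$fwd_seq else pair$rev_seq)
  rlen <- nchar(if (hit$rev_oligo == "fwd") pair$fwd_seq else pair$rev_seq)
  w0 <- hit$fwd_5p; w1 <- hit$rev_5p               # 0-based inclusive window
  seq <- substr(template_seq, w0 + 1L, w1 + 1L)
  marks <- rep(".", nchar(seq))
  marks[seq_len(flen)] <- ">"
  marks[(nchar(seq) - rlen + 1L):nchar(seq)] <- "<"
  lines <- c(sprintf("  %s [%d-%d] product %d bp (fwd as %s, rev as %s)",
                     template_id, w0 + 1L, w1 + 1L, hit$length,
                     hit$fwd_oligo, hit$rev_oligo))
  for (off in seq(1L, nchar(seq), by = 60L)) {
    end <- min(off + 59L, nchar(seq))
    lines <- c(lines,
               sprintf("  %6d %s", w0 + off, substr(seq, off, end)),
               sprintf("         %s", paste(marks[off:end], collapse = "")))
  }
  lines
}

#' Per-gene detailed text report
#'
#' Sections, in order: isoform quantitation and the quantile cutoff with
#' the expressed isoforms; the isoforms/junctions used for design; primer
#' sequences; a coordinate-annotated hybridization display of each matched
#' isoform; FASTA records of the matched isoforms; and thermodynamic
#' diagnostics (Tm, GC, complementarity, hairpin flags, design penalty).
#'
#' @param gene_result one element of `pipeline_result$genes`.
#' @param transcriptome named character vector of transcript sequences.
#' @param path optional output path.
#' @return character vector of report lines.
#' @export
write_gene_report <- function(gene_result, transcriptome, path = NULL) {
  g <- gene_result
  L <- c(sprintf("Gene report: %s", g$gene_id),
         sprintf("Mode: %s", if (is.null(g$selection)) "skipped"
                 else g$selection$mode),
         "",
         "== Isoform quantitation ==",
         sprintf("Quantile threshold percentile: %s  (cutoff %s TPM)",
                 fmt_num(g$threshold_percentile),
                 fmt_num(g$calls$gene_quantile_cutoff[1])))
  for (i in seq_len(nrow(g$calls)))
    L <- c(L, sprintf("  %s\t%s TPM\t%s", g$calls$transcript_id[i],
                      fmt_num(g$calls$mean_tpm[i]),
                      ifelse(g$calls$expressed[i], "expressed", "-")))
  if (!is.null(g$selection) && length(g$selection$selected)) {
    L <- c(L, "", "== Selected primer pairs ==")
    for (k in seq_along(g$selection$selected)) {
      sp <- g$selection$selected[[k]]
      p <- sp$pair
      L <- c(L, sprintf("-- pair %d (%s) --", k, p$pair_id),
             sprintf("Design template: %s%s", p$template_transcript_id,
                     if (!is.na(p$junction_id))
                       sprintf("; junction %s at transcript position %d (%s primer spans it)",
                               p$junction_id, p$junction_pos,
                               p$junction_primer)
                     else "; no junction (single-isoform mode)"),
             sprintf("Forward 5'->3': %s", p$fwd_seq),
             sprintf("Reverse 5'->3': %s", p$rev_seq),
             sprintf("Score %s; coverage %s%%; expressed isoforms amplified: %s",
                     fmt_num(sp$score), fmt_num(sp$coverage_percent),
                     paste(sp$amplified_expressed_ids, collapse = ",")),
             "Hybridization:")
      for (i in seq_len(nrow(sp$hits_specific))) {
        hit <- sp$hits_specific[i, ]
        L <- c(L, hybridization_block(hit$template_id,
                                      transcriptome[[hit$template_id]],
                                      hit, p))
      }
      L <- c(L, "Matched isoform sequences (FASTA):")
      for (tid in unique(sp$hits_specific$template_id))
        L <- c(L, paste0(">", tid), transcriptome[[tid]])
      L <- c(L, "Diagnostics:",
             sprintf("  fwd: Tm %s C, GC %s%%, self-comp %d, 3'-run %d, hairpin %s",
                     fmt_num(p$fwd_tm), fmt_num(p$fwd_gc),
                     p$fwd_self_comp, p$fwd_self_end,
                     ifelse(p$fwd_hairpin, "yes", "no")),
             sprintf("  rev: Tm %s C, GC %s%%, self-comp %d, 3'-run %d, hairpin %s",
                     fmt_num(p$rev_tm), fmt_num(p$rev_gc),
                     p$rev_self_comp, p$rev_self_end,
                     ifelse(p$rev_hairpin, "yes", "no")),
             sprintf("  pair: complementarity %d, 3'-run %d, |dTm| %s C, penalty %s",
                     p$pair_comp, p$pair_end_comp,
                     fmt_num(abs(p$fwd_tm - p$rev_tm)), fmt_num(p$penalty)))
    }
    if (length(g$selection$uncovered_expressed))
      L <- c(L, "", paste("Uncovered expressed isoform(s):",
                          paste(g$selection$uncovered_expressed,
                                collapse = ",")))
  } else {
    L <- c(L, "", "No primer pair selected.",
           if (!is.null(g$skip_reason)) sprintf("Reason: %s", g$skip_reason))
  }
  if (!is.null(path)) writeLines(L, path)
  invisible(L)
}
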