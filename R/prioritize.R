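# Turning raw design candidates plus in-silico PCR results into scored,
# filtered, selected primer sets per gene.

#' Specificity verdict for one pair from its transcriptome hits
#'
#' A pair is discarded as non-specific the moment any predicted amplicon
#' template lies outside the target gene's transcript set.  Amplification
#' of the gene's own non-expressed isoforms is not penalized (the template
#' is still the right gene) but contributes nothing to coverage.  A pair
#' that amplifies nothing at all is unusable and discarded as
#' `no_expressed_target`.
#'
#' @param hits data.frame from [predict_amplicons()] against the
#'   transcriptome.
#' @param gene_transcript_ids transcripts belonging to the target gene
#'   (normalized ids).
#' @return list: `specific` (logical), `discarded_reason` (`"none"`,
#'   `"nonspecific"` or `"no_expressed_target"`), `amplified_isoform_ids`.
#' @export
specificity_filter <- function(hits, gene_transcript_ids) {
  tmpl <- strip_version(unique(hits$template_id))
  if (length(tmpl) == 0L)
    return(list(specific = FALSE, discarded_reason = "no_expressed_target",
                amplified_isoform_ids = character(0)))
  if (any(!tmpl %in% gene_transcript_ids))
    return(list(specific = FALSE, discarded_reason = "nonspecific",
                amplified_isoform_ids = tmpl))
  list(specific = TRUE, discarded_reason = "none",
       amplified_isoform_ids = tmpl)
}

#' Amplicon length-spread filter
#'
#' Pairs whose specific amplicons differ by more than 25 nt in length are
#' discarded: such pairs would report a mixture of products and distort
#' quantification.  The boundary is inclusive (a spread of exactly 25 nt
#' passes).
#'
#' @param lengths amplicon lengths (bp) of one pair's specific hits.
#' @param max_spread maximum tolerated `max - min` (default 25).
#' @return `TRUE` when the pair passes.
#' @export
length_spread_filter <- function(lengths, max_spread = 25L) {
  if (length(lengths) == 0L) stop("no amplicons supplied", call. = FALSE)
  (max(lengths) - min(lengths)) <= max_spread
}

#' Amplicon length-preference score component
#'
#' A tent function peaking at the preferred ~200 bp product:
#' `L = max(0, 10 - |median(lengths) - 200| / 10)`, symmetric and zero from
#' 100 bp away.
#'
#' @param lengths amplicon lengths (bp).
#' @param target preferred product length (default 200).
#' @return numeric in `[0, 10]`.
#' @export
length_component <- function(lengths, target = 200) {
  if (length(lengths) == 0L) stop("no amplicons supplied", call. = FALSE)
  max(0, 10 - abs(median(lengths) - target) / 10)
}

#' Score a specific primer pair by the expression it captures
#'
#' `score = coverage_percent + 10 * (number of amplified expressed
#' isoforms) + length_component`, where `coverage_percent` is the share of
#' the gene's expressed abundance the pair amplifies: `100 * sum(mean_tpm
#' of amplified expressed isoforms) / sum(mean_tpm of all expressed
#' isoforms)`.  A pair that amplifies the sole expressed isoform of a gene
#' at 200 bp therefore scores 100 + 10 + 10 = 120.
#'
#' @param amplified_isoform_ids isoforms the pair amplifies.
#' @param expression_calls data.frame from [classify_expressed()] for the
#'   gene.
#' @param amplicon_lengths the pair's specific amplicon lengths (bp).
#' @param bonus_per_isoform score bonus per amplified expressed isoform
#'   (default 10).
#' @return list: `score`, `coverage_percent`, `amplified_expressed_ids`,
#'   `length_component`.
#' @export
score_pair <- function(amplified_isoform_ids, expression_calls,
                       amplicon_lengths, bonus_per_isoform = 10) {
  expr <- expression_calls[expression_calls$expressed, , drop = FALSE]
  amp_expr <- intersect(amplified_isoform_ids, expr$transcript_id)
  denom <- sum(expr$mean_tpm)
  cov <- if (denom > 0)
    100 * sum(expr$mean_tpm[expr$transcript_id %in% amp_expr]) / denom
  else 0
  lc <- length_component(amplicon_lengths)
  list(score = cov + bonus_per_isoform * length(amp_expr) + lc,
       coverage_percent = cov,
       amplified_expressed_ids = amp_expr,
       length_component = lc)
}

# Deterministic ordering of scored pairs: score desc, then closeness of
# the median amplicon to the preferred length, then fwd_seq lexicographic.
order_scored <- function(sp) {
  med_dev <- vapply(sp, function(p) abs(median(p$amplicon_lengths) - 200),
                    numeric(1))
  order(-vapply(sp, `[[`, numeric(1), "score"), med_dev,
        vapply(sp, function(p) p$pair$fwd_seq, character(1)))
}

#' Select the primer pairs reported for one gene
#'
#' Applies the selection policy to scored, surviving pairs: when a single
#' pair alone amplifies every expressed isoform, the highest-scoring such
#' pair is returned (mode `shared_junction`, or `single_isoform` when the
#' gene has one isoform); otherwise pairs are added greedily, highest
#' score first, as long as each covers at least one still-uncovered
#' expressed isoform (mode `multi_pair_cover`).  Isoforms no surviving pair
#' reaches are reported as uncovered.  Ties break by the smaller
#' |median amplicon - 200|, then lexicographic forward sequence.
#'
#' @param gene_id gene identifier.
#' @param scored_pairs list of surviving scored pairs; each element carries
#'   `pair` (design row), `score`, `coverage_percent`,
#'   `amplified_expressed_ids`, `amplicon_lengths`.
#' @param expression_calls data.frame from [classify_expressed()].
#' @param single_isoform logical: the gene has exactly one isoform.
#' @return list of class `gene_design_result`: `gene_id`, `selected`
#'   (ordered list of scored pairs), `covered_expressed`,
#'   `uncovered_expressed`, `mode`.
#' @export
select_pairs <- function(gene_id, scored_pairs, expression_calls,
                         single_isoform = FALSE) {
  expressed <- expression_calls$transcript_id[expression_calls$expressed]
  result <- function(selected, mode) {
    covered <- unique(unlist(lapply(selected, `[[`,
                                    "amplified_expressed_ids")))
    structure(list(gene_id = gene_id, selected = selected,
                   covered_expressed = intersect(expressed, covered),
                   uncovered_expressed = setdiff(expressed, covered),
                   mode = mode),
              class = "gene_design_result")
  }
  if (length(scored_pairs) == 0L) return(result(list(), "failed"))
  o <- order_scored(scored_pairs)
  scored_pairs <- scored_pairs[o]
  full <- vapply(scored_pairs, function(p)
    setequal(p$amplified_expressed_ids, expressed), logical(1))
  if (any(full)) {
    mode <- if (single_isoform) "single_isoform" else "shared_junction"
    return(result(scored_pairs[which(full)[1]], mode))
  }
  # greedy cover, highest score first, progress required
  uncovered <- expressed
  selected <- list()
  for (p in scored_pairs) {
    gain <- intersect(p$amplified_expressed_ids, uncovered)
    if (length(gain) == 0L) next
    selected[[length(selected) + 1L]] <- p
    uncovered <- setdiff(uncovered, gain)
    if (length(uncovered) == 0L) break
  }
  if (length(selected) == 0L) return(result(list(), "failed"))
  result(selected, "multi_pair_cover")
}

#' @export
print.gene_design_result <- function(x, ...) {
  cat(sprintf("<design result %s: mode %s, %d pair(s), %d/%d expressed isoform(s) covered>\n",
              x$gene_id, x$mode, length(x$selected),
              length(x$covered_expressed),
              length(x$covered_expressed) + length(x$uncovered_expressed)))
  invisible(x)
}
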