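# Mismatch-tolerant in-silico PCR: primer annealing-site search on both
# strands (pure Hamming, no indels), amplicon enumeration against template
# sets, and the genomic cross-check report.
#
# The matcher is implemented in-package rather than on Biostrings'
# matchPattern because the required ambiguity semantics are asymmetric: an
# IUPAC code in the primer matches any base of its set, while an N (or any
# ambiguity) in the template never matches anything, a conservative rule
# for specificity screening.

# IUPAC bitmasks for primer letters (A=1 C=2 G=4 T=8).
IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L)
# Template letters: a single base bit; anything ambiguous matches nothing.
TEMPLATE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Mismatches allowed for a primer at a percent tolerance
#'
#' @param primer_len primer length in nt.
#' @param pct mismatch tolerance as a percentage of primer length
#'   (default 20); the allowed count is `floor(primer_len * pct / 100)`.
#' @return integer number of mismatches tolerated.
#' @export
#' @examples
#' allowed_mismatches(20, 20) # 4
allowed_mismatches <- function(primer_len, pct = 20) {
  if (pct < 0 || pct > 100) stop("pct must be in [0,100]", call. = FALSE)
  as.integer(floor(primer_len * pct / 100))
}

# Hamming mismatch counts of `primer` at every offset of `template_bits`
# (template already encoded); returns integer vector of length L - m + 1.
hamming_profile <- function(primer_masks, template_bits) {
  m <- length(primer_masks)
  L <- length(template_bits)
  if (L < m) return(integer(0))
  n_off <- L - m + 1L
  mism <- integer(n_off)
  for (i in seq_len(m)) {
    mism <- mism + as.integer(
      bitwAnd(primer_masks[i], template_bits[i:(i + n_off - 1L)]) == 0L)
  }
  mism
}

encode_template <- function(template) {
  b <- strsplit(template, "", fixed = TRUE)[[1]]
  bits <- TEMPLATE_BIT[b]
  bits[is.na(bits)] <- 0L           # N / ambiguity: matches nothing
  unname(bits)
}

encode_primer <- function(primer) {
  b <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  masks <- IUPAC_MASK[b]
  if (anyNA(masks))
    stop("primer contains non-IUPAC characters", call. = FALSE)
  unname(masks)
}

#' Find primer annealing sites on a template
#'
#' Scans the primer against the plus strand and its reverse complement
#' against the template (minus-strand annealing), counting pure Hamming
#' mismatches at every ungapped offset; sites with at most
#' [allowed_mismatches()] mismatches are reported.  No 3'-anchoring is
#' imposed unless `anchor_3p > 0`, which additionally requires that many
#' exact matches at the primer's 3' terminus.
#'
#' @param primer oligo sequence (IUPAC codes allowed).
#' @param template template sequence over `{A,C,G,T,N}`.
#' @param pct mismatch tolerance percent.
#' @param template_id identifier recorded in the result.
#' @param anchor_3p require this many exact 3'-terminal matches (default 0).
#' @return data.frame with columns `template_id`, `strand` (`+`/`-`),
#'   `five_prime_pos` (0-based, + strand coordinates: for a minus-strand
#'   site this is the rightmost template position of the footprint),
#'   `start`, `end` (0-based half-open footprint) and `mismatches`.
#' @export
find_sites <- function(primer, template, pct = 20,
                       template_id = "template", anchor_3p = 0L) {
  tb <- encode_template(template)
  m <- nchar(primer)
  allowed <- allowed_mismatches(m, pct)
  res <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else revcomp(primer)
    pm <- encode_primer(p)
    mism <- hamming_profile(pm, tb)
    ok <- which(mism <= allowed)
    if (anchor_3p > 0L && length(ok)) {
      # primer 3' end sits at the right end of the footprint (+) or the
      # left end (-); require exact matches there
      idx3 <- if (strand == "+") (m - anchor_3p + 1L):m else 1L:anchor_3p
      keep <- vapply(ok, function(o) {
        all(bitwAnd(pm[idx3], tb[o - 1L + idx3]) != 0L)
      }, logical(1))
      ok <- ok[keep]
    }
    if (length(ok)) {
      start <- ok - 1L
      res[[strand]] <- data.frame(
        template_id = template_id, strand = strand,
        five_prime_pos = if (strand == "+") start else start + m - 1L,
        start = start, end = start + m,
        mismatches = mism[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(template_id = character(), strand = character(),
                      five_prime_pos = integer(), start = integer(),
                      end = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(out$five_prime_pos, out$strand), , drop = FALSE]
}

#' Predict in-silico PCR amplicons of a primer pair
#'
#' For every template, every combination of a plus-strand site of one
#' oligo and a minus-strand site of the other oligo with the correct
#' relative orientation (the minus-strand 3' end strictly downstream of the
#' plus-strand 3' end) and a product at most `max_amplicon` long yields one
#' predicted amplicon.  Both oligos are tried in both roles, so the
#' prediction is symmetric under swapping the forward/reverse labels.
#' Products primed by two sites of the same oligo are not counted.
#'
#' @param pair list/row with `fwd_seq` and `rev_seq` (synthesized 5'->3'
#'   oligo sequences).
#' @param templates named character vector or `DNAStringSet` of templates.
#' @param pct mismatch tolerance percent.
#' @param max_amplicon maximum reported product length in bp (default 3500).
#' @param anchor_3p passed to [find_sites()].
#' @return data.frame with `template_id`, `fwd_oligo`, `rev_oligo`
#'   (which synthesized oligo primed which strand), `fwd_5p`, `rev_5p`
#'   (0-based), `length`, `fwd_mm`, `rev_mm`, sorted by
#'   (`template_id`, `fwd_5p`).
#' @export
predict_amplicons <- function(pair, templates, pct = 20,
                              max_amplicon = 3500L, anchor_3p = 0L) {
  if (methods::is(templates, "DNAStringSet"))
    templates <- setNames(as.character(templates), names(templates))
  oligos <- c(fwd = pair$fwd_seq, rev = pair$rev_seq)
  hits <- list()
  for (tmpl_id in names(templates)) {
    tmpl <- templates[[tmpl_id]]
    sites <- lapply(oligos, find_sites, template = tmpl, pct = pct,
                    template_id = tmpl_id, anchor_3p = anchor_3p)
    for (combo in list(c("fwd", "rev"), c("rev", "fwd"))) {
      sp <- sites[[combo[1]]]; sp <- sp[sp$strand == "+", , drop = FALSE]
      sm <- sites[[combo[2]]]; sm <- sm[sm$strand == "-", , drop = FALSE]
      if (nrow(sp) == 0L || nrow(sm) == 0L) next
      for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sm))) {
        # minus-strand 3' end (footprint left edge) must lie strictly
        # downstream of the plus-strand 3' end (footprint right edge)
        if (sm$start[j] < sp$end[i]) next
        len <- sm$five_prime_pos[j] - sp$five_prime_pos[i] + 1L
        if (len > max_amplicon) next
        hits[[length(hits) + 1L]] <- data.frame(
          template_id = tmpl_id,
          fwd_oligo = combo[1], rev_oligo = combo[2],
          fwd_5p = sp$five_prime_pos[i], rev_5p = sm$five_prime_pos[j],
          length = len, fwd_mm = sp$mismatches[i], rev_mm = sm$mismatches[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(template_id = character(), fwd_oligo = character(),
                      rev_oligo = character(), fwd_5p = integer(),
                      rev_5p = integer(), length = integer(),
                      fwd_mm = integer(), rev_mm = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  out[order(out$template_id, out$fwd_5p, out$rev_5p), , drop = FALSE]
}

#' Genomic cross-check of finalized primer pairs
#'
#' Runs [predict_amplicons()] for each pair against the genome and formats
#' one tab-separated line per predicted genomic amplicon: gene id, pair id,
#' chromosome, start, end, length (1-based inclusive genomic coordinates).
#' The report is empty when no genomic amplification is predicted, which is
#' the desired outcome for junction-spanning pairs whose genomic target is
#' interrupted by an intron longer than the amplicon cap.
#'
#' @param pairs data.frame of pairs with `gene_id`, `pair_id`, `fwd_seq`,
#'   `rev_seq`.
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @param pct mismatch tolerance percent.
#' @param max_amplicon maximum genomic product length considered.
#' @param path optional output path; when given the lines are written there
#'   (an empty file when there are none).
#' @return character vector of report lines, invisibly when `path` given.
#' @export
genome_check <- function(pairs, genome, pct = 20, max_amplicon = 3500L,
                         path = NULL) {
  lines <- character(0)
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      hits <- predict_amplicons(pairs[i, ], genome, pct = pct,
                                max_amplicon = max_amplicon)
      if (nrow(hits))
        lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t%d",
                                  pairs$gene_id[i], pairs$pair_id[i],
                                  hits$template_id, hits$fwd_5p + 1L,
                                  hits$rev_5p + 1L, hits$length))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
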