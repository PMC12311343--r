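# Junction-overlapping primer pair enumeration and ranking under standard
# qPCR constraints, plus the unconstrained single-isoform mode.

#' Primer design constraints
#'
#' Bundles every tunable of the design stage with the standard qPCR
#' defaults: primer length 20-25 nt, GC 30-60%, Tm 55-75 degC, product
#' 100-300 bp, homopolymer runs capped at 4, self/pair complementarity
#' rejection at a run of `max_self_comp` anywhere or `max_end_comp` at a 3'
#' end, pair Tm difference capped at 5 degC, and 5 pairs returned per
#' junction.  A junction-overlapping primer must keep at least
#' `junction_overlap_5p` bases on the 5' side of the junction and
#' `junction_overlap_3p` on the 3' side, which rules out token 1-bp
#' overlaps.  Penalty weights (`w_tm`, `w_len`, `w_gc`, `w_pair_tm`) and
#' optima (`opt_tm` 60 degC, `opt_len` 22 nt, `opt_gc` 50%) define the
#' ranking objective; see [pair_penalty()].
#'
#' @param ... overrides of any default listed above.
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(...) {
  cons <- list(
    primer_len_min = 20L, primer_len_max = 25L,
    gc_min = 30, gc_max = 60,
    tm_min = 55, tm_max = 75,
    product_min = 100L, product_max = 300L,
    max_poly_run = 4L,
    max_self_comp = 8L,      # reject when self/pair run >= this
    max_end_comp = 4L,       # reject when 3'-anchored run >= this
    max_pair_tm_diff = 5,
    n_return = 5L,
    junction_overlap_5p = 7L, junction_overlap_3p = 4L,
    reject_hairpin = TRUE, min_stem = 4L, min_loop = 3L,
    oligo_conc = 50e-9, monovalent_salt = 50e-3,
    w_tm = 1.0, w_len = 0.5, w_gc = 0.2, w_pair_tm = 1.0,
    opt_tm = 60, opt_len = 22L, opt_gc = 50)
  over <- list(...)
  unknown <- setdiff(names(over), names(cons))
  if (length(unknown))
    stop("unknown constraint(s): ", paste(unknown, collapse = ","),
         call. = FALSE)
  cons[names(over)] <- over
  if (cons$primer_len_min > cons$primer_len_max ||
      cons$product_min > cons$product_max || cons$n_return < 1L)
    stop("empty constraint range", call. = FALSE)
  structure(cons, class = "design_constraints")
}

# Enumerate candidate windows [start, start+len) over template positions
# [lo, hi), compute oligo stats and apply all single-primer hard filters.
# orientation "F": oligo = window; "R": oligo = revcomp(window).
window_candidates <- function(template, lo, hi, orientation, cons) {
  n <- nchar(template)
  lo <- max(0L, lo); hi <- min(n, hi)
  rows <- list()
  for (len in cons$primer_len_min:cons$primer_len_max) {
    if (hi - lo < len) next
    starts <- lo:(hi - len)
    rows[[length(rows) + 1L]] <- data.frame(start = starts, len = len)
  }
  empty <- data.frame(orientation = character(), start = integer(),
                      len = integer(), seq = character(), gc = numeric(),
                      tm = numeric(), max_run = integer(),
                      self_comp = integer(), self_end = integer(),
                      hairpin = logical(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  w <- do.call(rbind, rows)
  win <- substring(template, w$start + 1L, w$start + w$len)
  seqs <- if (orientation == "F") win else revcomp(win)
  # cheap screens first
  bases <- strsplit(seqs, "", fixed = TRUE)
  gc <- vapply(bases, function(b) 100 * sum(b %in% c("G", "C")) / length(b),
               numeric(1))
  run <- vapply(bases, function(b) max(rle(b)$lengths), integer(1))
  keep <- gc >= cons$gc_min & gc <= cons$gc_max & run <= cons$max_poly_run &
    !grepl("[^ACGT]", seqs)
  w <- w[keep, , drop = FALSE]; seqs <- seqs[keep]
  gc <- gc[keep]; run <- run[keep]
  if (nrow(w) == 0L) return(empty)
  tm <- vapply(seqs, melting_temperature, numeric(1),
               oligo_conc = cons$oligo_conc,
               monovalent_salt = cons$monovalent_salt, USE.NAMES = FALSE)
  keep <- tm >= cons$tm_min & tm <= cons$tm_max
  w <- w[keep, , drop = FALSE]; seqs <- seqs[keep]
  gc <- gc[keep]; run <- run[keep]; tm <- tm[keep]
  if (nrow(w) == 0L) return(empty)
  sc <- lapply(seqs, function(s) complementarity(s, s))
  self_comp <- vapply(sc, `[[`, integer(1), "score")
  self_end <- vapply(sc, `[[`, integer(1), "end_run")
  hp <- vapply(seqs, hairpin_flag, logical(1),
               min_stem = cons$min_stem, min_loop = cons$min_loop,
               USE.NAMES = FALSE)
  keep <- self_comp < cons$max_self_comp & self_end < cons$max_end_comp &
    (!cons$reject_hairpin | !hp)
  out <- data.frame(orientation = rep(orientation, sum(keep)),
                    start = w$start[keep],
                    len = w$len[keep], seq = seqs[keep], gc = gc[keep],
                    tm = tm[keep], max_run = run[keep],
                    self_comp = self_comp[keep], self_end = self_end[keep],
                    hairpin = hp[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate junction-overlapping primer candidates
#'
#' Returns every primer window (both orientations) whose span covers the
#' junction with at least `junction_overlap_5p` bases on the primer's 5'
#' side of the junction and `junction_overlap_3p` on its 3' side, after
#' discarding candidates violating any single-primer hard constraint (GC,
#' Tm, homopolymer run, self-complementarity, hairpin).  For a forward
#' primer the 5' side is the template left of the junction; for a reverse
#' primer it is the template right of it.
#'
#' @param template spliced transcript sequence (character).
#' @param junction_pos 0-based transcript-local junction position.
#' @param constraints a [design_constraints()] object.
#' @return data.frame of candidates with orientation, 0-based window
#'   `start`, `len`, oligo `seq` and screening statistics.
#' @export
enumerate_junction_primers <- function(template, junction_pos,
                                       constraints = design_constraints()) {
  cons <- constraints
  n <- nchar(template)
  if (junction_pos <= 0L || junction_pos >= n)
    stop("junction_pos outside template", call. = FALSE)
  pick <- function(cand, o5, o3, orientation) {
    if (nrow(cand) == 0L) return(cand)
    left <- junction_pos - cand$start          # bases before the junction
    right <- cand$start + cand$len - junction_pos
    keep <- if (orientation == "F") left >= o5 & right >= o3
            else right >= o5 & left >= o3
    cand[keep & left > 0L & right > 0L, , drop = FALSE]
  }
  lo <- junction_pos - cons$primer_len_max
  hi <- junction_pos + cons$primer_len_max
  fc <- pick(window_candidates(template, lo, hi, "F", cons),
             cons$junction_overlap_5p, cons$junction_overlap_3p, "F")
  rc <- pick(window_candidates(template, lo, hi, "R", cons),
             cons$junction_overlap_5p, cons$junction_overlap_3p, "R")
  out <- rbind(fc, rc)
  rownames(out) <- NULL
  out
}

#' Ranking penalty of a primer pair
#'
#' `penalty = sum over both primers of [w_tm |Tm - opt_tm| + w_len |len -
#' opt_len| + w_gc |GC - opt_gc|] + w_pair_tm |Tm_fwd - Tm_rev|`; lower is
#' better and zero is attained by two 22-mers at 60 degC and 50% GC with
#' equal Tm.
#'
#' @param fwd_tm,rev_tm,fwd_len,rev_len,fwd_gc,rev_gc per-primer stats
#'   (vectorized).
#' @param constraints a [design_constraints()] object (weights/optima).
#' @return numeric penalty, >= 0.
#' @export
pair_penalty <- function(fwd_tm, rev_tm, fwd_len, rev_len, fwd_gc, rev_gc,
                         constraints = design_constraints()) {
  cons <- constraints
  cons$w_tm * (abs(fwd_tm - cons$opt_tm) + abs(rev_tm - cons$opt_tm)) +
    cons$w_len * (abs(fwd_len - cons$opt_len) + abs(rev_len - cons$opt_len)) +
    cons$w_gc * (abs(fwd_gc - cons$opt_gc) + abs(rev_gc - cons$opt_gc)) +
    cons$w_pair_tm * abs(fwd_tm - rev_tm)
}

# Assemble, rank and lazily pair-check candidate combinations.
# fwd/rev are candidate data.frames (template coordinates); returns up to
# n pairs as a data.frame.
rank_pairs <- function(fwd, rev, template, cons, n, junction_side = NA) {
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty_pairs())
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  prod_len <- rev$start[grid$r] + rev$len[grid$r] - fwd$start[grid$f]
  ok <- prod_len >= cons$product_min & prod_len <= cons$product_max &
    rev$start[grid$r] >= fwd$start[grid$f] + fwd$len[grid$f]
  grid <- grid[ok, , drop = FALSE]; prod_len <- prod_len[ok]
  if (nrow(grid) == 0L) return(empty_pairs())
  pen <- pair_penalty(fwd$tm[grid$f], rev$tm[grid$r],
                      fwd$len[grid$f], rev$len[grid$r],
                      fwd$gc[grid$f], rev$gc[grid$r], cons)
  dtm <- abs(fwd$tm[grid$f] - rev$tm[grid$r])
  o <- order(pen, fwd$start[grid$f], rev$start[grid$r], fwd$seq[grid$f])
  taken <- list()
  for (k in o) {
    if (dtm[k] > cons$max_pair_tm_diff) next
    pc <- complementarity(fwd$seq[grid$f[k]], rev$seq[grid$r[k]])
    if (pc$score >= cons$max_self_comp || pc$end_run >= cons$max_end_comp)
      next
    f <- grid$f[k]; r <- grid$r[k]
    taken[[length(taken) + 1L]] <- data.frame(
      fwd_seq = fwd$seq[f], rev_seq = rev$seq[r],
      fwd_start = fwd$start[f], rev_start = rev$start[r] + rev$len[r] - 1L,
      fwd_len = fwd$len[f], rev_len = rev$len[r],
      product_len = prod_len[k],
      fwd_tm = fwd$tm[f], rev_tm = rev$tm[r],
      fwd_gc = fwd$gc[f], rev_gc = rev$gc[r],
      pair_comp = pc$score, pair_end_comp = pc$end_run,
      penalty = pen[k], junction_primer = junction_side,
      stringsAsFactors = FALSE)
    if (length(taken) == n) break
  }
  if (length(taken) == 0L) return(empty_pairs())
  do.call(rbind, c(taken, list(make.row.names = FALSE)))
}

empty_pairs <- function() {
  data.frame(fwd_seq = character(), rev_seq = character(),
             fwd_start = integer(), rev_start = integer(),
             fwd_len = integer(), rev_len = integer(),
             product_len = integer(), fwd_tm = numeric(),
             rev_tm = numeric(), fwd_gc = numeric(), rev_gc = numeric(),
             pair_comp = integer(), pair_end_comp = integer(),
             penalty = numeric(), junction_primer = character(),
             stringsAsFactors = FALSE)
}

#' Design primer pairs across a splice junction
#'
#' Enumerates all (junction-overlapping candidate, opposite free candidate)
#' combinations in both configurations (junction-spanning forward with a
#' downstream free reverse, and junction-spanning reverse with an upstream
#' free forward), keeps those with an in-range product, a pair Tm
#' difference within the cap and acceptable pair complementarity, ranks
#' them by [pair_penalty()] with deterministic tie-breaks
#' (`fwd_start`, `rev_start`, `fwd_seq`) and returns the top `n`.  The free
#' primer never touches the junction, so exactly one primer of every
#' returned pair overlaps it.
#'
#' @param template spliced transcript sequence.
#' @param junction_pos 0-based transcript-local junction position.
#' @param constraints a [design_constraints()] object.
#' @param n maximum number of pairs (default `constraints$n_return`, 5).
#' @return data.frame of pairs (possibly empty): oligo sequences, 0-based
#'   5' positions (`fwd_start`, `rev_start`), product length, per-primer
#'   stats, `penalty` and which primer spans the junction
#'   (`junction_primer` = `"F"`/`"R"`).
#' @export
design_pairs <- function(template, junction_pos,
                         constraints = design_constraints(),
                         n = constraints$n_return) {
  cons <- constraints
  jc <- enumerate_junction_primers(template, junction_pos, cons)
  res <- empty_pairs()
  jF <- jc[jc$orientation == "F", , drop = FALSE]
  if (nrow(jF)) {
    freeR <- window_candidates(template, junction_pos,
                               min(nchar(template),
                                   max(jF$start) + cons$product_max),
                               "R", cons)
    res <- rbind(res, rank_pairs(jF, freeR, template, cons, n, "F"))
  }
  jR <- jc[jc$orientation == "R", , drop = FALSE]
  if (nrow(jR)) {
    freeF <- window_candidates(template,
                               max(0L, min(jR$start + jR$len) -
                                     cons$product_max),
                               junction_pos, "F", cons)
    # free forward must end at or before the junction
    freeF <- freeF[freeF$start + freeF$len <= junction_pos, , drop = FALSE]
    res <- rbind(res, rank_pairs(freeF, jR, template, cons, n, "R"))
  }
  if (nrow(res) == 0L) return(res)
  res <- res[order(res$penalty, res$fwd_start, res$rev_start, res$fwd_seq), ,
             drop = FALSE]
  res <- res[seq_len(min(n, nrow(res))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Design primer pairs without a junction requirement
#'
#' Single-isoform mode: same enumeration, filtering and ranking as
#' [design_pairs()] but with no junction-overlap rule; any forward/reverse
#' window combination with an in-range product competes.
#'
#' @inheritParams design_pairs
#' @return data.frame of pairs as in [design_pairs()], `junction_primer`
#'   `NA`.
#' @export
design_free_pairs <- function(template,
                              constraints = design_constraints(),
                              n = constraints$n_return) {
  cons <- constraints
  if (nchar(template) < cons$product_min) return(empty_pairs())
  fwd <- window_candidates(template, 0L, nchar(template), "F", cons)
  rev <- window_candidates(template, 0L, nchar(template), "R", cons)
  res <- rank_pairs(fwd, rev, template, cons, n, NA_character_)
  if (nrow(res) == 0L) return(res)
  res <- res[order(res$penalty, res$fwd_start, res$rev_start, res$fwd_seq), ,
             drop = FALSE]
  res <- res[seq_len(min(n, nrow(res))), , drop = FALSE]
  rownames(res) <- NULL
  res
}
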