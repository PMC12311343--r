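# Junction-overlapping primer enumeration, penalty ranking, pair design.

# Balanced random template so quality filters leave plenty of candidates.
balanced_template <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
}

test_that("junction candidates obey the overlap geometry", {
  tpl <- balanced_template(600, 501)
  cand <- enumerate_junction_primers(tpl, 300)
  expect_gt(nrow(cand), 0)
  f <- cand[cand$orientation == "F", ]
  r <- cand[cand$orientation == "R", ]
  # forward: >= 7 nt 5' of the junction, >= 4 nt 3' of it
  expect_true(all(f$start <= 300 - 7))
  expect_true(all(f$start + f$len >= 300 + 4))
  # reverse: mirrored (5' side is right of the junction)
  expect_true(all(r$start + r$len >= 300 + 7))
  expect_true(all(r$start <= 300 - 4))
})

test_that("a junction too close to the 5' end only admits reverse primers", {
  tpl <- balanced_template(400, 502)
  cand <- enumerate_junction_primers(tpl, 5)
  expect_false(any(cand$orientation == "F"))
})

test_that("candidates violating hard constraints are absent", {
  tpl <- balanced_template(600, 503)
  # plant a 5-A homopolymer right of the junction
  tpl <- paste0(substr(tpl, 1, 304), "AAAAA", substr(tpl, 310, 600))
  cand <- enumerate_junction_primers(tpl, 300)
  cons <- design_constraints()
  expect_true(all(!grepl("AAAAA", cand$seq)))
  expect_true(all(grepl("TTTTT", cand$seq) == FALSE))
  expect_true(all(cand$gc >= cons$gc_min & cand$gc <= cons$gc_max))
  expect_true(all(cand$tm >= cons$tm_min & cand$tm <= cons$tm_max))
  expect_true(all(cand$max_run <= cons$max_poly_run))
})

test_that("pair_penalty matches an independently coded formula", {
  cons <- design_constraints()
  expect_equal(pair_penalty(60, 60, 22, 22, 50, 50, cons), 0)
  # monotone in any single deviation
  expect_gt(pair_penalty(62, 60, 22, 22, 50, 50, cons),
            pair_penalty(61, 60, 22, 22, 50, 50, cons))
  oracle <- function(ft, rt, fl, rl, fg, rg)
    (abs(ft - 60) + abs(rt - 60)) + 0.5 * (abs(fl - 22) + abs(rl - 22)) +
    0.2 * (abs(fg - 50) + abs(rg - 50)) + abs(ft - rt)
  set.seed(61)
  for (i in 1:100) {
    ft <- runif(1, 50, 80); rt <- runif(1, 50, 80)
    fl <- sample(18:28, 1); rl <- sample(18:28, 1)
    fg <- runif(1, 20, 80); rg <- runif(1, 20, 80)
    expect_equal(pair_penalty(ft, rt, fl, rl, fg, rg, cons),
                 oracle(ft, rt, fl, rl, fg, rg))
  }
})

test_that("design_pairs returns n ranked pairs with one junction primer each", {
  tpl <- balanced_template(600, 504)
  pairs <- design_pairs(tpl, 300)
  expect_equal(nrow(pairs), 5L)
  expect_true(all(diff(pairs$penalty) >= 0))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    # exactly one primer spans the junction
    f_spans <- p$fwd_start <= 300 - 7 &&
      p$fwd_start + p$fwd_len >= 300 + 4
    r0 <- p$rev_start - p$rev_len + 1      # reverse footprint left edge
    r_spans <- r0 <= 300 - 4 && p$rev_start + 1 >= 300 + 7
    expect_equal(f_spans + r_spans, 1L)
    expect_equal(p$product_len, p$rev_start - p$fwd_start + 1L)
  }
  # narrowed constraints cannot exceed the feasible set
  few <- design_pairs(tpl, 300, design_constraints(tm_min = 55, tm_max = 58))
  expect_lte(nrow(few), 5L)
  # determinism
  expect_identical(design_pairs(tpl, 300), pairs)
})

test_that("emitted pairs always satisfy every hard constraint", {
  cons <- design_constraints()
  seeds <- 600 + 1:40
  for (s in seeds) {
    tpl <- balanced_template(sample(seq(350, 650, by = 50), 1), s)
    jpos <- nchar(tpl) %/% 2
    pairs <- design_pairs(tpl, jpos)
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      for (oligo in c(p$fwd_seq, p$rev_seq)) {
        st <- oligo_stats(oligo)
        expect_true(nchar(oligo) >= cons$primer_len_min &&
                      nchar(oligo) <= cons$primer_len_max)
        expect_true(st$gc_percent >= cons$gc_min &&
                      st$gc_percent <= cons$gc_max)
        expect_true(st$tm_celsius >= cons$tm_min &&
                      st$tm_celsius <= cons$tm_max)
        expect_lte(st$max_run, cons$max_poly_run)
        expect_lt(st$self_comp_score, cons$max_self_comp)
        expect_lt(st$self_end_run, cons$max_end_comp)
        expect_false(st$hairpin_flag)
      }
      expect_true(p$product_len >= cons$product_min &&
                    p$product_len <= cons$product_max)
      expect_lte(abs(p$fwd_tm - p$rev_tm), cons$max_pair_tm_diff)
      pc <- complementarity(p$fwd_seq, p$rev_seq)
      expect_lt(pc$score, cons$max_self_comp)
      expect_lt(pc$end_run, cons$max_end_comp)
    }
  }
})

test_that("the top-ranked pair is penalty-optimal among all feasible pairs", {
  # exhaustive oracle on a small template: every window's stats computed
  # once from the primitives, then every pair combination enumerated
  # directly; the minimum penalty must equal design_pairs' top rank.
  cons <- design_constraints()
  tpl <- NULL
  for (s in 505:512) {                     # first template with a feasible pair
    cand <- balanced_template(400, s)
    if (nrow(design_pairs(cand, 200L)) > 0L) { tpl <- cand; break }
  }
  expect_false(is.null(tpl))
  jpos <- 200L
  pairs <- design_pairs(tpl, jpos)
  n <- nchar(tpl)
  wins <- list()
  for (len in 20:25) for (st in 0:(n - len)) {
    win <- substr(tpl, st + 1, st + len)
    for (ori in c("F", "R")) {
      oligo <- if (ori == "F") win else revcomp(win)
      os <- oligo_stats(oligo)
      if (os$gc_percent < 30 || os$gc_percent > 60) next
      if (os$tm_celsius < 55 || os$tm_celsius > 75) next
      if (os$max_run > 4 || os$self_comp_score >= 8 ||
          os$self_end_run >= 4 || os$hairpin_flag) next
      wins[[length(wins) + 1L]] <- list(ori = ori, s = st, e = st + len,
                                        len = len, seq = oligo,
                                        tm = os$tm_celsius,
                                        gc = os$gc_percent)
    }
  }
  fwds <- Filter(function(w) w$ori == "F", wins)
  revs <- Filter(function(w) w$ori == "R", wins)
  best <- Inf
  for (f in fwds) for (r in revs) {
    prod <- r$e - f$s
    if (prod < 100 || prod > 300 || r$s < f$e) next
    f_spans <- f$s <= jpos - 7 && f$e >= jpos + 4
    r_spans <- r$e >= jpos + 7 && r$s <= jpos - 4
    r_free <- r$s >= jpos
    f_free <- f$e <= jpos
    if (!((f_spans && r_free) || (r_spans && f_free))) next
    if (abs(f$tm - r$tm) > 5) next
    pen <- pair_penalty(f$tm, r$tm, f$len, r$len, f$gc, r$gc, cons)
    if (pen >= best) next                   # complementarity check last
    pc <- complementarity(f$seq, r$seq)
    if (pc$score >= 8 || pc$end_run >= 4) next
    best <- pen
  }
  expect_equal(pairs$penalty[1], best, tolerance = 1e-9)
})

test_that("design_free_pairs covers the single-isoform mode", {
  tpl <- balanced_template(500, 506)
  pairs <- design_free_pairs(tpl)
  expect_gte(nrow(pairs), 1L)
  expect_true(all(pairs$product_len >= 100 & pairs$product_len <= 300))
  expect_true(all(diff(pairs$penalty) >= 0))
  expect_true(all(is.na(pairs$junction_primer)))
  # an 80-nt template cannot reach the 100-bp minimum product
  expect_equal(nrow(design_free_pairs(balanced_template(80, 507))), 0L)
})
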