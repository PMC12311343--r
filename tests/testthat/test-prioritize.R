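# Specificity, filters, scoring and selection policy.

mk_hits <- function(ids, lengths = rep(200L, length(ids))) {
  data.frame(template_id = ids, length = lengths, stringsAsFactors = FALSE)
}

mk_calls <- function(tpm, expressed = NULL) {
  if (is.null(expressed)) expressed <- tpm > 0
  data.frame(transcript_id = names(tpm), mean_tpm = unname(tpm),
             expressed = unname(expressed), gene_quantile_cutoff = 0,
             stringsAsFactors = FALSE)
}

mk_scored <- function(ids, score, lengths = rep(200L, length(ids)),
                      fwd = "ACGT") {
  list(pair = list(fwd_seq = fwd, pair_id = "p"),
       score = score, amplified_expressed_ids = ids,
       amplicon_lengths = lengths, coverage_percent = NA_real_)
}

test_that("specificity_filter discards outside-gene and empty hit sets", {
  gene_tx <- c("T1", "T2", "T3")
  v <- specificity_filter(mk_hits(c("T1", "T2")), gene_tx)
  expect_true(v$specific)
  expect_equal(v$discarded_reason, "none")
  v <- specificity_filter(mk_hits(c("T1", "DECOY")), gene_tx)
  expect_false(v$specific)
  expect_equal(v$discarded_reason, "nonspecific")
  v <- specificity_filter(mk_hits(character(0)), gene_tx)
  expect_equal(v$discarded_reason, "no_expressed_target")
})

test_that("length-spread boundary is inclusive at 25 nt", {
  expect_false(length_spread_filter(c(180L, 206L)))   # spread 26: discard
  expect_true(length_spread_filter(c(180L, 205L)))    # spread 25: pass
  expect_true(length_spread_filter(195L))             # single amplicon
  expect_error(length_spread_filter(integer(0)), "no amplicons")
})

test_that("length preference peaks at 200 bp and is symmetric", {
  expect_equal(length_component(200), 10)
  expect_equal(length_component(300), 0)
  expect_equal(length_component(190), length_component(210))
  expect_equal(length_component(c(190, 200, 210)), 10)  # median based
  grid <- vapply(100:300, length_component, numeric(1))
  expect_equal(100 + which.max(grid) - 1L, 200L)
  expect_true(all(diff(grid[101:201]) <= 0))            # away from 200
})

test_that("score_pair composes coverage, isoform bonus and length preference", {
  calls <- mk_calls(c(T1 = 50, T2 = 0, T3 = 0))
  sc <- score_pair("T1", calls, 200L)
  expect_equal(sc$coverage_percent, 100)
  expect_equal(sc$score, 120)                          # 100 + 10 + 10
  sc <- score_pair("T1", calls, 300L)
  expect_equal(sc$score, 110)
  # an extra amplified expressed isoform never lowers the score
  calls2 <- mk_calls(c(T1 = 50, T2 = 30, T3 = 0))
  s1 <- score_pair("T1", calls2, 200L)
  s2 <- score_pair(c("T1", "T2"), calls2, 200L)
  expect_gte(s2$score, s1$score)
  # coverage weights by expression
  expect_equal(s1$coverage_percent, 100 * 50 / 80)
  # non-expressed amplification adds nothing
  s3 <- score_pair(c("T1", "T3"), calls2, 200L)
  expect_equal(s3$score, s1$score)
})

test_that("select_pairs implements the selection modes", {
  calls <- mk_calls(c(A = 40, B = 30, C = 20))
  # greedy cover when no single pair covers everything
  sp <- list(mk_scored(c("A", "B"), 120, fwd = "AAAA"),
             mk_scored(c("B", "C"), 110, fwd = "CCCC"),
             mk_scored("C", 105, fwd = "GGGG"))
  res <- select_pairs("G", sp, calls)
  expect_equal(res$mode, "multi_pair_cover")
  expect_length(res$selected, 2L)
  expect_setequal(unlist(lapply(res$selected, `[[`,
                                "amplified_expressed_ids")),
                  c("A", "B", "C"))
  expect_length(res$uncovered_expressed, 0L)
  # single full-cover pair wins alone
  sp2 <- c(sp, list(mk_scored(c("A", "B", "C"), 140, fwd = "TTTT")))
  res2 <- select_pairs("G", sp2, calls)
  expect_equal(res2$mode, "shared_junction")
  expect_length(res2$selected, 1L)
  expect_equal(res2$selected[[1]]$score, 140)
  # no-progress stop reports uncovered isoforms
  res3 <- select_pairs("G", list(mk_scored("A", 120)), calls)
  expect_equal(res3$mode, "multi_pair_cover")
  expect_setequal(res3$uncovered_expressed, c("B", "C"))
  # nothing survives
  res4 <- select_pairs("G", list(), calls)
  expect_equal(res4$mode, "failed")
  # single-isoform gene label
  res5 <- select_pairs("G", list(mk_scored("A", 120)),
                       mk_calls(c(A = 10)), single_isoform = TRUE)
  expect_equal(res5$mode, "single_isoform")
})

test_that("greedy cover is complete, irredundant and near-minimal", {
  # Instances with scores computed by score_pair itself (as in the
  # pipeline), so that wider-covering pairs outscore their subsets.
  set.seed(71)
  n_bound_checked <- 0L
  for (trial in 1:60) {
    n_iso <- sample(3:10, 1)
    iso <- paste0("I", seq_len(n_iso))
    tpm <- setNames(runif(n_iso, 1, 100), iso)
    calls <- mk_calls(tpm)
    n_pairs <- sample(3:12, 1)
    pairs <- lapply(seq_len(n_pairs), function(i) {
      cov <- sample(iso, sample(1:min(4, n_iso), 1))
      len <- sample(100:300, 1)
      sc <- score_pair(cov, calls, len)
      s <- mk_scored(cov, score = sc$score, lengths = len,
                     fwd = paste0("P", i))
      s$coverage_percent <- sc$coverage_percent
      s
    })
    res <- select_pairs("G", pairs, calls)
    union_cov <- unique(unlist(lapply(pairs, `[[`,
                                      "amplified_expressed_ids")))
    # complete whenever a cover exists
    expect_equal(length(res$uncovered_expressed) == 0,
                 setequal(intersect(union_cov, iso), iso))
    # every selected pair contributes a new isoform (irredundancy)
    seen <- character(0)
    for (p in res$selected) {
      expect_gt(length(setdiff(p$amplified_expressed_ids, seen)), 0)
      seen <- union(seen, p$amplified_expressed_ids)
    }
    # near-minimality against the exhaustive minimum cover
    if (length(res$uncovered_expressed) == 0 && res$mode != "failed") {
      best <- Inf
      for (mask in 1:(2^n_pairs - 1)) {
        sel <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0)
        cov <- unique(unlist(lapply(pairs[sel], `[[`,
                                    "amplified_expressed_ids")))
        if (setequal(intersect(cov, iso), iso))
          best <- min(best, length(sel))
      }
      expect_lte(length(res$selected), best + 1)
      n_bound_checked <- n_bound_checked + 1L
    }
  }
  expect_gt(n_bound_checked, 10)
})

test_that("selection is invariant to the order pairs are supplied", {
  calls <- mk_calls(c(A = 40, B = 30, C = 20))
  sp <- list(mk_scored(c("A", "B"), 120, fwd = "AAAA"),
             mk_scored(c("B", "C"), 110, fwd = "CCCC"),
             mk_scored("C", 105, fwd = "GGGG"),
             mk_scored(c("A", "C"), 115, fwd = "TTTT"))
  ref <- select_pairs("G", sp, calls)
  set.seed(81)
  for (i in 1:10) {
    perm <- sample(sp)
    got <- select_pairs("G", perm, calls)
    expect_equal(got$mode, ref$mode)
    expect_equal(lapply(got$selected, `[[`, "amplified_expressed_ids"),
                 lapply(ref$selected, `[[`, "amplified_expressed_ids"))
  }
})
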