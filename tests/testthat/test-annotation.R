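# GTF parsing, spliced sequences, TSL filtering, junctions and probes.

toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_support_level "1";',
    'chr1\ttest\texon\t301\t360\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_support_level "1";',
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T2"; transcript_support_level "4";',
    'chr1\ttest\texon\t241\t260\t.\t+\t.\tgene_id "G1"; transcript_id "T2"; transcript_support_level "4";',
    'chr1\ttest\texon\t301\t360\t.\t+\t.\tgene_id "G1"; transcript_id "T2"; transcript_support_level "4";'
  ), path)
  path
}

test_that("parse_gtf groups exons, converts coordinates and reports absences", {
  genes <- suppressWarnings(parse_gtf(toy_gtf(), c("G1", "GX")))
  expect_named(genes, "G1")
  g <- genes$G1
  expect_equal(length(g$transcripts), 2L)
  expect_equal(nrow(g$transcripts$T1$exons), 2L)
  expect_equal(nrow(g$transcripts$T2$exons), 3L)
  # 1-based [101,200] -> 0-based half-open [100,200), length 100
  expect_equal(g$transcripts$T1$exons$start[1], 100L)
  expect_equal(g$transcripts$T1$exons$end[1], 200L)
  expect_equal(g$transcripts$T1$exons$end[1] - g$transcripts$T1$exons$start[1],
               100L)
  expect_equal(g$transcripts$T1$tsl, 1L)
  expect_equal(g$transcripts$T2$tsl, 4L)
  expect_warning(parse_gtf(toy_gtf(), c("G1", "GX")), "GX")
})

test_that("parse_gtf rejects malformed lines and duplicate exons", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(readLines(toy_gtf()), "chr1\tbroken line"), bad)
  expect_error(parse_gtf(bad, "G1"), "line 6")
  dup <- tempfile(fileext = ".gtf")
  l <- readLines(toy_gtf())
  writeLines(c(l, l[1]), dup)
  expect_error(parse_gtf(dup, "G1"), "duplicate exon")
  expect_error(parse_gtf(toy_gtf(), character(0)), "non-empty")
})

test_that("splice_sequence concatenates, reverse-complements and cross-checks", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = "TTTACGTCCGGCCAAA",     # exons [3,7)=ACGT and [9,13)=GGCC
    chrB = "TTAAACCCGG"))          # single exon [2,8) = AAACCC
  tx_plus <- isoqpcr:::new_transcript_model(
    "P1", "G", "chrA", "+", data.frame(start = c(3L, 9L), end = c(7L, 13L)))
  expect_equal(splice_sequence(tx_plus, genome), "ACGTGGCC")
  tx_minus <- isoqpcr:::new_transcript_model(
    "M1", "G", "chrB", "-", data.frame(start = 2L, end = 8L))
  expect_equal(splice_sequence(tx_minus, genome), "GGGTTT")
  # transcriptome disagreement: warning, FASTA wins
  fa <- Biostrings::DNAStringSet(c(P1 = "ACGTGGCA"))
  expect_warning(s <- splice_sequence(tx_plus, genome, fa), "disagrees")
  expect_equal(s, "ACGTGGCA")
  # exon beyond chromosome end
  tx_bad <- isoqpcr:::new_transcript_model(
    "B1", "G", "chrB", "+", data.frame(start = 2L, end = 99L))
  expect_error(splice_sequence(tx_bad, genome), "outside")
})

test_that("filter_by_tsl keeps TSL <= 3 and missing TSL, flags empty genes", {
  mk_gene <- function(tsls) {
    txs <- lapply(seq_along(tsls), function(i)
      isoqpcr:::new_transcript_model(paste0("T", i), "G", "chr1", "+",
                                     data.frame(start = 0L, end = 10L),
                                     tsl = tsls[i]))
    names(txs) <- paste0("T", seq_along(tsls))
    structure(list(gene_id = "G", gene_id_full = "G", transcripts = txs,
                   template_ids = names(txs)), class = "gene_model")
  }
  g <- filter_by_tsl(mk_gene(c(1L, 2L, 3L, 4L, 5L)))
  expect_equal(g$template_ids, c("T1", "T2", "T3"))
  g <- filter_by_tsl(mk_gene(c(NA_integer_, NA_integer_)))
  expect_equal(g$template_ids, c("T1", "T2"))
  expect_warning(g <- filter_by_tsl(mk_gene(c(5L, 5L))), "no eligible")
  expect_true(attr(g, "no_template"))
})

test_that("junction_probe slices the straddling 10-mer or returns NA", {
  expect_equal(junction_probe("AAAAACCCCCGGGGGTTTTT", 10), "CCCCCGGGGG")
  expect_true(is.na(junction_probe("AAAAACCCCCGGGGGTTTTT", 3)))
  expect_true(is.na(junction_probe("AAAAACCCCCGGGGGTTTTT", 17)))
  expect_equal(junction_probe("AAAAACCCCCGGGGGTTTTT", 5), "AAAAACCCCC")
  expect_error(junction_probe("ACGT", 0), "0 < pos")
})

test_that("enumerate_junctions: positions, deduplication, single-exon", {
  fx <- fx_shared()
  g <- fx$genes$GENE1
  # junction positions are cumulative exon length boundaries
  for (tx in g$transcripts) {
    lens <- tx$exons$end - tx$exons$start
    occ <- g$junction_occ[g$junction_occ$transcript_id == tx$transcript_id, ]
    expect_equal(sort(occ$pos), cumsum(lens)[-length(lens)],
                 info = tx$transcript_id)
    expect_equal(nrow(occ), nrow(tx$exons) - 1L)  # e-1 junctions, always
  }
  # shared junction deduplicated into one gene-level record
  shared <- g$junctions$junction_id[
    g$junctions$junction_id %in%
      names(which(table(g$junction_occ$junction_id) == 3))]
  expect_length(shared, 1L)
  # single-exon transcript contributes none
  tx1 <- isoqpcr:::new_transcript_model("S1", "GS", "chr1", "+",
                                        data.frame(start = 0L, end = 50L))
  tx1$spliced_seq <- strrep("ACGT", 13)
  gs <- structure(list(gene_id = "GS", gene_id_full = "GS",
                       transcripts = list(S1 = tx1),
                       template_ids = "S1"), class = "gene_model")
  gs <- enumerate_junctions(gs)
  expect_equal(nrow(gs$junctions), 0L)
})

test_that("probes straddle the exon boundary on fixture genes", {
  fx <- fx_shared()
  g <- fx$genes$GENE1
  for (i in seq_len(nrow(g$junctions))) {
    jid <- g$junctions$junction_id[i]
    probe <- g$junctions$probe[i]
    if (is.na(probe)) next
    occ <- g$junction_occ[g$junction_occ$junction_id == jid, ][1, ]
    tx <- g$transcripts[[occ$transcript_id]]
    expect_equal(substr(tx$spliced_seq, occ$pos - 4, occ$pos + 5), probe)
    # 5 bases each side of the boundary
    expect_equal(probe,
                 paste0(substr(tx$spliced_seq, occ$pos - 4, occ$pos),
                        substr(tx$spliced_seq, occ$pos + 1, occ$pos + 5)))
  }
})

test_that("rank_junctions prevalence equals a naive substring oracle", {
  fx <- fx_shared()
  g <- fx$genes$GENE1
  rk <- rank_junctions(g)
  seqs <- vapply(g$transcripts, `[[`, character(1), "spliced_seq")
  for (i in seq_len(nrow(rk))) {
    naive <- sum(vapply(seqs, function(s)
      length(gregexpr(rk$probe[i], s, fixed = TRUE)[[1]]) > 0 &&
        gregexpr(rk$probe[i], s, fixed = TRUE)[[1]][1] != -1, logical(1)))
    expect_equal(rk$prevalence[i], naive, info = rk$junction_id[i])
  }
  expect_true(all(diff(rk$prevalence) <= 0))   # sorted descending
  # a junction of the shared fixture is present in all three isoforms
  expect_equal(rk$prevalence[1], 3L)

  # random multi-isoform gene: build 12 isoforms over random exon subsets
  spec <- locus_spec(n_isoforms = 6L, seed = 99L)
  fx2 <- make_locus(spec)
  g2 <- fx2$genes$GENE1
  rk2 <- rank_junctions(g2)
  seqs2 <- vapply(g2$transcripts, `[[`, character(1), "spliced_seq")
  for (i in seq_len(nrow(rk2))) {
    naive <- sum(vapply(seqs2, function(s)
      grepl(rk2$probe[i], s, fixed = TRUE), logical(1)))
    expect_equal(rk2$prevalence[i], naive)
  }
  # a probe occurring twice within one transcript still counts once
  tx <- g$transcripts[[1]]
  probe <- rank_junctions(g)$probe[1]
  tx$spliced_seq <- paste0(tx$spliced_seq, probe)  # plant a second copy
  gmod <- g
  gmod$transcripts[[1]] <- tx
  rkm <- rank_junctions(gmod)
  expect_equal(rkm$prevalence[rkm$probe == probe], 3L)
})

test_that("gene models round-trip through GTF", {
  fx <- fx_shared()
  path <- tempfile(fileext = ".gtf")
  write_gtf(fx$genes, path)
  back <- parse_gtf(path, names(fx$genes))
  for (gid in names(fx$genes)) {
    for (tid in names(fx$genes[[gid]]$transcripts)) {
      a <- fx$genes[[gid]]$transcripts[[tid]]
      b <- back[[gid]]$transcripts[[tid]]
      expect_equal(a$exons, b$exons, info = tid)
      expect_equal(a$strand, b$strand)
      expect_equal(a$tsl, b$tsl)
    }
  }
})

test_that("minus-strand fixtures splice to the transcriptome records", {
  fxm <- make_locus(locus_spec(strand = "-", seed = 77L))
  genome <- Biostrings::DNAStringSet(fxm$genome)
  for (g in fxm$genes) for (tx in g$transcripts) {
    expect_equal(splice_sequence(tx, genome),
                 unname(fxm$transcriptome[[tx$transcript_id]]))
  }
})
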