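# Seeded generator of toy genomes, annotations, transcriptomes and
# expression tables with controlled splicing structure, so every stage and
# the end-to-end pipeline are testable without downloads.

#' Specification of a synthetic locus
#'
#' Describes one multi-isoform gene (plus, optionally, a decoy paralog on a
#' second chromosome) to be generated by [make_locus()].  Isoform
#' structures are deterministic functions of `n_isoforms`: with
#' `shared_junction = TRUE` every isoform contains master exons 1 and 2
#' consecutively, so junction (1,2) is common to all; with `FALSE` isoform
#' k is the exon chain {k, k+1}, so no junction occurs in more than one
#' isoform.  Exon and intron lengths are drawn uniformly from their
#' ranges; base composition is uniform.
#'
#' @param n_isoforms number of isoforms of the target gene (>= 1).
#' @param exon_len_range,intron_len_range length ranges in nt (defaults
#'   80-300 and 500-5000).
#' @param shared_junction logical, see above; must be `TRUE` when
#'   `n_isoforms == 1`.
#' @param decoy_paralog add a second gene on another chromosome whose
#'   exons are ~90% identical to the target's.
#' @param expression_profile numeric TPM per isoform; default
#'   `100 * 0.6^(k-1)`.
#' @param tsl integer TSL per isoform (default all 1).
#' @param strand `"+"` or `"-"`.
#' @param gene_id,chrom identifiers used in the generated files.
#' @param n_samples number of expression-table samples (default 3; sample
#'   s scales the profile by 0.9/1.0/1.1..., so the across-sample mean
#'   equals the profile exactly).
#' @param seed RNG seed; the generated files are a pure function of the
#'   spec including the seed.
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(n_isoforms = 3L, exon_len_range = c(80L, 300L),
                       intron_len_range = c(500L, 5000L),
                       shared_junction = TRUE, decoy_paralog = FALSE,
                       expression_profile = NULL, tsl = NULL,
                       strand = "+", gene_id = "GENE1", chrom = "chrT1",
                       n_samples = 3L, seed = 42L) {
  if (n_isoforms < 1L) stop("n_isoforms must be >= 1", call. = FALSE)
  if (n_isoforms == 1L && !shared_junction)
    stop("a single-isoform gene cannot have a non-shared junction structure",
         call. = FALSE)
  if (is.null(expression_profile))
    expression_profile <- 100 * 0.6^(seq_len(n_isoforms) - 1)
  if (length(expression_profile) != n_isoforms)
    stop("expression_profile length must equal n_isoforms", call. = FALSE)
  if (is.null(tsl)) tsl <- rep(1L, n_isoforms)
  structure(list(n_isoforms = as.integer(n_isoforms),
                 exon_len_range = exon_len_range,
                 intron_len_range = intron_len_range,
                 shared_junction = shared_junction,
                 decoy_paralog = decoy_paralog,
                 expression_profile = expression_profile,
                 tsl = as.integer(tsl), strand = strand,
                 gene_id = gene_id, chrom = chrom,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "locus_spec")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Isoform structures as index vectors into the master exon list.
isoform_structures <- function(spec) {
  n <- spec$n_isoforms
  if (n == 1L) return(list(c(1L, 2L, 3L)))
  if (spec$shared_junction) {
    s <- lapply(seq_len(n - 1L), function(k) c(1L, 2L, 2L + k))
    c(s, list(c(1L, 2L)))
  } else {
    lapply(seq_len(n), function(k) c(k, k + 1L))
  }
}

mutate_seq <- function(seq, rate = 0.1) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(b), max(1L, round(rate * length(b))))
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  b[idx] <- swap[b[idx]]
  paste(b, collapse = "")
}

#' Generate a synthetic locus
#'
#' Builds a mutually consistent genome FASTA, GTF, transcriptome FASTA and
#' expression table for a [locus_spec()]: transcript sequences are
#' re-derivable from genome + GTF by construction, which the test-suite
#' round-trip checks exploit.  Deterministic for a given spec (the caller's
#' RNG state is left untouched).
#'
#' @param spec a [locus_spec()].
#' @param dir optional directory; when given, `genome.fa`,
#'   `annotation.gtf`, `transcriptome.fa`, `kalcounts.tsv` and `genes.txt`
#'   are written there.
#' @return list of class `locus_fixture`: `spec`, `genes` (list of
#'   `gene_model` with spliced sequences), `target_gene_ids`, `genome`
#'   (named character), `transcriptome` (named character), `kalcounts`
#'   (data.frame) and, when written, `paths`.
#' @export
make_locus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "locus_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  structs <- isoform_structures(spec)
  n_exons <- max(unlist(structs))
  exon_len <- sample(spec$exon_len_range[1]:spec$exon_len_range[2], n_exons,
                     replace = TRUE)
  intron_len <- sample(spec$intron_len_range[1]:spec$intron_len_range[2],
                       max(1L, n_exons - 1L), replace = TRUE)
  exon_seq <- vapply(exon_len, rand_dna, character(1))

  build_gene <- function(gene_id, chrom, exon_seq, tsl_vec) {
    pad <- 200L
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- pad
    chrom_parts <- list(rand_dna(pad))
    for (i in seq_len(n_exons)) {
      starts[i] <- pos
      ends[i] <- pos + nchar(exon_seq[i])
      chrom_parts[[length(chrom_parts) + 1L]] <- exon_seq[i]
      pos <- ends[i]
      if (i < n_exons) {
        chrom_parts[[length(chrom_parts) + 1L]] <- rand_dna(intron_len[i])
        pos <- pos + intron_len[i]
      }
    }
    chrom_parts[[length(chrom_parts) + 1L]] <- rand_dna(pad)
    chrom_seq <- paste(unlist(chrom_parts), collapse = "")
    txs <- list()
    for (k in seq_along(structs)) {
      idx <- structs[[k]]
      ex <- data.frame(start = starts[idx], end = ends[idx])
      if (spec$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
      tid <- sprintf("%s_T%d", gene_id, k)
      txs[[tid]] <- new_transcript_model(tid, gene_id, chrom, spec$strand,
                                         ex, tsl_vec[k])
    }
    gene <- structure(list(gene_id = gene_id, gene_id_full = gene_id,
                           transcripts = txs, template_ids = names(txs),
                           junctions = NULL, junction_occ = NULL),
                      class = "gene_model")
    list(gene = gene, chrom_seq = chrom_seq)
  }

  target <- build_gene(spec$gene_id, spec$chrom, exon_seq, spec$tsl)
  genome <- setNames(target$chrom_seq, spec$chrom)
  genes <- list(target$gene)
  profiles <- list(setNames(spec$expression_profile,
                            names(target$gene$transcripts)))
  if (spec$decoy_paralog) {
    decoy_exon <- vapply(exon_seq, mutate_seq, character(1),
                         USE.NAMES = FALSE)
    decoy_id <- paste0(spec$gene_id, "_PARALOG")
    decoy <- build_gene(decoy_id, paste0(spec$chrom, "d"), decoy_exon,
                        rep(1L, spec$n_isoforms))
    genome[paste0(spec$chrom, "d")] <- decoy$chrom_seq
    genes[[2]] <- decoy$gene
    profiles[[2]] <- setNames(rep(10, length(decoy$gene$transcripts)),
                              names(decoy$gene$transcripts))
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")

  genome_ss <- Biostrings::DNAStringSet(genome)
  genes <- lapply(genes, function(g) {
    g$transcripts <- lapply(g$transcripts, function(tx) {
      tx$spliced_seq <- splice_sequence(tx, genome_ss)
      tx
    })
    enumerate_junctions(g)
  })
  transcriptome <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, `[[`, character(1), "spliced_seq")))
  names(transcriptome) <- unlist(lapply(genes, function(g)
    names(g$transcripts)))

  profile <- unlist(profiles)
  scale <- 0.9 + 0.1 * (seq_len(spec$n_samples) - 1)
  scale <- scale / mean(scale)              # across-sample mean == profile
  kal <- data.frame(target_id = names(profile), stringsAsFactors = FALSE)
  for (s in seq_len(spec$n_samples))
    kal[[sprintf("sample%d", s)]] <- unname(profile) * scale[s]

  fixture <- structure(list(spec = spec, genes = genes,
                            target_gene_ids = spec$gene_id,
                            genome = genome, transcriptome = transcriptome,
                            kalcounts = kal),
                       class = "locus_fixture")
  if (!is.null(dir)) fixture <- write_locus(fixture, dir)
  fixture
}

#' Write a synthetic locus to disk
#'
#' @param fixture a `locus_fixture`.
#' @param dir output directory (created if needed).
#' @return the fixture with a `paths` element added.
#' @export
write_locus <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                transcriptome = file.path(dir, "transcriptome.fa"),
                kalcounts = file.path(dir, "kalcounts.tsv"),
                genes = file.path(dir, "genes.txt"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fixture$genome),
                              paths$genome)
  write_gtf(fixture$genes, paths$gtf)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$transcriptome), paths$transcriptome)
  utils::write.table(fixture$kalcounts, paths$kalcounts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(fixture$target_gene_ids, paths$genes)
  fixture$paths <- paths
  fixture
}

#' Plant a known defect in a fixture
#'
#' Negative-path fixtures with known ground truth:
#' `"nonspecific_decoy"` appends a verbatim copy of the target gene's
#' first transcript to the transcriptome under a foreign identifier, so
#' every pair amplifying that transcript becomes non-specific;
#' `"zero_expression"` zeroes the target gene's expression rows, so the
#' gene is flagged not expressed and skipped; `"mismatch_primer_site"`
#' substitutes `n_sub` evenly spaced bases inside the window
#' `[site_start, site_start + site_len)` of transcript `transcript_id` in
#' the transcriptome, hiding a primer site from tolerances below
#' `n_sub / site_len`.
#'
#' @param fixture a `locus_fixture`.
#' @param mode one of `"mismatch_primer_site"`, `"nonspecific_decoy"`,
#'   `"zero_expression"`.
#' @param transcript_id,site_start,site_len,n_sub parameters of
#'   `"mismatch_primer_site"` (0-based `site_start`, defaults 20-nt window,
#'   5 substitutions).
#' @return the modified fixture (files are rewritten when the fixture has
#'   `paths`).
#' @export
corrupt <- function(fixture, mode = c("mismatch_primer_site",
                                      "nonspecific_decoy",
                                      "zero_expression"),
                    transcript_id = NULL, site_start = 0L, site_len = 20L,
                    n_sub = 5L) {
  mode <- match.arg(mode)
  if (mode == "nonspecific_decoy") {
    src <- fixture$transcriptome[[1]]
    fixture$transcriptome <- c(fixture$transcriptome,
                               setNames(src, "DECOY_TX1"))
  } else if (mode == "zero_expression") {
    gene <- fixture$genes[[fixture$target_gene_ids[1]]]
    rows <- fixture$kalcounts$target_id %in% names(gene$transcripts)
    fixture$kalcounts[rows, -1] <- 0
  } else {
    if (is.null(transcript_id)) transcript_id <- names(fixture$transcriptome)[1]
    seq <- fixture$transcriptome[[transcript_id]]
    pos <- site_start + round(seq(1L, site_len, length.out = n_sub))
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    swap <- c(A = "C", C = "A", G = "T", T = "G")
    b[pos] <- swap[b[pos]]
    fixture$transcriptome[[transcript_id]] <- paste(b, collapse = "")
  }
  if (!is.null(fixture$paths)) {
    dir <- dirname(fixture$paths$genome)
    fixture$paths <- NULL
    fixture <- write_locus(fixture, dir)
  }
  fixture
}
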