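# Transcript models from GTF + FASTA: parsing, TSL filtering, splice
# junction enumeration, junction probes and prevalence ranking.
#
# Coordinate conventions: GTF is 1-based inclusive on disk; every internal
# interval is 0-based half-open, and transcript-local positions are
# 0-based.  Exons are stored 5'->3' in transcript orientation (descending
# genomic coordinates on the minus strand).

new_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                 exons, tsl = NA_integer_,
                                 transcript_id_full = transcript_id) {
  structure(list(transcript_id = transcript_id,
                 transcript_id_full = transcript_id_full,
                 gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, tsl = tsl, spliced_seq = NULL),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s%s) %d exon(s), TSL %s>\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              ifelse(is.na(x$tsl), "NA", x$tsl)))
  invisible(x)
}

transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start)

# Parse a GENCODE/Ensembl transcript_support_level attribute value; "NA"
# and annotation dialects without the attribute map to NA (they pass the
# TSL filter).
parse_tsl <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_integer_)
  m <- regmatches(x, regexpr("^[0-9]+", trimws(x)))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

#' Parse a GTF into per-gene transcript models
#'
#' Exon records are grouped per transcript and converted from 1-based
#' inclusive GTF coordinates to internal 0-based half-open intervals.
#' Identifiers are matched with version suffixes stripped.  Target genes
#' absent from the annotation produce a warning, not an error.  A
#' non-comment line without the mandatory 9 tab-separated GTF fields stops
#' parsing with an error naming the line; a duplicated exon interval within
#' one transcript is a validation error.
#'
#' @param gtf_path path to a GTF file (GENCODE/Ensembl attribute dialect;
#'   `transcript_support_level` is parsed when present).
#' @param target_gene_ids character vector of gene identifiers to extract.
#' @return named list of `gene_model` objects (one per target gene found),
#'   each with fields `gene_id`, `gene_id_full` and `transcripts`.
#' @export
parse_gtf <- function(gtf_path, target_gene_ids) {
  if (length(target_gene_ids) == 0L)
    stop("target_gene_ids must be non-empty", call. = FALSE)
  lines <- readLines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields, found %d",
                 bad, gtf_path, nf[which(nf != 9L)[1]]), call. = FALSE)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  gid_full <- as.character(md$gene_id)
  tid_full <- as.character(md$transcript_id)
  gid <- strip_version(gid_full)
  tid <- strip_version(tid_full)
  tsl_raw <- if ("transcript_support_level" %in% colnames(md))
    as.character(md$transcript_support_level) else rep(NA_character_, length(gr))

  want <- strip_version(target_gene_ids)
  missing <- target_gene_ids[!(want %in% gid)]
  if (length(missing))
    warning("target gene(s) not found in GTF: ",
            paste(missing, collapse = ", "), call. = FALSE)

  genes <- list()
  for (g in want[want %in% gid]) {
    sel <- gid == g
    txs <- list()
    for (t in unique(tid[sel])) {
      tsel <- sel & tid == t
      start0 <- GenomicRanges::start(gr[tsel]) - 1L   # to 0-based half-open
      end0 <- GenomicRanges::end(gr[tsel])
      if (anyDuplicated(paste(start0, end0)))
        stop(sprintf("duplicate exon for transcript %s", t), call. = FALSE)
      o <- order(start0)
      strand <- as.character(GenomicRanges::strand(gr[tsel]))[1]
      if (strand == "-") o <- rev(o)
      exons <- data.frame(start = start0[o], end = end0[o])
      if (any(exons$end <= exons$start))
        stop(sprintf("invalid exon interval for transcript %s", t),
             call. = FALSE)
      tsl <- parse_tsl(tsl_raw[tsel][1])
      txs[[t]] <- new_transcript_model(
        t, g, as.character(GenomicRanges::seqnames(gr[tsel]))[1], strand,
        exons, tsl, transcript_id_full = tid_full[tsel][1])
    }
    genes[[g]] <- structure(
      list(gene_id = g, gene_id_full = gid_full[sel][1], transcripts = txs,
           template_ids = names(txs), junctions = NULL, junction_occ = NULL),
      class = "gene_model")
  }
  genes
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s: %d transcript(s), %s junction(s)>\n", x$gene_id,
              length(x$transcripts),
              if (is.null(x$junctions)) "?" else nrow(x$junctions)))
  invisible(x)
}

#' Spliced transcript sequence from the genome
#'
#' Concatenates exon sequences in transcript orientation
#' (reverse-complementing minus-strand transcripts).  When a transcriptome
#' FASTA record exists for the transcript it is used as a cross-check: on
#' disagreement a warning is emitted and the FASTA record wins, since the
#' transcriptome file is also the in-silico PCR template.
#'
#' @param transcript a `transcript_model`.
#' @param genome chromosome-indexed `DNAStringSet`.
#' @param transcriptome optional `DNAStringSet` keyed by transcript id.
#' @return spliced sequence as a character string.
#' @export
splice_sequence <- function(transcript, genome, transcriptome = NULL) {
  chrom <- transcript$chrom
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from genome", call. = FALSE)
  chr <- genome[[chrom]]
  ex <- transcript$exons
  if (any(ex$start < 0) || any(ex$end > length(chr)))
    stop(sprintf("exon outside chromosome %s for transcript %s",
                 chrom, transcript$transcript_id), call. = FALSE)
  # genomic order for extraction, then orient
  gex <- ex[order(ex$start), , drop = FALSE]
  parts <- Biostrings::DNAStringSet(
    chr, start = gex$start + 1L, end = gex$end)
  seq <- paste(as.character(parts), collapse = "")
  if (transcript$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  if (!is.null(transcriptome)) {
    key <- transcript$transcript_id
    keys <- strip_version(names(transcriptome))
    hit <- match(key, keys)
    if (!is.na(hit)) {
      fa <- as.character(transcriptome[[hit]])
      if (!identical(fa, seq)) {
        warning(sprintf(
          "spliced sequence of %s disagrees with transcriptome FASTA; using the FASTA record",
          key), call. = FALSE)
        seq <- fa
      }
    }
  }
  seq
}

#' Restrict a gene's design templates by transcript support level
#'
#' Transcripts with TSL above `max_tsl` are removed from the set of design
#' templates but remain part of the gene model (and of the in-silico PCR
#' template set).  Missing TSL (non-GENCODE annotations, or literal "NA")
#' passes the filter.  A gene left without any eligible template is flagged
#' and skipped downstream with a warning.
#'
#' @param gene a `gene_model`.
#' @param max_tsl maximum transcript support level retained (default 3).
#' @return the gene with `template_ids` updated; attribute `no_template`
#'   set when empty.
#' @export
filter_by_tsl <- function(gene, max_tsl = 3L) {
  tsl <- vapply(gene$transcripts, function(t) t$tsl, integer(1))
  keep <- is.na(tsl) | tsl <= max_tsl
  gene$template_ids <- names(gene$transcripts)[keep]
  if (length(gene$template_ids) == 0L) {
    warning("gene ", gene$gene_id,
            ": no transcript with TSL <= ", max_tsl,
            "; no eligible design template", call. = FALSE)
    attr(gene, "no_template") <- TRUE
  }
  gene
}

#' Extract the probe spanning a splice junction
#'
#' Returns the `2*flank`-nt window centred on a transcript-local junction
#' position (`flank` bases each side), or `NA` when the junction lies
#' closer than `flank` bases to a transcript end, in which case it is
#' excluded from probe-based prevalence ranking.
#'
#' @param spliced_seq transcript sequence (character).
#' @param pos 0-based transcript-local index of the first base of the
#'   downstream exon; must satisfy `0 < pos < nchar(spliced_seq)`.
#' @param flank bases kept on each side (default 5, i.e. a 10-nt probe).
#' @return probe string or `NA_character_`.
#' @export
#' @examples
#' junction_probe("AAAAACCCCCGGGGGTTTTT", 10) # "CCCCCGGGGG"
junction_probe <- function(spliced_seq, pos, flank = 5L) {
  n <- nchar(spliced_seq)
  if (pos <= 0L || pos >= n)
    stop("junction position must satisfy 0 < pos < transcript length",
         call. = FALSE)
  if (pos < flank || pos > n - flank) return(NA_character_)
  substr(spliced_seq, pos - flank + 1L, pos + flank)
}

#' Enumerate and deduplicate a gene's splice junctions
#'
#' Each transcript with `e` exons contributes `e - 1` junctions at its
#' cumulative exon-length boundaries; the gene-level list is deduplicated
#' by genomic (donor, acceptor) so the same biological junction seen in
#' several isoforms becomes a single design target.  Junction probes are
#' extracted from the spliced sequences (which must have been computed).
#'
#' @param gene a `gene_model` whose transcripts carry `spliced_seq`.
#' @param flank probe flank passed to [junction_probe()].
#' @return the gene with `junctions` (data.frame: `junction_id`, `chrom`,
#'   `donor`, `acceptor`, `probe`) and `junction_occ` (data.frame:
#'   `junction_id`, `transcript_id`, `pos`) filled in.
#' @export
enumerate_junctions <- function(gene, flank = 5L) {
  occ <- list()
  for (tx in gene$transcripts) {
    e <- nrow(tx$exons)
    if (e < 2L) next
    if (is.null(tx$spliced_seq))
      stop("spliced sequences must be computed before junction enumeration",
           call. = FALSE)
    lens <- tx$exons$end - tx$exons$start
    pos <- cumsum(lens)[-e]                       # 0-based, first base of next exon
    if (tx$strand == "+") {
      donor <- tx$exons$end[-e]; acceptor <- tx$exons$start[-1]
    } else {
      donor <- tx$exons$start[-e]; acceptor <- tx$exons$end[-1]
    }
    occ[[tx$transcript_id]] <- data.frame(
      transcript_id = tx$transcript_id, pos = pos,
      donor = donor, acceptor = acceptor, stringsAsFactors = FALSE)
  }
  if (length(occ) == 0L) {
    gene$junctions <- data.frame(junction_id = character(), chrom = character(),
                                 donor = integer(), acceptor = integer(),
                                 probe = character(), stringsAsFactors = FALSE)
    gene$junction_occ <- data.frame(junction_id = character(),
                                    transcript_id = character(),
                                    pos = integer(), stringsAsFactors = FALSE)
    return(gene)
  }
  occ <- do.call(rbind, c(occ, list(make.row.names = FALSE)))
  key <- paste(occ$donor, occ$acceptor, sep = ":")
  ukey <- unique(key)
  jid <- paste0(gene$gene_id, "_J", seq_along(ukey))
  occ$junction_id <- jid[match(key, ukey)]
  chrom <- gene$transcripts[[1]]$chrom
  probes <- vapply(seq_along(ukey), function(i) {
    rows <- which(key == ukey[i])
    for (r in rows) {                # first transcript giving a full probe
      tx <- gene$transcripts[[occ$transcript_id[r]]]
      p <- junction_probe(tx$spliced_seq, occ$pos[r], flank)
      if (!is.na(p)) return(p)
    }
    NA_character_
  }, character(1))
  first <- match(ukey, key)
  gene$junctions <- data.frame(
    junction_id = jid, chrom = chrom,
    donor = occ$donor[first], acceptor = occ$acceptor[first],
    probe = probes, stringsAsFactors = FALSE)
  gene$junction_occ <- occ[, c("junction_id", "transcript_id", "pos")]
  gene
}

#' Rank a gene's junctions by prevalence across isoforms
#'
#' A junction's prevalence is the number of distinct transcripts of the
#' gene whose spliced sequence contains the junction's 10-nt probe as an
#' exact substring (presence/absence; multiple hits within one transcript
#' count once).  Junctions without a probe are excluded.  Ordering is
#' prevalence descending, then 5'-most genomic donor coordinate, then probe
#' lexicographic, so output is deterministic.
#'
#' @param gene a `gene_model` processed by [enumerate_junctions()].
#' @return data.frame of probed junctions with a `prevalence` column, in
#'   rank order.
#' @export
rank_junctions <- function(gene) {
  j <- gene$junctions
  j <- j[!is.na(j$probe), , drop = FALSE]
  if (nrow(j) == 0L) { j$prevalence <- integer(0); return(j) }
  seqs <- vapply(gene$transcripts, function(t) t$spliced_seq, character(1))
  j$prevalence <- vapply(j$probe, function(p)
    sum(vapply(seqs, function(s) grepl(p, s, fixed = TRUE), logical(1))),
    integer(1), USE.NAMES = FALSE)
  j <- j[order(-j$prevalence, j$donor, j$probe), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Write gene models back to GTF
#'
#' Emits exon features (1-based inclusive coordinates) with `gene_id`,
#' `transcript_id` and, when known, `transcript_support_level` attributes.
#' Round-tripping through [parse_gtf()] reproduces exon intervals, strands
#' and TSLs; also used by the synthetic-locus generator.
#'
#' @param genes list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       g$gene_id_full %||% g$gene_id,
                       tx$transcript_id_full %||% tx$transcript_id)
      if (!is.na(tx$tsl))
        attrs <- paste0(attrs, sprintf(' transcript_support_level "%d";',
                                       tx$tsl))
      lines <- c(lines, sprintf("%s\tisoqpcr\texon\t%d\t%d\t.\t%s\t.\t%s",
                                tx$chrom, ex$start + 1L, ex$end,
                                tx$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load annotation, sequences and junction structure for target genes
#'
#' Convenience wrapper running [parse_gtf()], [splice_sequence()],
#' [filter_by_tsl()] and [enumerate_junctions()] in order.
#'
#' @param gtf_path,genome_path,transcriptome_path input file paths.
#' @param target_gene_ids gene identifiers to extract.
#' @param max_tsl TSL filter threshold.
#' @return named list of fully populated `gene_model` objects.
#' @export
load_annotation <- function(gtf_path, genome_path, transcriptome_path,
                            target_gene_ids, max_tsl = 3L) {
  genome <- read_fasta_named(genome_path)
  txome <- read_fasta_named(transcriptome_path)
  genes <- parse_gtf(gtf_path, target_gene_ids)
  lapply(genes, function(g) {
    g$transcripts <- lapply(g$transcripts, function(tx) {
      tx$spliced_seq <- splice_sequence(tx, genome, txome)
      tx
    })
    g <- filter_by_tsl(g, max_tsl)
    enumerate_junctions(g)
  })
}
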