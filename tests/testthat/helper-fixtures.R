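# Shared, lazily built fixtures and pipeline runs, memoized so the suite
# pays for each expensive end-to-end run once.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

fx_shared <- function() memo("fx_shared", function() {
  dir <- file.path(tempdir(), "fx_shared")
  make_locus(locus_spec(seed = 42L), dir = dir)
})

fx_noshare <- function() memo("fx_noshare", function() {
  dir <- file.path(tempdir(), "fx_noshare")
  make_locus(locus_spec(shared_junction = FALSE, seed = 43L,
                        expression_profile = c(100, 90, 80)), dir = dir)
})

fx_single <- function() memo("fx_single", function() {
  dir <- file.path(tempdir(), "fx_single")
  make_locus(locus_spec(n_isoforms = 1L, seed = 45L), dir = dir)
})

fx_one_expressed <- function() memo("fx_one_expressed", function() {
  dir <- file.path(tempdir(), "fx_one_expressed")
  make_locus(locus_spec(n_isoforms = 4L,
                        expression_profile = c(100, 1, 1, 1),
                        seed = 46L), dir = dir)
})

fixture_config <- function(fx, outdir, ...) {
  run_config(genome = fx$paths$genome, gtf = fx$paths$gtf,
             transcriptome = fx$paths$transcriptome,
             quant_table = fx$paths$kalcounts,
             gene_list = fx$target_gene_ids, outdir = outdir, ...)
}

run_fixture <- function(fx, key, ...) memo(key, function() {
  outdir <- file.path(tempdir(), paste0("out_", key))
  suppressWarnings(suppressMessages(
    run_pipeline(fixture_config(fx, outdir, ...), quiet = TRUE)))
})

res_shared <- function() run_fixture(fx_shared(), "res_shared")
res_noshare <- function() run_fixture(fx_noshare(), "res_noshare",
                                      expression_threshold_percentile = 25)
res_single <- function() run_fixture(fx_single(), "res_single")
res_one_expressed <- function() run_fixture(fx_one_expressed(),
                                            "res_one_expressed")

# Independent naive Hamming site scanner used as the in-silico PCR oracle:
# character-by-character, both strands, no shared code with the package
# internals.
oracle_sites <- function(primer, template, pct) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  match1 <- function(p, t) {
    if (p %in% c("A", "C", "G", "T")) p == t
    else if (p == "N") t %in% c("A", "C", "G", "T")
    else FALSE
  }
  pv <- strsplit(primer, "")[[1]]
  tv <- strsplit(template, "")[[1]]
  m <- length(pv); L <- length(tv)
  allowed <- floor(m * pct / 100)
  out <- list()
  if (L >= m) for (o in 0:(L - m)) {
    # plus strand
    mm <- sum(!mapply(match1, pv, tv[(o + 1):(o + m)]))
    if (mm <= allowed)
      out[[length(out) + 1L]] <- data.frame(strand = "+", start = o,
                                            five_prime_pos = o,
                                            mismatches = mm)
    # minus strand: primer 3'->5' along plus strand, complemented
    rp <- rev(pv)
    mm <- sum(!mapply(function(p, t) match1(p, unname(comp[t])),
                      rp, tv[(o + 1):(o + m)]))
    if (mm <= allowed)
      out[[length(out) + 1L]] <- data.frame(strand = "-", start = o,
                                            five_prime_pos = o + m - 1L,
                                            mismatches = mm)
  }
  if (!length(out))
    return(data.frame(strand = character(), start = integer(),
                      five_prime_pos = integer(), mismatches = integer()))
  df <- do.call(rbind, out)
  df[order(df$five_prime_pos, df$strand), , drop = FALSE]
}

# Oracle amplicon enumeration from oracle sites.
oracle_amplicons <- function(fwd, rev, templates, pct, max_amplicon = 3500) {
  out <- list()
  for (id in names(templates)) {
    for (combo in list(c("fwd", "rev"), c("rev", "fwd"))) {
      p1 <- if (combo[1] == "fwd") fwd else rev
      p2 <- if (combo[2] == "fwd") fwd else rev
      sp <- oracle_sites(p1, templates[[id]], pct)
      sp <- sp[sp$strand == "+", , drop = FALSE]
      sm <- oracle_sites(p2, templates[[id]], pct)
      sm <- sm[sm$strand == "-", , drop = FALSE]
      for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sm))) {
        if (sm$start[j] < sp$start[i] + nchar(p1)) next
        len <- sm$five_prime_pos[j] - sp$five_prime_pos[i] + 1L
        if (len > max_amplicon) next
        out[[length(out) + 1L]] <- data.frame(
          template_id = id, fwd_5p = sp$five_prime_pos[i],
          rev_5p = sm$five_prime_pos[j], length = len)
      }
    }
  }
  if (!length(out))
    return(data.frame(template_id = character(), fwd_5p = integer(),
                      rev_5p = integer(), length = integer()))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$template_id, df$fwd_5p, df$rev_5p), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
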