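# Sequence-level primer physics: GC content, nearest-neighbor melting
# temperature, homopolymer runs, self/pair complementarity and hairpin
# screening.  Everything here is a pure function of the sequence(s).

# Unified nearest-neighbor duplex parameters (Allawi & SantaLucia 1997):
# dH in kcal/mol, dS in cal/(K*mol), one entry per 5'->3' dinucleotide step.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0, TT = -7.9)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9, TT = -22.2)
# Duplex-initiation terms per terminal base pair.
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

#' GC content of an oligonucleotide
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @return percentage of G+C bases, in `[0, 100]`.
#' @export
#' @examples
#' gc_percent("ATGC") # 50
gc_percent <- function(seq) {
  check_dna(seq, "primer")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor model:
#' `Tm = dH / (dS + R ln(C_eff)) - 273.15`, with the dinucleotide dH/dS
#' table above, per-terminus initiation terms, and the entropy salt
#' correction `0.368 (N-1) ln[Na+]`.  `C_eff` is `C/4` for a
#' non-self-complementary oligo annealing to its exact complement and `C/2`
#' (plus the `dS = -1.4` symmetry term) for palindromic oligos.
#'
#' @param seq DNA string over `{A,C,G,T}`, length >= 8.
#' @param oligo_conc total oligonucleotide concentration in mol/L.
#' @param monovalent_salt monovalent cation concentration in mol/L.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACCTGGCTATCCGTGATCAA")
melting_temperature <- function(seq, oligo_conc = 50e-9,
                                monovalent_salt = 50e-3) {
  check_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 8) stop("Tm model requires length >= 8", call. = FALSE)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[b[1]] + NN_INIT_DH[b[n]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[b[1]] + NN_INIT_DS[b[n]]
  selfcomp <- identical(revcomp(seq), seq)
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(monovalent_salt)
  c_eff <- if (selfcomp) oligo_conc / 2 else oligo_conc / 4
  unname(1000 * dh / (ds + 1.987 * log(c_eff)) - 273.15)
}

#' Longest homopolymer run
#'
#' @param seq non-empty DNA string.
#' @return length of the longest run of a single repeated base.
#' @export
max_homopolymer_run <- function(seq) {
  check_dna(seq, "primer", allow = "ACGTN")
  max(rle(strsplit(seq, "", fixed = TRUE)[[1]])$lengths)
}

#' Ungapped complementarity between two oligos
#'
#' Slides `b` (read 3'->5', i.e. its reverse complement) along `a` at every
#' ungapped offset and records the longest contiguous complementary run
#' anywhere (`score`) and the longest run anchored at the 3' terminus of
#' either primer (`end_run`).  Self-complementarity is
#' `complementarity(a, a)`.  The metric is a run length, not an alignment
#' score, so it is symmetric in its arguments.
#'
#' @param a,b DNA strings over `{A,C,G,T}` (5'->3').
#' @return list with integer elements `score` and `end_run`.
#' @export
#' @examples
#' complementarity("ACGTACGT", revcomp("ACGTACGT"))$score # 8
complementarity <- function(a, b) {
  check_dna(a, "primer a"); check_dna(b, "primer b")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  # rc(b)[k] pairs a[i] when aligned antiparallel; rc index 1 is b's 3' end.
  rv <- strsplit(revcomp(b), "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(rv)
  score <- 0L; end_run <- 0L
  for (off in seq(-(nb - 1L), na - 1L)) {
    ia <- max(1L, off + 1L):min(na, off + nb)
    if (length(ia) == 0L) next
    ib <- ia - off
    m <- av[ia] == rv[ib]
    r <- rle(m)
    runs <- r$lengths[r$values]
    if (length(runs)) score <- max(score, max(runs))
    # run touching a's 3' terminus (position na of a)
    if (ia[length(ia)] == na && r$values[length(r$values)])
      end_run <- max(end_run, r$lengths[length(r$lengths)])
    # run touching b's 3' terminus (rc(b) index 1)
    if (ib[1L] == 1L && r$values[1L])
      end_run <- max(end_run, r$lengths[1L])
  }
  list(score = as.integer(score), end_run = as.integer(end_run))
}

#' Hairpin screen by exact-complement stem search
#'
#' Flags a sequence when two in-sequence segments of length >= `min_stem`,
#' separated by a loop of >= `min_loop` bases, are exact reverse
#' complements.  A stem of length > `min_stem` always contains a
#' `min_stem`-length stem, so only that length is searched.
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param min_stem minimum paired stem length (nt).
#' @param min_loop minimum unpaired loop length (nt).
#' @return logical flag.
#' @export
hairpin_flag <- function(seq, min_stem = 4L, min_loop = 3L) {
  check_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 2L * min_stem + min_loop) return(FALSE)
  kmers <- substring(seq, 1:(n - min_stem + 1L), min_stem:n)
  rc <- revcomp(kmers)
  for (i in seq_along(kmers)) {
    j0 <- i + min_stem + min_loop
    if (j0 > length(kmers)) break
    if (any(kmers[j0:length(kmers)] == rc[i])) return(TRUE)
  }
  FALSE
}

#' All screening statistics for one oligo
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @inheritParams melting_temperature
#' @inheritParams hairpin_flag
#' @return list of class `oligo_stats`: `seq`, `len`, `gc_percent`,
#'   `tm_celsius`, `max_run`, `self_comp_score`, `self_end_run`,
#'   `hairpin_flag`.
#' @export
oligo_stats <- function(seq, oligo_conc = 50e-9, monovalent_salt = 50e-3,
                        min_stem = 4L, min_loop = 3L) {
  sc <- complementarity(seq, seq)
  structure(list(
    seq = seq, len = nchar(seq),
    gc_percent = gc_percent(seq),
    tm_celsius = melting_temperature(seq, oligo_conc, monovalent_salt),
    max_run = max_homopolymer_run(seq),
    self_comp_score = sc$score, self_end_run = sc$end_run,
    hairpin_flag = hairpin_flag(seq, min_stem, min_loop)
  ), class = "oligo_stats")
}
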