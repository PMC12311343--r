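#' @importFrom stats quantile median setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip Ensembl-style version suffixes from identifiers
#'
#' Removes a trailing `.N` (e.g. `ENST00000456328.2` -> `ENST00000456328`)
#' so that GTF, transcriptome FASTA and quantification-table identifiers can
#' be matched even when their version annotations disagree.  The original
#' strings are kept by callers for output.
#'
#' @param ids character vector of identifiers.
#' @return character vector with version suffixes removed.
#' @export
strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Reverse-complement a DNA string
#'
#' Plain-character convenience wrapper used throughout for primer-sized
#' sequences; IUPAC ambiguity codes are complemented correctly.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Internal: validate a DNA string over a strict alphabet, error otherwise.
check_dna <- function(seq, what = "sequence", allow = "ACGT") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
  bad <- setdiff(strsplit(seq, "", fixed = TRUE)[[1]],
                 strsplit(allow, "", fixed = TRUE)[[1]])
  if (length(bad))
    stop(what, " contains characters outside {", allow, "}: ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  invisible(seq)
}

# Internal: read FASTA keyed by the first whitespace-delimited token.
read_fasta_named <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ss
}

# Internal: deterministic number formatting for report tables.
fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
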