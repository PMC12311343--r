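# Isoform quantification table parsing and expressed-isoform classification
# by a per-gene quantile threshold.

#' Parse an isoform quantification table
#'
#' Reads a tab-separated table whose first column holds transcript
#' identifiers and whose remaining columns hold one non-negative numeric
#' abundance (typically TPM) per sample.  Identifiers are matched with
#' Ensembl version suffixes stripped; the original strings are preserved
#' for output.  A table populated by hand with arbitrary values is accepted
#' unchanged, which lets users force the prioritization of specific
#' isoform sets.
#'
#' @param path path to the TSV file (header row required).
#' @param aggregate `"mean"` (default) or `"median"` across samples.
#' @return object of class `expression_table`: list with `ids` (normalized),
#'   `ids_full` (as read), `matrix` (transcripts x samples) and `mean_tpm`
#'   (named by normalized id).
#' @export
parse_quant_table <- function(path, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("quantification table is empty or has no sample columns",
         call. = FALSE)
  ids_full <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
    bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric expression value at row %d, column %d",
                 bad[1, 1], bad[1, 2] + 1L), call. = FALSE)
  }
  if (anyNA(mat) || any(!is.finite(mat)) || any(mat < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  ids <- strip_version(ids_full)
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in quantification table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","), call. = FALSE)
  agg <- if (aggregate == "mean") rowMeans(mat) else apply(mat, 1, median)
  structure(list(ids = ids, ids_full = ids_full, matrix = mat,
                 mean_tpm = setNames(as.numeric(agg), ids)),
            class = "expression_table")
}

#' Classify a gene's isoforms as expressed by a quantile threshold
#'
#' The cutoff is the linear-interpolation quantile (index `h = p/100 *
#' (n-1)` between order statistics, i.e. R's type-7 default) of the gene's
#' isoform abundances; an isoform is expressed when its abundance is
#' strictly greater than the cutoff, so a threshold of 75 keeps the top 25%
#' of distinctly-expressed isoforms.  Two degenerate cases are handled
#' explicitly: a gene whose isoforms are all zero is flagged not expressed
#' (callers skip it), and when the strict comparison leaves no isoform
#' above the cutoff but the gene has positive expression (e.g. all isoforms
#' tied, or a single isoform), every positive-abundance isoform is marked
#' expressed so that quantifiably expressed genes stay designable.
#'
#' @param mean_tpms named numeric vector, one abundance per isoform of one
#'   gene.
#' @param threshold_percentile quantile threshold in `[0, 100]`.
#' @return data.frame with columns `transcript_id`, `mean_tpm`, `expressed`,
#'   `gene_quantile_cutoff`; attribute `not_expressed` is `TRUE` when all
#'   abundances are zero, and attribute `fallback` is `TRUE` when the
#'   all-positive fallback fired.
#' @export
#' @examples
#' classify_expressed(c(t1 = 0, t2 = 0, t3 = 0, t4 = 10), 75)
classify_expressed <- function(mean_tpms, threshold_percentile = 75) {
  if (length(mean_tpms) == 0L) stop("no isoforms supplied", call. = FALSE)
  if (threshold_percentile < 0 || threshold_percentile > 100)
    stop("threshold_percentile must be in [0,100]", call. = FALSE)
  if (is.null(names(mean_tpms)))
    names(mean_tpms) <- paste0("iso", seq_along(mean_tpms))
  cutoff <- unname(quantile(mean_tpms, threshold_percentile / 100,
                            type = 7, names = FALSE))
  expressed <- mean_tpms > cutoff
  not_expressed <- all(mean_tpms == 0)
  fallback <- FALSE
  if (!not_expressed && !any(expressed)) {
    expressed <- mean_tpms > 0
    fallback <- TRUE
  }
  structure(
    data.frame(transcript_id = names(mean_tpms),
               mean_tpm = unname(mean_tpms),
               expressed = unname(expressed) & !not_expressed,
               gene_quantile_cutoff = cutoff,
               row.names = NULL, stringsAsFactors = FALSE),
    not_expressed = not_expressed, fallback = fallback)
}
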