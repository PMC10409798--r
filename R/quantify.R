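# CPM normalization, isoform proportions, capture enrichment metrics, and
# spike-in detection limits.

#' Counts per million mapped reads
#'
#' `CPM = count / mapped_total * 1e6`, using each sample's total mapped
#' reads (not the column sum), so column sums are at most 1e6 and equal
#' `1e6 * assigned/mapped`.
#'
#' @param cm a [count_matrix()].
#' @return Numeric matrix (isoforms x samples) of CPM values; attribute
#'   `"gene_ids"` carries the isoform -> gene map.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  bad <- names(cm$mapped_totals)[cm$mapped_totals <= 0]
  if (length(bad))
    stop("mapped_total is zero for sample(s): ", paste(bad, collapse = ", "))
  ab <- sweep(cm$counts, 2L, cm$mapped_totals, "/") * 1e6
  attr(ab, "gene_ids") <- cm$gene_ids
  ab
}

#' Gene-level CPM
#'
#' Gene CPM is the sum of CPM values over all isoforms discovered for the
#' gene.
#'
#' @param ab CPM matrix from [cpm()].
#' @param gene_ids isoform -> gene map (default: the matrix attribute).
#' @return Numeric matrix, genes x samples.
#' @export
gene_cpm <- function(ab, gene_ids = attr(ab, "gene_ids")) {
  if (is.null(gene_ids)) stop("gene_ids required")
  rowsum(ab, group = gene_ids[rownames(ab)], reorder = FALSE)
}

#' Isoform proportions
#'
#' Each isoform's CPM divided by its gene's CPM. Where the gene CPM is zero
#' the proportion is undefined (`NA`), not zero; defined proportions of one
#' gene in one sample sum to 1.
#'
#' @inheritParams gene_cpm
#' @return Numeric matrix (isoforms x samples) in `[0, 1]` with `NA` for
#'   unexpressed genes; attribute `"gene_ids"` preserved.
#' @export
isoform_proportion <- function(ab, gene_ids = attr(ab, "gene_ids")) {
  g <- gene_cpm(ab, gene_ids)
  denom <- g[gene_ids[rownames(ab)], , drop = FALSE]
  pr <- ab / denom
  pr[denom == 0] <- NA_real_
  attr(pr, "gene_ids") <- gene_ids
  pr
}

#' On-target rate of an alignment summary
#'
#' Number of reads mapped to target genes divided by total mapped reads,
#' with both numerator and denominator restricted to mapping quality
#' `>= min_mapq`.
#'
#' @param aln data frame with a `mapq` column and either a logical `target`
#'   column or a `gene` column (paired with `targets`).
#' @param targets optional character vector of target gene ids, used when
#'   `aln` carries a `gene` column.
#' @param min_mapq mapping-quality filter (default 1).
#' @return The on-target fraction.
#' @export
on_target_rate <- function(aln, targets = NULL, min_mapq = 1L) {
  keep <- aln$mapq >= min_mapq
  if (!any(keep)) stop("no reads with mapq >= ", min_mapq)
  flag <- if (!is.null(targets) && !is.null(aln$gene))
    aln$gene %in% targets else aln$target
  if (is.null(flag)) stop("alignment summary needs a target flag or gene column")
  mean(flag[keep])
}

#' Capture fold enrichment
#'
#' On-target rate of the capture library divided by that of the non-capture
#' control.
#'
#' @param rate_capture,rate_control on-target rates; `rate_control > 0`.
#' @return The fold enrichment.
#' @export
fold_enrichment <- function(rate_capture, rate_control) {
  if (rate_control <= 0) stop("control on-target rate must be > 0")
  rate_capture / rate_control
}

#' Consistent spike-in detection limit
#'
#' The smallest ladder concentration c such that every evaluated transcript
#' with concentration `>= c` has at least `min_reads` raw reads in every
#' replicate (detection "consistently across replicates"). Returns `Inf` if
#' no concentration qualifies.
#'
#' @param counts integer matrix of raw reads, spike-in transcripts x
#'   replicates (rownames are transcript ids).
#' @param ladder spike-in table with `transcript_id`, `concentration`; only
#'   transcripts present in both are evaluated.
#' @param min_reads per-replicate read threshold (default 2).
#' @return A concentration in the ladder's units, or `Inf`.
#' @export
detection_limit <- function(counts, ladder, min_reads = 2L) {
  ids <- intersect(rownames(counts), ladder$transcript_id)
  if (length(ids) == 0L) stop("no spike-in transcripts to evaluate")
  conc <- setNames(ladder$concentration, ladder$transcript_id)[ids]
  ok <- apply(counts[ids, , drop = FALSE] >= min_reads, 1L, all)
  for (c0 in sort(unique(conc))) {
    if (all(ok[conc >= c0])) return(c0)
  }
  Inf
}

#' Ratio of two positive quantities
#' @param a numerator.
#' @param b denominator (> 0).
#' @return `a / b`.
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be > 0")
  a / b
}

#' Pearson and Spearman concordance
#'
#' Standard correlation pair between two abundance vectors, optionally on
#' the `log10(x + eps)` scale (the 1-CPM pseudo-count used for log-scale
#' abundance comparisons).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param log compute on `log10(. + eps)` scale.
#' @param eps pseudo-count for the log scale (default 1).
#' @return Named numeric vector `c(pearson =, spearman =)`.
#' @export
concordance <- function(x, y, log = FALSE, eps = 1) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (log) { x <- log10(x + eps); y <- log10(y + eps) }
  c(pearson = cor(x, y, method = "pearson"),
    spearman = cor(x, y, method = "spearman"))
}
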