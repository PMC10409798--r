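#' Genome interval constructor
#'
#' Intervals are 0-based half-open `[start, end)` on a named chromosome, the
#' convention used throughout the package (GTF I/O converts to/from the
#' 1-based inclusive GTF convention; BED emission is direct).
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row data frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genome_interval <- function(chrom, start, end, strand = "+") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!all(start < end)) stop("interval start must be < end")
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Transcript model
#'
#' A transcript is an ordered set of exons on one chromosome and strand, with
#' a canonical flag (at most one isoform per gene) and an annotation status
#' used to route transcripts through NMD prediction:
#' `"annotated_basic_or_nmd"` (full-length annotated coding or annotated
#' NMD-target: the annotated status is kept), `"annotated_other"`, or
#' `"novel"` (both are sent to the ORF scan).
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends parallel integer vectors of exon coordinates, 0-based
#'   half-open. Exons may be given in any order; they are sorted by genomic
#'   start and must not overlap.
#' @param is_canonical logical flag.
#' @param annotation_status one of `"annotated_basic_or_nmd"`,
#'   `"annotated_other"`, `"novel"`.
#' @return An object of class `transcript_model`.
#' @examples
#' t1 <- transcript_model("tx1", "g1", "chr1", "+", c(100, 300), c(200, 400))
#' splice_junctions(t1)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             starts, ends, is_canonical = FALSE,
                             annotation_status = "novel") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("starts/ends must be parallel, non-empty vectors")
  starts <- as.integer(starts); ends <- as.integer(ends)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts >= ends))
    stop(sprintf("transcript %s: exon with start >= end", transcript_id))
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop(sprintf("transcript %s: overlapping exons", transcript_id))
  annotation_status <- match.arg(annotation_status,
    c("novel", "annotated_basic_or_nmd", "annotated_other"))
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand,
    exons = data.frame(start = starts, end = ends),
    is_canonical = isTRUE(is_canonical),
    annotation_status = annotation_status
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s, %d exon(s), %d nt%s [%s]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x),
              if (x$is_canonical) ", canonical" else "",
              x$annotation_status))
  invisible(x)
}

#' Spliced length of a transcript
#' @param t a [transcript_model()].
#' @return Integer, the sum of exon lengths.
#' @export
transcript_length <- function(t) sum(t$exons$end - t$exons$start)

#' Introns of a transcript
#'
#' Returns the gaps between consecutive exons as 0-based half-open intervals
#' in genomic order. A transcript with n exons has n - 1 introns; single-exon
#' transcripts return an empty frame.
#'
#' @param t a [transcript_model()].
#' @return Data frame with columns `start`, `end` (possibly zero rows).
#' @export
splice_junctions <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exons$end[-n], end = t$exons$start[-1L])
}

#' Group transcript models by gene
#' @param models list of [transcript_model()] objects.
#' @return Named list of lists, one entry per gene_id.
#' @export
models_by_gene <- function(models) {
  split(models, vapply(models, function(m) m$gene_id, character(1)))
}

#' Canonical isoform of a gene
#' @param gene_models list of [transcript_model()] for one gene.
#' @return The canonical model, or `NULL` if none is flagged.
#' @export
canonical_of <- function(gene_models) {
  flags <- vapply(gene_models, function(m) m$is_canonical, logical(1))
  if (sum(flags) > 1L) stop("more than one canonical isoform flagged for gene")
  if (!any(flags)) return(NULL)
  gene_models[[which(flags)]]
}

# transcript-orientation exon lengths (5' -> 3')
exon_lengths_tx <- function(t) {
  lens <- t$exons$end - t$exons$start
  if (t$strand == "-") rev(lens) else lens
}

#' Splice-junction positions in transcript coordinates
#'
#' Offsets (0-based, 5' to 3') of each exon-exon boundary in the spliced
#' transcript; the last element is the 3'-most junction used by the 50-nt
#' NMD rule.
#'
#' @param t a [transcript_model()].
#' @return Integer vector of length `n_exons - 1` (empty for single exons).
#' @export
junction_tx_positions <- function(t) {
  lens <- exon_lengths_tx(t)
  if (length(lens) < 2L) return(integer(0))
  cumsum(lens)[-length(lens)]
}
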