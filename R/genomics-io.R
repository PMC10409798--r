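#' Read transcript models from a GTF file
#'
#' Parses a GENCODE-dialect GTF (via rtracklayer) into a list of
#' [transcript_model()] objects. Exon records are grouped by `transcript_id`,
#' sorted, and overlapping exons merged. The canonical flag is read from a
#' `canonical` attribute; annotation status from an `annotation_status`
#' attribute, or, failing that, derived from `tag "basic"` +
#' `transcript_type` (protein_coding / nonsense_mediated_decay =>
#' `annotated_basic_or_nmd`). Absent attributes default to non-canonical /
#' `novel`, so synthetic fixtures are self-contained.
#'
#' @param path path to a GTF file.
#' @return Named list of [transcript_model()] in file order.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
      anyNA(gr$transcript_id) || anyNA(gr$gene_id))
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id, gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  df$canonical <- if (!is.null(gr$canonical))
    tolower(as.character(gr$canonical)) %in% c("true", "1", "yes") else FALSE
  df$status <- if (!is.null(gr$annotation_status)) {
    as.character(gr$annotation_status)
  } else if (!is.null(gr$tag) && !is.null(gr$transcript_type)) {
    ifelse(!is.na(gr$tag) & gr$tag == "basic" &
             gr$transcript_type %in% c("protein_coding",
                                       "nonsense_mediated_decay"),
           "annotated_basic_or_nmd", "annotated_other")
  } else "novel"
  txs <- unique(df$transcript_id)
  models <- lapply(txs, function(tx) {
    e <- df[df$transcript_id == tx, ]
    # merge book-ended/overlapping exon records
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    transcript_model(tx, e$gene_id[1L], e$chrom[1L], e$strand[1L],
                     IRanges::start(ir) - 1L, IRanges::end(ir),
                     is_canonical = e$canonical[1L],
                     annotation_status = e$status[1L] %||% "novel")
  })
  names(models) <- txs
  models
}

#' Write transcript models to a GTF file
#'
#' Emits transcript and exon records in GENCODE dialect with `gene_id`,
#' `transcript_id`, `canonical`, and `annotation_status` attributes, so that
#' `read_gtf(write_gtf(models))` reproduces the models exactly.
#'
#' @param models list of [transcript_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; canonical "%s"; annotation_status "%s";',
      m$gene_id, m$transcript_id, if (m$is_canonical) "TRUE" else "FALSE",
      m$annotation_status)
    tx_line <- paste(m$chrom, "isopanel", "transcript",
                     min(m$exons$start) + 1L, max(m$exons$end), ".", m$strand,
                     ".", attrs, sep = "\t")
    ex_lines <- paste(m$chrom, "isopanel", "exon",
                      m$exons$start + 1L, m$exons$end, ".", m$strand, ".",
                      attrs, sep = "\t")
    c(tx_line, ex_lines)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Extract the spliced sequence of a transcript
#'
#' Concatenates the exon sequences in transcript (5' to 3') order; on the
#' minus strand the concatenated plus-strand sequence is reverse-complemented.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param t a [transcript_model()].
#' @return The spliced nucleotide sequence as a character string; its length
#'   equals [transcript_length()].
#' @export
spliced_sequence <- function(genome, t) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!t$chrom %in% names(genome))
    stop("chromosome not found in genome: ", t$chrom)
  chrom <- genome[[t$chrom]]
  if (max(t$exons$end) > length(chrom))
    stop("exon beyond chromosome bounds on ", t$chrom)
  parts <- Biostrings::DNAStringSet(chrom, start = t$exons$start + 1L,
                                    end = t$exons$end)
  s <- unlist(parts)
  if (t$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Isoform count matrix container
#'
#' Holds non-negative per-isoform read counts across samples together with
#' the per-sample total mapped read counts and the sample -> cell line ->
#' subtype maps required by the proportion-based tests.
#'
#' @param counts numeric matrix, isoforms x samples, with rownames
#'   (isoform ids) and colnames (sample ids).
#' @param gene_ids character vector parallel to rows mapping each isoform to
#'   its gene.
#' @param mapped_totals named numeric vector of total mapped reads per
#'   sample; must be `>=` the corresponding column sums.
#' @param replicate_map named character vector: sample id -> cell line.
#' @param subtype_map optional named character vector: cell line -> subtype.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, mapped_totals, replicate_map,
                         subtype_map = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids must be parallel to count rows")
  samples <- colnames(counts)
  if (!all(samples %in% names(mapped_totals)))
    stop("every sample needs a mapped_totals entry")
  mapped_totals <- mapped_totals[samples]
  if (any(mapped_totals + 1e-9 < colSums(counts)))
    stop("mapped_totals must be >= assigned counts for every sample")
  if (!all(samples %in% names(replicate_map)))
    stop("every sample must appear in replicate_map")
  structure(list(counts = counts, gene_ids = setNames(gene_ids,
                                                      rownames(counts)),
                 mapped_totals = mapped_totals,
                 replicate_map = replicate_map[samples],
                 subtype_map = subtype_map),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d isoforms (%d genes) x %d samples, %d cell line(s)\n",
              nrow(x$counts), length(unique(x$gene_ids)), ncol(x$counts),
              length(unique(x$replicate_map))))
  invisible(x)
}

#' Read a count matrix and its sidecar tables from TSV files
#'
#' The counts TSV carries `isoform_id`, `gene_id`, then one column per
#' sample; the totals TSV has `sample_id`, `mapped_total`; the sample sheet
#' has `sample_id`, `cell_line`, `subtype`, `replicate`.
#'
#' @param counts_path,totals_path,samples_path file paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, totals_path, samples_path) {
  ct <- read.delim(counts_path, check.names = FALSE)
  if (!all(c("isoform_id", "gene_id") %in% names(ct)[1:2]))
    stop("counts TSV must begin with isoform_id, gene_id columns")
  m <- as.matrix(ct[, -(1:2), drop = FALSE])
  rownames(m) <- ct$isoform_id
  tot <- read.delim(totals_path)
  sheet <- read.delim(samples_path)
  count_matrix(m, ct$gene_id,
               setNames(tot$mapped_total, tot$sample_id),
               setNames(sheet$cell_line, sheet$sample_id),
               subtype_map = if ("subtype" %in% names(sheet))
                 setNames(sheet$subtype, sheet$cell_line)[
                   !duplicated(sheet$cell_line)] else NULL)
}

#' Write a count matrix and its sidecar tables to TSV files
#' @param cm a [count_matrix()].
#' @param counts_path,totals_path,samples_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_count_matrix <- function(cm, counts_path, totals_path, samples_path) {
  out <- data.frame(isoform_id = rownames(cm$counts),
                    gene_id = unname(cm$gene_ids), cm$counts,
                    check.names = FALSE)
  write.table(out, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cm$mapped_totals),
                         mapped_total = unname(cm$mapped_totals)),
              totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- unname(cm$replicate_map)
  sheet <- data.frame(sample_id = names(cm$replicate_map), cell_line = lines,
                      subtype = if (!is.null(cm$subtype_map))
                        unname(cm$subtype_map[lines]) else NA,
                      replicate = stats::ave(seq_along(lines), lines,
                                             FUN = seq_along))
  write.table(sheet, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, totals_path, samples_path))
}

#' Write intervals as BED6
#' @param df data frame with columns `chrom`, `start`, `end`, `name`,
#'   optional `score`, `strand` (0-based half-open, BED-native).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(df$chrom, df$start, df$end,
                    df$name %||% ".", df$score %||% 0L, df$strand %||% "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
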