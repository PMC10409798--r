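# Fixture builders shared across test files; everything is constructed in
# code at test time.

# two-isoform cassette-exon gene: inclusion isoform carries both inclusion
# junctions, skipping isoform the bridging junction
cassette_models <- function(gene = "gX", chrom = "chrX") {
  list(
    inc = transcript_model(paste0(gene, "_inc"), gene, chrom, "+",
                           c(0, 200, 400), c(100, 300, 500),
                           is_canonical = TRUE),
    skp = transcript_model(paste0(gene, "_skp"), gene, chrom, "+",
                           c(0, 400), c(100, 500)))
}

cassette_event <- function(gene = "gX", chrom = "chrX") {
  es_event("ev1", gene, chrom, "+", 100, 200, 300, 400)
}

# minimal CPM matrix for given isoform rows
toy_ab <- function(values, isoforms, samples = NULL, gene_ids = NULL) {
  m <- matrix(values, nrow = length(isoforms))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(isoforms, samples)
  attr(m, "gene_ids") <- setNames(gene_ids %||% rep("gX", length(isoforms)),
                                  isoforms)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# count_matrix from an explicit counts matrix, 2 replicates per line
toy_count_matrix <- function(counts, gene_ids, subtypes = NULL) {
  samples <- colnames(counts)
  lines <- sub("_r[0-9]+$", "", samples)
  count_matrix(counts, gene_ids,
               mapped_totals = setNames(pmax(colSums(counts), 1), samples),
               replicate_map = setNames(lines, samples),
               subtype_map = subtypes)
}

# transcript + genome whose spliced sequence is exactly `parts` joined
# across exons of the given lengths (introns are 50-nt C/G filler that can
# form neither ATG nor a stop codon)
tx_with_sequence <- function(spliced, exon_lens, chrom = "chrT",
                             tx_id = "txT", gene = "gT",
                             status = "novel") {
  stopifnot(sum(exon_lens) == nchar(spliced))
  filler <- strrep("C", 50)
  pieces <- character(0); starts <- integer(0); ends <- integer(0)
  pos <- 0L; off <- 0L
  for (k in seq_along(exon_lens)) {
    exon_seq <- substr(spliced, off + 1L, off + exon_lens[k])
    pieces <- c(pieces, exon_seq, filler)
    starts <- c(starts, pos)
    ends <- c(ends, pos + exon_lens[k])
    pos <- pos + exon_lens[k] + 50L
    off <- off + exon_lens[k]
  }
  genome <- setNames(paste0(pieces, collapse = ""), chrom)
  t <- transcript_model(tx_id, gene, chrom, "+", starts, ends,
                        annotation_status = status)
  list(t = t, genome = genome)
}

# null simulation design: no planted effects
null_design <- function(n_genes = 50L, seed = 1L, ...) {
  genes <- lapply(seq_len(n_genes), function(i)
    sim_gene(sprintf("gene%03d", i)))
  sim_design(genes, seed = seed, ...)
}
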