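# 1x-tiling capture-probe template design over exonic unions, adapter
# assembly, and probe-yield / reaction-capacity arithmetic.

#' Universal adapter pair for probe synthesis oligos
#'
#' The 150-nt oligo templates carry a 3' 30-nt universal primer binding
#' sequence; amplification is primed by its reverse complement (the
#' RC-oligo). The defaults are the published pair, and
#' [validate_adapters()] asserts the reverse-complement identity.
#'
#' @param adapter 30-nt adapter appended to each 120-nt target sequence.
#' @param rc_primer 30-nt amplification primer; must be the reverse
#'   complement of `adapter`.
#' @return List of class `adapter_pair`.
#' @export
adapter_pair <- function(adapter = "CGAAGAGCCCTATAGTGAGTCGTATTAGAA",
                         rc_primer = "TTCTAATACGACTCACTATAGGGCTCTTCG") {
  structure(list(adapter = adapter, rc_primer = rc_primer),
            class = "adapter_pair")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Validate an adapter pair
#' @param adapters an [adapter_pair()].
#' @return `TRUE` invisibly; errors if lengths are wrong or the RC-oligo is
#'   not the reverse complement of the adapter.
#' @export
validate_adapters <- function(adapters) {
  if (nchar(adapters$adapter) != 30L || nchar(adapters$rc_primer) != 30L)
    stop("adapter and RC-oligo must both be 30 nt")
  if (revcomp(adapters$adapter) != adapters$rc_primer)
    stop("RC-oligo is not the reverse complement of the adapter")
  invisible(TRUE)
}

#' Exonic union of a gene's transcripts
#'
#' Union of all exon intervals over all isoforms, with overlapping or
#' book-ended intervals merged (the target space for probe tiling across
#' all annotated exons, including UTRs).
#'
#' @param gene_models list of [transcript_model()] for one gene.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
exonic_union <- function(gene_models) {
  stopifnot(length(gene_models) >= 1L)
  chrom <- gene_models[[1L]]$chrom
  starts <- unlist(lapply(gene_models, function(m) m$exons$start))
  ends <- unlist(lapply(gene_models, function(m) m$exons$end))
  ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir))
}

#' Tile probe target windows over exonic blocks at 1x density
#'
#' Per block of length L: if `L >= probe_len`, abutting windows step by
#' `probe_len` from the block start, and the final window is re-anchored to
#' end at the block end (overlapping its predecessor) so every base is
#' covered at most twice; if `min_block <= L < probe_len`, a single window
#' of `probe_len` is centered on the block, extending into flanking
#' genomic sequence; blocks shorter than `min_block` are skipped with a
#' warning.
#'
#' @param blocks data frame from [exonic_union()].
#' @param probe_len window length (default 120 nt).
#' @param min_block minimum block length to receive a probe (default 40 nt).
#' @return Data frame `chrom`, `start`, `end`, `block` (index); attribute
#'   `"skipped"` lists skipped block indices.
#' @export
tile_probes <- function(blocks, probe_len = 120L, min_block = 40L) {
  stopifnot(probe_len > 0L)
  out <- list(); skipped <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    s <- blocks$start[b]; e <- blocks$end[b]; L <- e - s
    if (L < min_block) {
      warning(sprintf("block %d (%d nt) shorter than %d nt, skipped",
                      b, L, min_block))
      skipped <- c(skipped, b)
      next
    }
    if (L >= probe_len) {
      starts <- seq.int(s, e - probe_len, by = probe_len)
      if (max(starts) + probe_len < e) starts <- c(starts, e - probe_len)
    } else {
      starts <- max(0L, s - (probe_len - L) %/% 2L)
    }
    out[[length(out) + 1L]] <- data.frame(chrom = blocks$chrom[b],
                                          start = starts,
                                          end = starts + probe_len,
                                          block = b)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               block = integer(0))
  attr(res, "skipped") <- skipped
  res
}

#' Assemble a 150-nt synthesis oligo
#'
#' `oligo = 120-nt target sequence + 30-nt adapter` (adapter at the 3' end).
#'
#' @param target_seq 120-nt sequence over ACGT.
#' @param adapters an [adapter_pair()] (validated).
#' @return The 150-nt oligo string.
#' @export
build_oligo <- function(target_seq, adapters = adapter_pair()) {
  validate_adapters(adapters)
  if (nchar(target_seq) != 120L) stop("target sequence must be 120 nt")
  if (grepl("[^ACGTacgt]", target_seq))
    stop("target sequence must be over ACGT")
  paste0(toupper(target_seq), adapters$adapter)
}

#' Design capture probes for a set of genes
#'
#' Tiling windows over each gene's exonic union, target sequences extracted
#' from the genome (transcribed-sense strand), and 150-nt synthesis oligos
#' with the universal adapter.
#'
#' @param models named list of [transcript_model()].
#' @param genome chromosome sequences (see [spliced_sequence()]).
#' @param genes gene ids to design for (default: all).
#' @param adapters an [adapter_pair()].
#' @param probe_len,min_block tiling parameters (see [tile_probes()]).
#' @param both_strands also emit reverse-complement probes.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`, `name`,
#'   `target_seq`, `oligo_seq`.
#' @export
design_probes <- function(models, genome, genes = NULL,
                          adapters = adapter_pair(), probe_len = 120L,
                          min_block = 40L, both_strands = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  by_gene <- models_by_gene(models)
  genes <- genes %||% names(by_gene)
  rows <- lapply(genes, function(g) {
    gm <- by_gene[[g]]
    if (is.null(gm)) stop("no models for gene ", g)
    strand <- gm[[1L]]$strand
    win <- suppressWarnings(tile_probes(exonic_union(gm), probe_len,
                                        min_block))
    if (nrow(win) == 0L) return(NULL)
    seqs <- vapply(seq_len(nrow(win)), function(i) {
      spliced_sequence(genome, transcript_model(
        "w", g, win$chrom[i], strand, win$start[i], win$end[i]))
    }, character(1))
    df <- data.frame(gene_id = g, chrom = win$chrom, start = win$start,
                     end = win$end, strand = strand,
                     name = sprintf("%s_probe%03d", g, seq_len(nrow(win))),
                     target_seq = seqs,
                     oligo_seq = vapply(seqs, build_oligo, character(1),
                                        adapters = adapters,
                                        USE.NAMES = FALSE))
    if (both_strands) {
      rc <- df
      rc$name <- paste0(df$name, "_rc")
      rc$target_seq <- vapply(df$target_seq, revcomp, character(1),
                              USE.NAMES = FALSE)
      rc$oligo_seq <- vapply(rc$target_seq, build_oligo, character(1),
                             adapters = adapters, USE.NAMES = FALSE)
      df <- rbind(df, rc)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probe-yield reaction-capacity arithmetic
#'
#' `reactions_per_synthesis = floor(yield_ug * 1000 / probe_ng_per_reaction)`;
#' `n_syntheses = floor(total_template_ng / template_ng_per_synthesis)`;
#' total reactions is their product. With a 25-ug synthesis yield and
#' 100 ng of probe per capture reaction, one synthesis supports 250
#' reactions; a 50-200 ng template pool at 2 ng per synthesis then supports
#' 6250-25000 reactions in total.
#'
#' @param yield_ug_per_synthesis probe yield per synthesis reaction, ug.
#' @param probe_ng_per_reaction probe input per capture reaction, ng.
#' @param template_ng_per_synthesis template oligo pool consumed per
#'   synthesis, ng.
#' @param total_template_ng total template pool available, ng.
#' @return List `reactions_per_synthesis`, `n_syntheses`,
#'   `total_reactions`.
#' @export
reaction_capacity <- function(yield_ug_per_synthesis, probe_ng_per_reaction,
                              template_ng_per_synthesis, total_template_ng) {
  stopifnot(yield_ug_per_synthesis > 0, probe_ng_per_reaction > 0,
            template_ng_per_synthesis > 0, total_template_ng > 0)
  rps <- floor(yield_ug_per_synthesis * 1000 / probe_ng_per_reaction)
  ns <- floor(total_template_ng / template_ng_per_synthesis)
  list(reactions_per_synthesis = rps, n_syntheses = ns,
       total_reactions = rps * ns)
}
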