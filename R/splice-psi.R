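# Percent-spliced-in (psi) for cassette exons: long-read psi from isoform
# abundances, a junction-count surrogate for short-read psi, and the
# four-rule high-confidence exon-skipping filter.

#' Exon skipping event
#'
#' A cassette-exon event is defined by three splice junctions on one
#' chromosome and strand: the upstream inclusion intron `inc1`, the
#' downstream inclusion intron `inc2`, and the skipping intron, which spans
#' both (`[inc1_start, inc2_end)`). The four splice sites of the event are
#' the two boundaries of each inclusion intron.
#'
#' @param event_id,gene_id identifiers.
#' @param chrom,strand location.
#' @param inc1_start,inc1_end,inc2_start,inc2_end 0-based half-open intron
#'   coordinates with `inc1_end <= inc2_start` (the skipped exon lies
#'   between them).
#' @return One-row data frame describing the event.
#' @export
es_event <- function(event_id, gene_id, chrom, strand,
                     inc1_start, inc1_end, inc2_start, inc2_end) {
  if (!(inc1_start < inc1_end && inc1_end <= inc2_start &&
          inc2_start < inc2_end))
    stop("event introns must satisfy inc1 < skipped exon < inc2")
  data.frame(event_id = event_id, gene_id = gene_id, chrom = chrom,
             strand = strand, inc1_start = inc1_start, inc1_end = inc1_end,
             inc2_start = inc2_start, inc2_end = inc2_end,
             stringsAsFactors = FALSE)
}

has_intron <- function(model, start, end) {
  j <- splice_junctions(model)
  any(j$start == start & j$end == end)
}

#' Long-read psi from isoform abundances
#'
#' `psi = I / (I + S)` where `I` is the summed CPM of isoforms carrying both
#' exon-included splice junctions (exact intron-coordinate match) and `S`
#' the summed CPM of isoforms carrying the exon-skipped junction. Isoforms
#' carrying neither pattern are ignored; psi is undefined (`NA`) in samples
#' where `I + S = 0`.
#'
#' @param event one-row event frame from [es_event()].
#' @param models list of [transcript_model()] (the gene's isoforms; other
#'   genes are ignored).
#' @param ab CPM matrix from [cpm()].
#' @return Data frame with one row per sample: `sample`, `I`, `S`, `psi`.
#' @export
long_read_psi <- function(event, models, ab) {
  models <- Filter(function(m) m$gene_id == event$gene_id, models)
  if (length(models) == 0L) stop("no isoform models for gene ", event$gene_id)
  if (!any(vapply(models, function(m) m$chrom == event$chrom, logical(1))))
    stop("event chromosome does not match the gene's isoform models")
  ids <- vapply(models, function(m) m$transcript_id, character(1))
  inc <- vapply(models, function(m)
    has_intron(m, event$inc1_start, event$inc1_end) &&
      has_intron(m, event$inc2_start, event$inc2_end), logical(1))
  skp <- vapply(models, function(m)
    has_intron(m, event$inc1_start, event$inc2_end), logical(1))
  present <- intersect(ids, rownames(ab))
  sum_cpm <- function(sel) {
    sel <- intersect(ids[sel], present)
    if (length(sel) == 0L) rep(0, ncol(ab))
    else colSums(ab[sel, , drop = FALSE])
  }
  I <- sum_cpm(inc); S <- sum_cpm(skp)
  psi <- ifelse(I + S > 0, I / (I + S), NA_real_)
  data.frame(sample = colnames(ab), I = I, S = S, psi = psi,
             row.names = NULL)
}

#' Short-read psi from junction counts
#'
#' Junction-count surrogate:
#' `psi = mean(n_inc1, n_inc2) / (mean(n_inc1, n_inc2) + n_skip)`;
#' undefined (`NA`) when all three supports are zero.
#'
#' @param n_inc1,n_inc2 reads supporting the two exon-included junctions.
#' @param n_skip reads supporting the exon-skipped junction.
#' @return psi value(s) in `[0, 1]`, vectorized over inputs.
#' @export
short_read_psi <- function(n_inc1, n_inc2, n_skip) {
  inc <- (n_inc1 + n_inc2) / 2
  ifelse(inc + n_skip > 0, inc / (inc + n_skip), NA_real_)
}

event_sites <- function(events) {
  data.frame(event_id = rep(events$event_id, 4L),
             chrom = rep(events$chrom, 4L),
             pos = c(events$inc1_start, events$inc1_end,
                     events$inc2_start, events$inc2_end))
}

#' High-confidence exon-skipping filter
#'
#' Keeps events satisfying all four criteria: (1) the average short-read
#' support of the two inclusion junctions, or the skip-junction support, is
#' >= 10; (2) the inclusion-support ratio `n_inc1 / n_inc2` is between 0.2
#' and 5 (inclusive; one-sided zeros fail, 0/0 is left to criterion 1);
#' (3) the short-read psi is between 0.01 and 0.99 (inclusive); (4) none of
#' the event's four splice sites occurs in any other catalog event.
#'
#' @param events event frame (as from [es_event()], row-bound) with
#'   junction-support columns `n_inc1`, `n_inc2`, `n_skip`.
#' @param catalog the full catalog of discovered events used for criterion
#'   4 (default: `events` itself).
#' @return The retained subset of `events`, with a `psi_short` column and
#'   the per-criterion logical columns `crit1`..`crit4`.
#' @export
high_confidence_filter <- function(events, catalog = events) {
  if (nrow(events) == 0L) return(events)
  inc_mean <- (events$n_inc1 + events$n_inc2) / 2
  crit1 <- inc_mean >= 10 | events$n_skip >= 10
  ratio <- ifelse(events$n_inc2 > 0, events$n_inc1 / events$n_inc2, NA_real_)
  crit2 <- ifelse(events$n_inc1 == 0 & events$n_inc2 == 0, TRUE,
                  ifelse(events$n_inc1 == 0 | events$n_inc2 == 0, FALSE,
                         ratio >= 0.2 & ratio <= 5))
  psi <- short_read_psi(events$n_inc1, events$n_inc2, events$n_skip)
  crit3 <- !is.na(psi) & psi >= 0.01 & psi <= 0.99
  sites <- event_sites(catalog)
  crit4 <- vapply(seq_len(nrow(events)), function(i) {
    own <- event_sites(events[i, , drop = FALSE])
    other <- sites[sites$event_id != events$event_id[i], ]
    !any(paste(own$chrom, own$pos) %in% paste(other$chrom, other$pos))
  }, logical(1))
  out <- events
  out$psi_short <- psi
  out$crit1 <- crit1; out$crit2 <- crit2; out$crit3 <- crit3
  out$crit4 <- crit4
  out[crit1 & crit2 & crit3 & crit4, , drop = FALSE]
}

#' Concordance of long- and short-read psi
#'
#' Pearson correlation over events defined in both tables (paired per-event
#' means).
#'
#' @param psi_long,psi_short named numeric vectors of per-event psi values
#'   (names are event ids).
#' @return Pearson r.
#' @export
psi_concordance <- function(psi_long, psi_short) {
  shared <- intersect(names(psi_long), names(psi_short))
  x <- psi_long[shared]; y <- psi_short[shared]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stop("need >= 3 shared, defined events")
  cor(x[keep], y[keep])
}
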