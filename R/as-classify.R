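# Structural classification of an isoform against its gene's canonical
# isoform into the seven basic AS categories, "complex", or "combinatorial".
#
# Introns shared (exact coordinates) between the two transcripts partition
# the gene into regions; each maximal run of non-shared introns between
# consecutive shared anchors (or a transcript terminus) is one local
# difference, classified independently. Pure terminal-end-length
# differences with identical junction sets are not events (TSS/poly(A)
# scatter is not an AS category here).

intron_keys <- function(j) if (nrow(j) == 0L) character(0) else
  paste(j$start, j$end, sep = "-")

#' Local structural differences between an isoform and the canonical
#'
#' @param iso,canon [transcript_model()] objects of the same gene, on one
#'   chromosome and strand.
#' @return List of `local_diff` objects, each with the non-shared introns
#'   of both transcripts inside the region (`iso_introns`,
#'   `canon_introns`, data frames), the region's genomic `span`, and
#'   logical flags `at_left`/`at_right` marking whether the region is
#'   bounded by a transcript terminus rather than a shared intron. Empty
#'   for structurally identical transcripts.
#' @export
diff_regions <- function(iso, canon) {
  if (iso$chrom != canon$chrom || iso$strand != canon$strand)
    stop("isoform and canonical must share chromosome and strand")
  ji <- splice_junctions(iso); jc <- splice_junctions(canon)
  ki <- intron_keys(ji); kc <- intron_keys(jc)
  shared <- intersect(ki, kc)
  ui <- ji[!(ki %in% shared), , drop = FALSE]
  uc <- jc[!(kc %in% shared), , drop = FALSE]
  if (nrow(ui) == 0L && nrow(uc) == 0L) return(list())
  sh <- ji[ki %in% shared, , drop = FALSE]
  sh <- sh[order(sh$start), , drop = FALSE]
  # region boundaries: gene extremes and shared-intron anchors
  bounds <- c(-Inf, sh$start, Inf)
  ends <- c(-Inf, sh$end, Inf)
  regions <- list()
  for (r in seq_len(nrow(sh) + 1L)) {
    lo <- ends[r]; hi <- bounds[r + 1L]
    sel_i <- ui$start >= lo & ui$end <= hi
    sel_c <- uc$start >= lo & uc$end <= hi
    if (!any(sel_i) && !any(sel_c)) next
    regions[[length(regions) + 1L]] <- structure(list(
      iso_introns = ui[sel_i, , drop = FALSE],
      canon_introns = uc[sel_c, , drop = FALSE],
      span = c(max(lo, min(iso$exons$start, canon$exons$start)),
               min(hi, max(iso$exons$end, canon$exons$end))),
      at_left = !is.finite(lo), at_right = !is.finite(hi)),
      class = "local_diff")
  }
  regions
}

# terminal exon of a transcript at the genomic left/right end
terminal_exon <- function(t, side) {
  e <- t$exons
  if (side == "left") c(e$start[1L], e$end[1L])
  else c(e$start[nrow(e)], e$end[nrow(e)])
}

overlaps <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]

# does `t` have an exon strictly containing interval [s, e)?
exon_contains <- function(t, s, e) {
  any(t$exons$start < s & t$exons$end > e)
}

#' Classify one local difference
#'
#' Applies the strand-aware decision rules for the seven basic AS
#' categories; anything not matching is `"complex"` (the catch-all).
#'
#' @param d a `local_diff` from [diff_regions()].
#' @param iso,canon the two [transcript_model()] objects.
#' @return A category string.
#' @export
classify_diff <- function(d, iso, canon) {
  A <- d$iso_introns; B <- d$canon_introns
  strand <- iso$strand
  nA <- nrow(A); nB <- nrow(B)
  # alternative first/last exon: the region includes the transcript
  # terminus, one non-shared intron on each side sharing the anchor-side
  # boundary, and non-overlapping terminal exons
  term_side_5p <- if (strand == "+") "left" else "right"
  if (nA == 1L && nB == 1L) {
    if ((if (term_side_5p == "left") d$at_left else d$at_right)) {
      match_anchor <- if (term_side_5p == "left")
        A$end == B$end else A$start == B$start
      if (match_anchor &&
          !overlaps(terminal_exon(iso, term_side_5p),
                    terminal_exon(canon, term_side_5p)))
        return("alt_first_exon")
    }
    term_side_3p <- if (strand == "+") "right" else "left"
    if ((if (term_side_3p == "right") d$at_right else d$at_left)) {
      match_anchor <- if (term_side_3p == "right")
        A$start == B$start else A$end == B$end
      if (match_anchor &&
          !overlaps(terminal_exon(iso, term_side_3p),
                    terminal_exon(canon, term_side_3p)))
        return("alt_last_exon")
    }
  }
  # intron retention: one transcript has no intron in the region, the other
  # exactly one, contained in an exon of the retaining transcript
  if (nA == 0L && nB == 1L &&
      exon_contains(iso, B$start[1L], B$end[1L]))
    return("intron_retention")
  if (nB == 0L && nA == 1L &&
      exon_contains(canon, A$start[1L], A$end[1L]))
    return("intron_retention")
  # exon skipping: one bridging intron vs >= 2 introns with matching outer
  # splice sites (>= 1 whole exon skipped through one junction)
  skip_rule <- function(one, many) {
    nrow(one) == 1L && nrow(many) >= 2L &&
      one$start[1L] == many$start[1L] &&
      one$end[1L] == many$end[nrow(many)]
  }
  if (skip_rule(A, B) || skip_rule(B, A)) return("exon_skipping")
  # mutually exclusive exons: two introns each, shared outer sites, one
  # internal exon per transcript, non-overlapping
  if (nA == 2L && nB == 2L &&
      A$start[1L] == B$start[1L] && A$end[2L] == B$end[2L]) {
    exon_i <- c(A$end[1L], A$start[2L])
    exon_c <- c(B$end[1L], B$start[2L])
    if (exon_i[1L] < exon_i[2L] && exon_c[1L] < exon_c[2L] &&
        !overlaps(exon_i, exon_c))
      return("mutually_exclusive_exons")
  }
  # alternative 5'/3' splice site: a single intron pair sharing exactly one
  # boundary; the differing side names the category in transcript
  # orientation
  if (nA == 1L && nB == 1L) {
    same_start <- A$start[1L] == B$start[1L]
    same_end <- A$end[1L] == B$end[1L]
    if (xor(same_start, same_end)) {
      diff_at_genomic_start <- !same_start
      if (diff_at_genomic_start)
        return(if (strand == "+") "alt_5ss" else "alt_3ss")
      return(if (strand == "+") "alt_3ss" else "alt_5ss")
    }
  }
  "complex"
}

#' Classify an isoform against the canonical isoform
#'
#' Each local difference is classified independently; an isoform with two
#' or more events is labeled `"combinatorial"`, one event takes that
#' event's category, and zero events yield the `"identical"` sentinel.
#'
#' @param iso,canon [transcript_model()] objects of the same gene.
#' @return List with `events` (character vector of per-region categories)
#'   and `label` (single category, `"combinatorial"`, or `"identical"`).
#' @export
classify_isoform <- function(iso, canon) {
  regions <- diff_regions(iso, canon)
  events <- vapply(regions, classify_diff, character(1), iso = iso,
                   canon = canon)
  label <- if (length(events) == 0L) "identical"
  else if (length(events) == 1L) events
  else "combinatorial"
  list(events = events, label = label)
}

#' Classify a set of isoforms against their genes' canonical isoforms
#'
#' @param models named list of [transcript_model()] containing, for each
#'   classified isoform's gene, a canonical isoform.
#' @param isoform_ids ids of the isoforms to classify (default: all
#'   non-canonical models).
#' @return Data frame `isoform_id`, `gene_id`, `events` (comma-joined),
#'   `label`.
#' @export
classify_isoforms <- function(models, isoform_ids = NULL) {
  by_gene <- models_by_gene(models)
  if (is.null(isoform_ids))
    isoform_ids <- names(models)[!vapply(models, function(m) m$is_canonical,
                                         logical(1))]
  rows <- lapply(isoform_ids, function(id) {
    m <- models[[id]]
    if (is.null(m)) stop("unknown isoform: ", id)
    canon <- canonical_of(by_gene[[m$gene_id]])
    if (is.null(canon)) stop("no canonical isoform for gene ", m$gene_id)
    cl <- classify_isoform(m, canon)
    data.frame(isoform_id = id, gene_id = m$gene_id,
               events = paste(cl$events, collapse = ","), label = cl$label)
  })
  do.call(rbind, rows)
}
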