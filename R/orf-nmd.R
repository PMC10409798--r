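# Transcript categorization, longest-ORF finding, NMD prediction by the
# 50-nt rule, and the gene-category (TSG/OG/Other) enrichment summaries.

#' Route a transcript to annotated status or ORF scan
#'
#' Transcripts annotated as full-length ("basic") protein-coding or
#' NMD-targeted keep their annotated status; all other annotated
#' transcripts and novel transcripts are routed to the ORF scan.
#'
#' @param t a [transcript_model()].
#' @return `"skip_annotated_coding_or_nmd"` or `"needs_orf_scan"`.
#' @export
categorize_transcript <- function(t) {
  if (t$annotation_status == "annotated_basic_or_nmd")
    "skip_annotated_coding_or_nmd" else "needs_orf_scan"
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans the sense strand for ORFs starting at any ATG and ending at the
#' first in-frame stop codon (TAA/TAG/TGA) fully inside the sequence.
#' Returns the longest by encoded amino-acid count, ties broken by the
#' 5'-most start; `NULL` if no stop-terminated ORF of at least `min_aa`
#' amino acids exists. `aa_length` counts the codons between the initiator
#' ATG and the stop codon (neither included), so `ATG + 20 codons + TAA`
#' sits exactly at the default 20-aa floor.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param min_aa minimum encoded amino acids (default 20).
#' @return `NULL`, or a list with `start` (0-based offset of the A of ATG),
#'   `stop_end` (offset one past the stop codon), and `aa_length`.
#' @export
find_longest_orf <- function(seq, min_aa = 20L) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 6L) return(NULL)
  find_all <- function(pat) {
    h <- gregexpr(pat, s, fixed = TRUE)[[1L]]
    if (h[1L] == -1L) integer(0) else as.integer(h)
  }
  atg <- find_all("ATG")
  if (length(atg) == 0L) return(NULL)
  stops <- sort(unique(c(find_all("TAA"), find_all("TAG"), find_all("TGA"))))
  stops <- stops[stops + 2L <= n]
  best <- NULL
  for (f in 0:2) {
    sa <- atg[(atg - 1L) %% 3L == f]
    st <- stops[(stops - 1L) %% 3L == f]
    if (length(sa) == 0L || length(st) == 0L) next
    # first in-frame stop at or after start+3
    idx <- findInterval(sa + 2L, st) + 1L
    for (k in seq_along(sa)) {
      if (idx[k] > length(st)) next
      start <- sa[k]; stop_pos <- st[idx[k]]
      aa <- (stop_pos + 3L - start) %/% 3L - 2L   # codons between ATG and stop
      if (is.null(best) || aa > best$aa_length ||
          (aa == best$aa_length && start - 1L < best$start)) {
        best <- list(start = start - 1L, stop_end = stop_pos + 2L,
                     aa_length = aa)
      }
    }
  }
  if (is.null(best) || best$aa_length < min_aa) return(NULL)
  best
}

#' NMD verdict for a transcript by the 50-nt rule
#'
#' A transcript is predicted NMD-targeted iff (1) it is at least
#' `min_length` nt long, (2) it contains at least one splice junction, and
#' (3) the stop codon of its (longest) ORF lies at least `min_distance` nt
#' upstream of the last splice junction, measuring from one past the stop
#' codon to the 3'-most exon-exon boundary in transcript coordinates
#' (>= 50 inclusive). A transcript without a qualifying ORF is not a
#' predicted NMD target (`no_orf`).
#'
#' @param t a [transcript_model()].
#' @param orf result of [find_longest_orf()] on `spliced_sequence(genome, t)`
#'   (possibly `NULL`).
#' @param min_length minimum transcript length (default 200 nt).
#' @param min_distance minimum stop-to-last-junction distance (default 50 nt).
#' @return List with `is_nmd` (logical) and `reasons` (character vector of
#'   failed criteria among `too_short`, `no_junction`, `stop_near_end`,
#'   `no_orf`; empty iff `is_nmd`).
#' @export
nmd_verdict <- function(t, orf, min_length = 200L, min_distance = 50L) {
  reasons <- character(0)
  if (is.null(orf)) reasons <- c(reasons, "no_orf")
  if (transcript_length(t) < min_length) reasons <- c(reasons, "too_short")
  jx <- junction_tx_positions(t)
  if (length(jx) == 0L) {
    reasons <- c(reasons, "no_junction")
  } else if (!is.null(orf) && (jx[length(jx)] - orf$stop_end) < min_distance) {
    reasons <- c(reasons, "stop_near_end")
  }
  list(is_nmd = length(reasons) == 0L, reasons = reasons)
}

#' Predict NMD status for a set of isoforms
#'
#' Convenience wrapper combining routing, ORF scan, and the 50-nt rule.
#' Transcripts annotated as basic coding/NMD keep their annotated status
#' (reported as `annotated`); the rest are scanned.
#'
#' @param models named list of [transcript_model()].
#' @param genome chromosome sequences (see [spliced_sequence()]).
#' @param min_aa,min_length,min_distance rule constants (20 aa / 200 nt /
#'   50 nt).
#' @return Data frame `isoform_id`, `gene_id`, `route`, `is_nmd`,
#'   `reasons` (comma-joined).
#' @export
predict_nmd <- function(models, genome, min_aa = 20L, min_length = 200L,
                        min_distance = 50L) {
  rows <- lapply(models, function(t) {
    route <- categorize_transcript(t)
    if (route == "skip_annotated_coding_or_nmd") {
      return(data.frame(isoform_id = t$transcript_id, gene_id = t$gene_id,
                        route = route, is_nmd = FALSE,
                        reasons = "annotated_status_retained"))
    }
    orf <- find_longest_orf(spliced_sequence(genome, t), min_aa = min_aa)
    v <- nmd_verdict(t, orf, min_length = min_length,
                     min_distance = min_distance)
    data.frame(isoform_id = t$transcript_id, gene_id = t$gene_id,
               route = route, is_nmd = v$is_nmd,
               reasons = paste(v$reasons, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-category enrichment of NMD-targeted aberrant isoforms
#'
#' Among genes expressed in at least `min_lines` cell lines (average CPM
#' across a line's replicates `>= cpm_threshold` counts the line), computes
#' per category (e.g. TSG/OG/Other) the fraction of genes with at least one
#' NMD-targeted aberrant isoform, pairwise two-sided Fisher's exact tests
#' on those 2x2 tables, and per-cell-line percentages compared across
#' categories by two-sided paired Wilcoxon tests over lines.
#'
#' @param nmd_genes character vector of gene ids with >= 1 NMD-targeted
#'   aberrant isoform.
#' @param categories data frame with `gene_id`, `category`.
#' @param cm a [count_matrix()] for the expression filter.
#' @param min_lines minimum number of expressing cell lines (default 10).
#' @param cpm_threshold per-line average-CPM detection threshold (default 1).
#' @return List with `fractions` (per-category data frame), `fisher`
#'   (pairwise p-values), `wilcoxon` (pairwise paired p-values over lines),
#'   and `per_line` (line x category percentage matrix).
#' @export
nmd_category_enrichment <- function(nmd_genes, categories, cm,
                                    min_lines = 10L, cpm_threshold = 1) {
  ab <- cpm(cm)
  g <- gene_cpm(ab)
  lines <- unique(unname(cm$replicate_map))
  # per-line detection: mean CPM across the line's replicates >= threshold
  det <- vapply(lines, function(l) {
    cols <- names(cm$replicate_map)[cm$replicate_map == l]
    rowMeans(g[, cols, drop = FALSE]) >= cpm_threshold
  }, logical(nrow(g)))
  rownames(det) <- rownames(g); colnames(det) <- lines
  expressed <- rownames(det)[rowSums(det) >= min_lines]
  cat_of <- setNames(categories$category, categories$gene_id)
  cats <- sort(unique(categories$category))
  frac <- do.call(rbind, lapply(cats, function(cc) {
    genes_c <- intersect(expressed, categories$gene_id[
      categories$category == cc])
    n_nmd <- sum(genes_c %in% nmd_genes)
    data.frame(category = cc, n_genes = length(genes_c), n_nmd = n_nmd,
               fraction = if (length(genes_c)) n_nmd / length(genes_c)
               else NA_real_)
  }))
  pairs <- if (length(cats) >= 2L) utils::combn(cats, 2L, simplify = FALSE)
  else list()
  fisher <- lapply(pairs, function(pr) {
    a <- frac[frac$category == pr[1L], ]; b <- frac[frac$category == pr[2L], ]
    if (a$n_genes == 0L || b$n_genes == 0L)
      return(data.frame(cat1 = pr[1L], cat2 = pr[2L], p_value = NA_real_))
    tab <- matrix(c(a$n_nmd, a$n_genes - a$n_nmd,
                    b$n_nmd, b$n_genes - b$n_nmd), nrow = 2L, byrow = TRUE)
    data.frame(cat1 = pr[1L], cat2 = pr[2L],
               p_value = fisher.test(tab, alternative = "two.sided")$p.value)
  })
  per_line <- vapply(cats, function(cc) {
    vapply(lines, function(l) {
      genes_cl <- rownames(det)[det[, l] &
                                  cat_of[rownames(det)] %in% cc]
      if (length(genes_cl) == 0L) return(NA_real_)
      100 * mean(genes_cl %in% nmd_genes)
    }, numeric(1))
  }, numeric(length(lines)))
  rownames(per_line) <- lines
  wilcoxon <- lapply(pairs, function(pr) {
    x <- per_line[, pr[1L]]; y <- per_line[, pr[2L]]
    keep <- !is.na(x) & !is.na(y)
    p <- if (sum(keep) < 2L || all(x[keep] == y[keep])) NA_real_
    else suppressWarnings(wilcox.test(x[keep], y[keep],
                                      paired = TRUE)$p.value)
    data.frame(cat1 = pr[1L], cat2 = pr[2L], p_value = p)
  })
  list(fractions = frac,
       fisher = if (length(fisher)) do.call(rbind, fisher) else NULL,
       wilcoxon = if (length(wilcoxon)) do.call(rbind, wilcoxon) else NULL,
       per_line = per_line)
}
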