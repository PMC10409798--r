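# Tumor-aberrant isoform detection: a three-stage outlier procedure on
# per-gene isoform-by-sample count matrices.
#
# Stage 1 screens each gene's m x N matrix with a chi-square test of
# homogeneity (BH FDR < q_gene). Stage 2 runs, within screened genes, a
# one-tailed binomial post hoc per (isoform, sample) against the overall
# isoform proportion p0 (BH FDR < q_pair). Stage 3 calls an isoform
# aberrant in a cell line only when BOTH replicates pass the adjusted-p
# threshold AND exceed p0 by at least min_excess; calls require 1..max_lines
# qualifying lines and a non-canonical isoform.

#' Per-gene isoform-by-sample test matrix
#'
#' Rounds the gene's counts half-away-from-zero to integers, drops samples
#' where the gene is unexpressed (zero column sum), and skips genes with a
#' single isoform or expression in at most one sample.
#'
#' @param cm a [count_matrix()].
#' @param gene gene id.
#' @return A list of class `gene_test_matrix` with `gene_id`, `counts`
#'   (m x N integer matrix), `p0` (overall per-isoform proportions,
#'   row sum / grand sum), and `retained` (kept sample ids); or a character
#'   skip reason (`"single_isoform"` / `"single_sample"`).
#' @export
prepare_gene_matrix <- function(cm, gene) {
  rows <- which(cm$gene_ids == gene)
  if (length(rows) == 0L) stop("gene not in count matrix: ", gene)
  if (length(rows) == 1L) return("single_isoform")
  m <- round_half_up(cm$counts[rows, , drop = FALSE])
  keep <- colSums(m) > 0
  if (sum(keep) <= 1L) return("single_sample")
  m <- m[, keep, drop = FALSE]
  structure(list(gene_id = gene, counts = m,
                 p0 = rowSums(m) / sum(m), retained = colnames(m)),
            class = "gene_test_matrix")
}

#' Chi-square test of homogeneity on a gene test matrix
#'
#' Classical Pearson chi-square on the m x N table (no continuity
#' correction), df = (m - 1)(N - 1). Rows that are all zero are dropped
#' before testing; if fewer than two rows remain the test is skipped
#' (`NA`).
#'
#' @param gm a `gene_test_matrix` from [prepare_gene_matrix()].
#' @return The p-value, with the statistic and df as attributes.
#' @export
chisq_homogeneity <- function(gm) {
  m <- gm$counts[rowSums(gm$counts) > 0, , drop = FALSE]
  if (nrow(m) < 2L) return(NA_real_)
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(unname(ht$p.value), statistic = unname(ht$statistic),
            df = unname(ht$parameter))
}

#' One-tailed binomial post hoc test
#'
#' For isoform i and sample s, `p = P(X >= x_is)` with
#' `X ~ Binomial(n = column total of s, p0_i)` (exact upper tail), testing
#' whether the isoform's proportion in the sample is elevated above the
#' overall proportion `p0`.
#'
#' @param gm a `gene_test_matrix` from [prepare_gene_matrix()].
#' @return Data frame with one row per (isoform, sample): `gene_id`,
#'   `isoform_id`, `sample`, `x`, `n`, `p0`, `prop`, `p_value`.
#' @export
posthoc_binomial <- function(gm) {
  n <- colSums(gm$counts)
  grid <- expand.grid(i = seq_len(nrow(gm$counts)),
                      s = seq_len(ncol(gm$counts)))
  x <- gm$counts[cbind(grid$i, grid$s)]
  ns <- n[grid$s]
  p0 <- gm$p0[grid$i]
  data.frame(gene_id = gm$gene_id,
             isoform_id = rownames(gm$counts)[grid$i],
             sample = colnames(gm$counts)[grid$s],
             x = x, n = ns, p0 = p0, prop = x / ns,
             p_value = pbinom(x - 1, ns, p0, lower.tail = FALSE),
             row.names = NULL)
}

#' Call tumor-aberrant transcript isoforms
#'
#' Runs the full three-stage procedure over all genes of a count matrix.
#' BH families: the chi-square screen is adjusted over all tested genes;
#' the post-hoc family is global over all (isoform, sample) pairs from
#' screened genes (`posthoc_family = "per_gene"` adjusts within gene). A
#' cell line qualifies for an isoform only when all of its replicates were
#' retained for the gene (at least two), each has adjusted post-hoc
#' `p < q_pair`, and each has proportion `>= p0 + min_excess` (proportions
#' on the rounded-count basis shared with `p0`). An isoform is called iff
#' it qualifies in `1..max_lines` cell lines and is not the canonical
#' isoform of its gene.
#'
#' @param cm a [count_matrix()] (with `replicate_map`).
#' @param canonical_ids character vector of canonical isoform ids.
#' @param q_gene chi-square FDR threshold (default 0.01).
#' @param q_pair post-hoc FDR threshold (default 0.01).
#' @param min_excess minimum proportion excess over p0 (default 0.10).
#' @param max_lines recurrence cap; default `ceiling(0.10 * n_cell_lines)`
#'   (4 lines for a 40-line panel).
#' @param posthoc_family `"global"` or `"per_gene"` BH family for the post
#'   hoc.
#' @return Data frame of calls (`isoform_id`, `gene_id`, `cell_lines`
#'   comma-joined, `n_lines`), with attributes `"gene_screen"` (per-gene
#'   chi-square p/FDR and skip reasons), `"posthoc"` (all pairs with
#'   adjusted p), and `"line_detail"` (per qualifying line and replicate).
#' @export
find_aberrant_isoforms <- function(cm, canonical_ids = character(0),
                                   q_gene = 0.01, q_pair = 0.01,
                                   min_excess = 0.10, max_lines = NULL,
                                   posthoc_family = c("global", "per_gene")) {
  posthoc_family <- match.arg(posthoc_family)
  lines_all <- unique(unname(cm$replicate_map))
  if (is.null(max_lines)) max_lines <- ceiling(0.10 * length(lines_all))
  if (max_lines < 1L) stop("max_lines must be >= 1")
  genes <- unique(unname(cm$gene_ids))
  gms <- list()
  screen <- data.frame(gene_id = genes, skip = NA_character_,
                       p_value = NA_real_)
  for (i in seq_along(genes)) {
    gm <- prepare_gene_matrix(cm, genes[i])
    if (is.character(gm)) { screen$skip[i] <- gm; next }
    p <- chisq_homogeneity(gm)
    if (is.na(p)) { screen$skip[i] <- "degenerate_table"; next }
    screen$p_value[i] <- p
    gms[[genes[i]]] <- gm
  }
  tested <- !is.na(screen$p_value)
  screen$fdr <- NA_real_
  screen$fdr[tested] <- p.adjust(screen$p_value[tested], method = "BH")
  screened <- screen$gene_id[tested & screen$fdr < q_gene]

  empty <- data.frame(isoform_id = character(0), gene_id = character(0),
                      cell_lines = character(0), n_lines = integer(0))
  attr(empty, "gene_screen") <- screen
  if (length(screened) == 0L) return(empty)

  ph <- do.call(rbind, lapply(gms[screened], posthoc_binomial))
  if (posthoc_family == "global") {
    ph$p_adj <- p.adjust(ph$p_value, method = "BH")
  } else {
    ph$p_adj <- stats::ave(ph$p_value, ph$gene_id,
                           FUN = function(p) p.adjust(p, method = "BH"))
  }
  ph$cell_line <- unname(cm$replicate_map[ph$sample])
  ph$pass <- ph$p_adj < q_pair & ph$prop >= ph$p0 + min_excess

  n_reps <- table(unname(cm$replicate_map))
  calls <- list(); detail <- list(); k <- 0L
  for (iso in unique(ph$isoform_id[ph$pass])) {
    sub <- ph[ph$isoform_id == iso, ]
    qual <- character(0)
    for (l in unique(sub$cell_line[sub$pass])) {
      reps <- sub[sub$cell_line == l, ]
      # every replicate of the line must be retained and pass both criteria
      if (nrow(reps) < 2L || nrow(reps) < n_reps[[l]]) next
      if (all(reps$pass)) qual <- c(qual, l)
    }
    n_q <- length(qual)
    if (n_q >= 1L && n_q <= max_lines && !(iso %in% canonical_ids)) {
      k <- k + 1L
      calls[[k]] <- data.frame(isoform_id = iso,
                               gene_id = sub$gene_id[1L],
                               cell_lines = paste(sort(qual),
                                                  collapse = ","),
                               n_lines = n_q)
      detail[[k]] <- sub[sub$cell_line %in% qual,
                         c("gene_id", "isoform_id", "cell_line", "sample",
                           "x", "n", "p0", "prop", "p_adj")]
    }
  }
  out <- if (k > 0L) do.call(rbind, calls) else empty
  out <- out[order(out$gene_id, out$isoform_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_screen") <- screen
  attr(out, "posthoc") <- ph
  attr(out, "line_detail") <- if (k > 0L) do.call(rbind, detail) else NULL
  out
}
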