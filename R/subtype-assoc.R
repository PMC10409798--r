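# Subtype-associated isoform detection: per-(isoform, subtype) two-sided
# t-tests on proportions, BH FDR over one pooled family, and a >=10%
# effect-size floor.

#' Find subtype-associated transcript isoforms
#'
#' For every (isoform, subtype) pair, compares the isoform's proportion in
#' samples of the subtype against all other samples with a two-sided
#' Student's t-test (pooled variance by default; Welch behind
#' `var_equal = FALSE`). Replicates are treated as independent observations;
#' samples where the gene is unexpressed (proportion `NA`) are excluded from
#' that test. Benjamini-Hochberg correction is applied over all executed
#' tests as one family (`family = "per_subtype"` adjusts within subtype
#' instead). An isoform is called for a subtype iff `fdr <= alpha` and the
#' subtype mean exceeds the out-group mean by at least `min_delta`
#' (one-directional: elevated in the subtype).
#'
#' @param pt proportion matrix from [isoform_proportion()].
#' @param replicate_map named character vector sample -> cell line.
#' @param subtype_map named character vector cell line -> subtype.
#' @param alpha FDR threshold (default 0.05).
#' @param min_delta minimum proportion difference (default 0.10).
#' @param var_equal pooled-variance Student's t (default) vs Welch.
#' @param family BH family: `"global"` (all tests pooled) or
#'   `"per_subtype"`.
#' @return Data frame with one row per executed or skipped test: `isoform_id`,
#'   `subtype`, `n_in`, `n_out`, `mean_in`, `mean_out`, `delta`, `p_value`,
#'   `fdr`, `called`, `skip_reason`. Skipped tests (a group with < 2 usable
#'   samples) carry `NA` statistics and a reason.
#' @export
find_subtype_associated <- function(pt, replicate_map, subtype_map,
                                    alpha = 0.05, min_delta = 0.10,
                                    var_equal = TRUE,
                                    family = c("global", "per_subtype")) {
  family <- match.arg(family)
  samples <- colnames(pt)
  sample_subtype <- unname(subtype_map[replicate_map[samples]])
  subtypes <- sort(unique(sample_subtype))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes")
  rows <- list(); k <- 0L
  for (iso in rownames(pt)) {
    x <- pt[iso, ]
    for (s in subtypes) {
      xin <- x[sample_subtype == s & !is.na(x)]
      xout <- x[sample_subtype != s & !is.na(x)]
      k <- k + 1L
      if (length(xin) < 2L || length(xout) < 2L) {
        rows[[k]] <- data.frame(isoform_id = iso, subtype = s,
                                n_in = length(xin), n_out = length(xout),
                                mean_in = NA_real_, mean_out = NA_real_,
                                delta = NA_real_, p_value = NA_real_,
                                skip_reason = "fewer_than_2_usable_samples")
        next
      }
      delta <- mean(xin) - mean(xout)
      p <- if (var(xin) == 0 && var(xout) == 0) {
        if (delta == 0) 1 else 0   # degenerate zero-variance fixtures
      } else {
        t.test(xin, xout, var.equal = var_equal)$p.value
      }
      rows[[k]] <- data.frame(isoform_id = iso, subtype = s,
                              n_in = length(xin), n_out = length(xout),
                              mean_in = mean(xin), mean_out = mean(xout),
                              delta = delta, p_value = p,
                              skip_reason = NA_character_)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  done <- !is.na(res$p_value)
  if (family == "global") {
    res$fdr[done] <- p.adjust(res$p_value[done], method = "BH")
  } else {
    for (s in subtypes) {
      sel <- done & res$subtype == s
      res$fdr[sel] <- p.adjust(res$p_value[sel], method = "BH")
    }
  }
  res$called <- done & res$fdr <= alpha & res$delta >= min_delta
  res
}
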