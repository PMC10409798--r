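# Independent oracles used to cross-check package computations.

# textbook Pearson chi-square of homogeneity
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(stat = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

# brute-force upper binomial tail by PMF summation
binom_tail_oracle <- function(x, n, p) {
  if (x > n) return(0)
  sum(dbinom(seq.int(x, n), n, p))
}

# exhaustive longest-ORF search: every ATG, first in-frame stop
brute_orf <- function(seq, min_aa = 20L) {
  n <- nchar(seq)
  best <- NULL
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        aa <- (j + 3L - i) %/% 3L - 2L
        if (is.null(best) || aa > best$aa_length)
          best <- list(start = i - 1L, stop_end = j + 2L, aa_length = aa)
        break
      }
      j <- j + 3L
    }
  }
  if (!is.null(best) && best$aa_length < min_aa) best <- NULL
  best
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
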