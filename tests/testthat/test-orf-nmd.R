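test_that("annotated basic coding/NMD transcripts skip the ORF scan", {
  t1 <- transcript_model("t", "g", "c", "+", 0, 300,
                         annotation_status = "annotated_basic_or_nmd")
  expect_equal(categorize_transcript(t1), "skip_annotated_coding_or_nmd")
  for (st in c("novel", "annotated_other")) {
    t2 <- transcript_model("t", "g", "c", "+", 0, 300,
                           annotation_status = st)
    expect_equal(categorize_transcript(t2), "needs_orf_scan")
  }
})

test_that("the 20-aa floor is an exact boundary of the ORF finder", {
  at20 <- paste0("ATG", strrep("GCA", 20), "TAA")
  orf <- find_longest_orf(at20)
  expect_equal(orf$aa_length, 20L)
  expect_equal(orf$start, 0L)
  expect_equal(orf$stop_end, nchar(at20))
  expect_null(find_longest_orf(paste0("ATG", strrep("GCA", 19), "TAA")))
  expect_null(find_longest_orf(paste0("ATG", strrep("GCA", 30))))  # no stop
})

test_that("the ORF finder matches exhaustive enumeration on random sequences", {
  set.seed(77)
  for (i in 1:60) {
    s <- random_dna(sample(300:1200, 1))
    expect_identical(find_longest_orf(s, min_aa = 1L),
                     brute_orf(s, min_aa = 1L))
    expect_identical(find_longest_orf(s), brute_orf(s))
  }
})

test_that("the NMD verdict flips exactly at the printed thresholds", {
  orf63 <- function(nc) paste0(strrep("C", 3), "ATG", strrep("GCA", 25),
                               "TAA", strrep("C", nc))
  # stop 50 nt upstream of the junction (stop_end 84, junction at 134): NMD
  fx50 <- tx_with_sequence(orf63(166), c(134, 116))
  orf <- find_longest_orf(spliced_sequence(fx50$genome, fx50$t))
  expect_equal(orf$stop_end, 84L)
  expect_true(nmd_verdict(fx50$t, orf)$is_nmd)
  # 49 nt: one base short of the rule
  fx49 <- tx_with_sequence(orf63(166), c(133, 117))
  v49 <- nmd_verdict(fx49$t, find_longest_orf(
    spliced_sequence(fx49$genome, fx49$t)))
  expect_false(v49$is_nmd)
  expect_equal(v49$reasons, "stop_near_end")
  # transcript length 199 vs 200
  fx199 <- tx_with_sequence(orf63(115), c(134, 65))
  v199 <- nmd_verdict(fx199$t, find_longest_orf(
    spliced_sequence(fx199$genome, fx199$t)))
  expect_equal(v199$reasons, "too_short")
  fx200 <- tx_with_sequence(orf63(116), c(134, 66))
  expect_true(nmd_verdict(fx200$t, find_longest_orf(
    spliced_sequence(fx200$genome, fx200$t)))$is_nmd)
  # single-exon transcripts cannot be NMD targets
  fx1ex <- tx_with_sequence(orf63(166), 250)
  v1 <- nmd_verdict(fx1ex$t, find_longest_orf(
    spliced_sequence(fx1ex$genome, fx1ex$t)))
  expect_equal(v1$reasons, "no_junction")
  # 19 vs 20 encoded amino acids
  orf_aa <- function(k, nc) paste0(strrep("C", 3), "ATG", strrep("GCA", k),
                                   "TAA", strrep("C", nc))
  fx19 <- tx_with_sequence(orf_aa(19, 154), c(120, 100))
  v19 <- nmd_verdict(fx19$t, find_longest_orf(
    spliced_sequence(fx19$genome, fx19$t)))
  expect_false(v19$is_nmd)
  expect_true("no_orf" %in% v19$reasons)
  fx20 <- tx_with_sequence(orf_aa(20, 151), c(120, 100))
  expect_true(nmd_verdict(fx20$t, find_longest_orf(
    spliced_sequence(fx20$genome, fx20$t)))$is_nmd)
})

test_that("moving the stop codon 5' never turns NMD off", {
  t2ex <- transcript_model("t", "g", "c", "+", c(0, 400), c(300, 500))
  verdicts <- vapply(seq(60, 297, by = 3), function(se) {
    nmd_verdict(t2ex, list(start = 0, stop_end = se,
                           aa_length = se / 3 - 1))$is_nmd
  }, logical(1))
  # TRUE for small stop_end, then FALSE; never FALSE -> TRUE going 3'
  expect_false(any(diff(verdicts) == 1))
  expect_true(verdicts[1])
  expect_false(verdicts[length(verdicts)])
})

test_that("a retained intron with an in-frame PTC is predicted NMD-targeted", {
  ann <- gen_annotation(3L)
  res <- predict_nmd(ann$models, ann$genome)
  expect_true(res$is_nmd[res$isoform_id == "g_ptc_alt"])
  # the PTC sits >= 50 nt upstream of the isoform's last junction
  alt <- ann$models$g_ptc_alt
  orf <- find_longest_orf(spliced_sequence(ann$genome, alt))
  jx <- junction_tx_positions(alt)
  expect_gte(jx[length(jx)] - orf$stop_end, 50L)
  # annotated canonical keeps its annotated status
  expect_equal(res$route[res$isoform_id == "g_ptc_canon"],
               "skip_annotated_coding_or_nmd")
})

enrichment_fixture <- function(n_per_cat = 40, n_lines = 10) {
  genes <- sprintf("g%03d", seq_len(2 * n_per_cat))
  samples <- as.vector(rbind(paste0("line", 1:n_lines, "_r1"),
                             paste0("line", 1:n_lines, "_r2")))
  counts <- matrix(100, length(genes), length(samples),
                   dimnames = list(genes, samples))
  list(cm = toy_count_matrix(counts, genes),
       categories = data.frame(gene_id = genes,
                               category = rep(c("TSG", "OG"),
                                              each = n_per_cat)))
}

test_that("category enrichment handles null and balanced cases", {
  fx <- enrichment_fixture()
  none <- nmd_category_enrichment(character(0), fx$categories, fx$cm)
  expect_true(all(none$fractions$fraction == 0))
  expect_equal(none$fisher$p_value, 1)
  # identical margins (10 of 40 in both categories): Fisher p = 1
  nmd_genes <- c(sprintf("g%03d", 1:10), sprintf("g%03d", 41:50))
  bal <- nmd_category_enrichment(nmd_genes, fx$categories, fx$cm)
  expect_equal(bal$fractions$fraction, c(0.25, 0.25))
  expect_equal(bal$fisher$p_value, 1)
  expect_true(all(bal$per_line[, "TSG"] == 25))
})

test_that("a planted TSG excess is detected by fraction and Fisher test", {
  fx <- enrichment_fixture(n_per_cat = 200)
  set.seed(101)
  wins <- 0L
  for (i in 1:100) {
    nmd_genes <- c(sprintf("g%03d", which(runif(200) < 0.20)),
                   sprintf("g%03d", 200 + which(runif(200) < 0.08)))
    enr <- nmd_category_enrichment(nmd_genes, fx$categories, fx$cm)
    fr <- setNames(enr$fractions$fraction, enr$fractions$category)
    if (fr["TSG"] > fr["OG"] && enr$fisher$p_value < 0.05) wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("genes expressed in too few lines are excluded from denominators", {
  fx <- enrichment_fixture(n_per_cat = 5, n_lines = 12)
  fx$cm$counts["g001", ] <- 0            # never detected
  fx$cm$counts["g002", -(1:4)] <- 0      # detected in 2 lines < 10
  enr <- nmd_category_enrichment(c("g001", "g003"), fx$categories, fx$cm)
  tsg <- enr$fractions[enr$fractions$category == "TSG", ]
  expect_equal(tsg$n_genes, 3)
  expect_equal(tsg$n_nmd, 1)   # g001 dropped by the expression filter
})
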