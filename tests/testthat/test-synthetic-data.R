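test_that("generators are pure functions of parameters and seed", {
  a1 <- gen_annotation(11L); a2 <- gen_annotation(11L)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(a1$models, f1); write_gtf(a2$models, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  d <- null_design(3, seed = 9, n_cell_lines = 4)
  expect_identical(gen_counts(d)$counts, gen_counts(d)$counts)
  s <- gen_spikein_reads(spikein_ladder(), 10, 1e4, seed = 3)
  expect_identical(s$counts, gen_spikein_reads(spikein_ladder(), 10, 1e4,
                                               seed = 3)$counts)
})

test_that("observed proportions converge to designed proportions", {
  g <- sim_gene("g1", c(0.5, 0.3, 0.2))
  d <- sim_design(list(g), n_cell_lines = 10, seed = 2, depth_mean = 1e5,
                  depth_dispersion = 0, proportion_concentration = 1e7)
  cm <- gen_counts(d)
  obs <- sweep(cm$counts, 2, colSums(cm$counts), "/")
  expect_lt(mean(abs(obs - g$baseline)), 0.01)
})

test_that("a planted single-line aberrant shift dominates in both replicates", {
  hits <- 0L
  for (seed in 1:100) {
    g <- sim_gene("g1", c(0.6, 0.3, 0.1),
                  aberrant_effect = list(isoform = "g1_iso2",
                                         cell_lines = "line03", delta = 0.4))
    cm <- gen_counts(sim_design(list(g), n_cell_lines = 10, seed = seed,
                                depth_mean = 1e4))
    pr <- cm$counts["g1_iso2", ] / colSums(cm$counts)
    planted <- grepl("^line03_", names(pr))
    if (min(pr[planted]) > max(pr[!planted])) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("without planted effects, per-line proportions are exchangeable", {
  pvals <- vapply(1:60, function(seed) {
    cm <- gen_counts(null_design(1, seed = seed, n_cell_lines = 8,
                                 depth_mean = 5000))
    pr <- cm$counts[2, ] / colSums(cm$counts)
    kruskal.test(pr, factor(unname(cm$replicate_map)))$p.value
  }, numeric(1))
  # Kruskal-Wallis p-values should look uniform under the null
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("gene totals match the negative-binomial noise model", {
  mu <- 2000; phi <- 0.1
  d <- null_design(1, seed = 31, n_cell_lines = 5000, n_replicates = 2,
                   depth_mean = mu, depth_dispersion = phi)
  tot <- colSums(gen_counts(d)$counts)
  n <- length(tot)
  sd_mean <- sqrt(mu + phi * mu^2) / sqrt(n)
  expect_lt(abs(mean(tot) - mu), 3 * sd_mean)
  expect_gt(var(tot), 0.9 * (mu + phi * mu^2))
  expect_lt(var(tot), 1.1 * (mu + phi * mu^2))
})

test_that("planted effects outside the simplex are rejected", {
  g <- sim_gene("g1", c(0.8, 0.2),
                aberrant_effect = list(isoform = "g1_iso2",
                                       cell_lines = "line01", delta = 0.9))
  expect_error(gen_counts(sim_design(list(g), n_cell_lines = 2, seed = 1)),
               "outside")
})

test_that("spike-in counts follow concentration and enrichment", {
  lad <- spikein_ladder()
  expect_gte(length(unique(lad$concentration)), 6L)
  expect_gt(max(lad$concentration) / min(lad$concentration), 1e6)
  # no enrichment: targeted and untargeted at one concentration have equal
  # expected counts
  s <- gen_spikein_reads(lad, enrichment_fold = 1, depth = 2e5,
                         n_replicates = 50, seed = 4)
  top <- lad$concentration == max(lad$concentration)
  m_t <- mean(s$counts[top & lad$targeted, ])
  m_u <- mean(s$counts[top & !lad$targeted, ])
  expect_lt(abs(m_t - m_u) / m_u, 0.05)
  expect_true(all(gen_spikein_reads(lad, 10, depth = 0, seed = 1)$counts == 0))
  expect_error(gen_spikein_reads(lad, enrichment_fold = 0.5))
})

test_that("alignment summaries reproduce the requested on-target fraction", {
  expect_equal(on_target_rate(gen_alignment_summary(1, n_reads = 1000,
                                                    seed = 1)), 1)
  aln <- gen_alignment_summary(0.65, n_reads = 1e6, seed = 8)
  expect_lt(abs(on_target_rate(aln) - 0.65), 0.002)
  all_zero <- gen_alignment_summary(0.5, mapq_distribution = c("0" = 1),
                                    n_reads = 100, seed = 1)
  expect_error(on_target_rate(all_zero), "mapq")
})
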