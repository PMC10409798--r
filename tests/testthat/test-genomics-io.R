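test_that("GTF coordinates convert from 1-based inclusive to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  models <- read_gtf(gtf)
  expect_length(models, 1L)
  expect_equal(models$t1$exons, data.frame(start = c(100L, 300L),
                                           end = c(200L, 400L)))
  expect_equal(models$t1$annotation_status, "novel")
  expect_false(models$t1$is_canonical)
})

test_that("exon order in the GTF does not matter", {
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  l1 <- 'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  l2 <- 'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  writeLines(c(l1, l2), f1); writeLines(c(l2, l1), f2)
  expect_equal(read_gtf(f1), read_gtf(f2))
})

test_that("GTF round-trip is lossless on all transcript fields", {
  models <- gen_annotation(7L)$models
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(models, f1)
  back <- read_gtf(f1)
  expect_equal(back[names(models)], models)
  write_gtf(back, f2)
  expect_equal(readLines(f1), readLines(f2))
})

test_that("malformed or invalid GTF records are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id "g"; transcript_id "t";',
             bad)
  expect_error(read_gtf(bad))
  noattr <- tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\texon\t100", noattr)
  expect_error(read_gtf(noattr))
  expect_error(transcript_model("t", "g", "c", "+", 100, 100))
  expect_error(transcript_model("t", "g", "c", "*", 100, 200))
  expect_error(transcript_model("t", "g", "c", "+", c(0, 50), c(100, 150)),
               "overlap")
})

test_that("spliced_sequence concatenates exons and honors strand", {
  genome <- c(chr1 = "AAATTGGG", chr2 = "ATGC")
  t_plus <- transcript_model("tp", "g", "chr1", "+", c(0, 5), c(3, 8))
  expect_equal(spliced_sequence(genome, t_plus), "AAAGGG")
  t_minus <- transcript_model("tm", "g", "chr2", "-", 0, 4)
  expect_equal(spliced_sequence(genome, t_minus), "GCAT")
  expect_error(spliced_sequence(genome, transcript_model("tx", "g", "chrZ",
                                                         "+", 0, 2)),
               "chrZ")
})

test_that("spliced length equals the exon-length sum on random toys", {
  set.seed(42)
  genome <- c(chrR = random_dna(5000))
  for (i in 1:20) {
    n_ex <- sample(1:6, 1)
    starts <- sort(sample(seq(0, 4800, by = 10), n_ex))
    ends <- starts + sample(5:9, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    t <- transcript_model("t", "g", "chrR", strand, starts, ends)
    expect_equal(nchar(spliced_sequence(genome, t)), transcript_length(t))
  }
})

test_that("splice_junctions yields n-1 introns filling inter-exon gaps", {
  single <- transcript_model("t", "g", "c", "+", 100, 700)
  expect_equal(nrow(splice_junctions(single)), 0L)
  two <- transcript_model("t", "g", "c", "+", c(100, 300), c(200, 400))
  expect_equal(splice_junctions(two), data.frame(start = 200L, end = 300L))
  five <- transcript_model("t", "g", "c", "+", seq(0, 800, 200),
                           seq(100, 900, 200))
  j <- splice_junctions(five)
  expect_equal(nrow(j), 4L)
  expect_equal(j$start, five$exons$end[1:4])
  expect_equal(j$end, five$exons$start[2:5])
})

test_that("count matrix TSV round-trips and invariants are enforced", {
  cm <- gen_counts(null_design(3, seed = 5, n_cell_lines = 4))
  fs <- replicate(3, tempfile(fileext = ".tsv"))
  write_count_matrix(cm, fs[1], fs[2], fs[3])
  back <- read_count_matrix(fs[1], fs[2], fs[3])
  expect_equal(back$counts, cm$counts)
  expect_equal(back$mapped_totals, cm$mapped_totals)
  expect_equal(back$replicate_map, cm$replicate_map)
  # mapped totals below the assigned counts violate the container invariant
  m <- matrix(10, 1, 2, dimnames = list("i1", c("a_r1", "a_r2")))
  expect_error(count_matrix(m, "g1", c(a_r1 = 5, a_r2 = 20),
                            c(a_r1 = "a", a_r2 = "a")), "mapped_totals")
  expect_error(count_matrix(-m, "g1", c(a_r1 = 50, a_r2 = 50),
                            c(a_r1 = "a", a_r2 = "a")), "non-negative")
})
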