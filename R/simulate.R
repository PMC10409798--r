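# Seeded generators for annotations, sequences, spike-in ladders, alignment
# summaries, and count matrices with the statistical structure the
# downstream stages assume. All generators are pure functions of
# (parameters, seed).

#' Simulated gene description
#'
#' Describes one gene of a simulated panel: its isoforms, baseline isoform
#' proportions (shared by every cell line), and optional planted effects. A
#' subtype effect shifts one isoform's proportion by `delta` in every cell
#' line of one subtype; an aberrant effect shifts it in an explicit small set
#' of cell lines (the outlier structure the aberrant-isoform procedure is
#' built to find). Effects are additive on the proportion scale with the
#' remaining mass rescaled proportionally.
#'
#' @param gene_id gene identifier.
#' @param baseline numeric probability vector of isoform proportions; names
#'   are used as isoform ids (default `<gene>_iso1..k`).
#' @param subtype_effect `NULL` or `list(isoform=, subtype=, delta=)`.
#' @param aberrant_effect `NULL` or `list(isoform=, cell_lines=, delta=)`;
#'   at least one cell line.
#' @param canonical_isoform id of the canonical isoform (default: the first).
#' @return An object of class `sim_gene`.
#' @export
sim_gene <- function(gene_id, baseline = c(0.7, 0.2, 0.07, 0.03),
                     subtype_effect = NULL, aberrant_effect = NULL,
                     canonical_isoform = NULL) {
  if (abs(sum(baseline) - 1) > 1e-8 || any(baseline < 0))
    stop("baseline must be a probability vector")
  if (is.null(names(baseline)))
    names(baseline) <- paste0(gene_id, "_iso", seq_along(baseline))
  if (!is.null(aberrant_effect) && length(aberrant_effect$cell_lines) < 1L)
    stop("aberrant_effect needs at least one cell line")
  structure(list(gene_id = gene_id, baseline = baseline,
                 subtype_effect = subtype_effect,
                 aberrant_effect = aberrant_effect,
                 canonical_isoform = canonical_isoform %||% names(baseline)[1L]),
            class = "sim_gene")
}

#' Simulation design for multi-cell-line isoform count matrices
#'
#' The default design mirrors the study layout this package targets: a panel
#' of 40 cell lines in 4 subtypes (9/13/11/7 lines) with 2 replicates each.
#' Per gene and sample, the gene read total is negative-binomial
#' (`depth_mean`, dispersion `depth_dispersion`, variance
#' `mu + phi * mu^2`) and the isoform split is Dirichlet-multinomial:
#' replicate proportions are drawn from
#' `Dirichlet(proportion_concentration * p_line)` so they stay on the
#' simplex, then counts are multinomial.
#'
#' @param genes list of [sim_gene()].
#' @param n_cell_lines number of cell lines.
#' @param n_replicates replicates per cell line (>= 1).
#' @param subtype_assignment named character vector cell line -> subtype;
#'   default partitions lines into 4 subtypes sized 9/13/11/7 (scaled for
#'   other panel sizes).
#' @param depth_mean,depth_dispersion negative-binomial parameters of the
#'   per-gene, per-sample read total.
#' @param proportion_concentration Dirichlet concentration scaling
#'   replicate-to-replicate proportion noise (larger = tighter).
#' @param off_target_fraction fraction of mapped reads not assigned to panel
#'   isoforms; per-sample mapped totals are column sums divided by
#'   `1 - off_target_fraction`.
#' @param seed integer seed.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(genes, n_cell_lines = 40L, n_replicates = 2L,
                       subtype_assignment = NULL,
                       depth_mean = 2000, depth_dispersion = 0.1,
                       proportion_concentration = 200,
                       off_target_fraction = 0.3, seed = 1L) {
  stopifnot(n_replicates >= 1L, proportion_concentration > 0,
            off_target_fraction >= 0, off_target_fraction < 1)
  lines <- sprintf("line%02d", seq_len(n_cell_lines))
  if (is.null(subtype_assignment)) {
    sizes <- diff(c(0L, round(cumsum(c(9, 13, 11, 7) / 40) * n_cell_lines)))
    subtype_assignment <- setNames(
      rep(c("luminal", "her2", "basalA", "basalB"), times = sizes), lines)
  }
  structure(list(genes = genes, n_cell_lines = n_cell_lines,
                 n_replicates = n_replicates, cell_lines = lines,
                 subtype_assignment = subtype_assignment,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 proportion_concentration = proportion_concentration,
                 off_target_fraction = off_target_fraction,
                 seed = as.integer(seed)),
            class = "sim_design")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1   # degenerate guard
  g / sum(g)
}

# apply an additive proportion shift to one isoform, rescaling the others
shift_proportions <- function(p, isoform, delta) {
  i <- match(isoform, names(p))
  if (is.na(i)) stop("effect isoform not in baseline: ", isoform)
  pn <- p
  pn[i] <- p[i] + delta
  if (pn[i] < 0 || pn[i] > 1)
    stop("planted effect pushes proportion outside [0,1]")
  rest <- sum(p[-i])
  if (rest > 0) pn[-i] <- p[-i] * (1 - pn[i]) / rest
  pn
}

#' Generate an isoform count matrix from a simulation design
#'
#' @param design a [sim_design()].
#' @return A [count_matrix()] whose rows are all isoforms of all design
#'   genes; attribute `"design"` carries the design used.
#' @export
gen_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    lines <- design$cell_lines
    samples <- as.vector(t(outer(lines, seq_len(design$n_replicates),
                                 function(l, r) paste0(l, "_r", r))))
    replicate_map <- setNames(rep(lines, each = design$n_replicates), samples)
    size <- if (design$depth_dispersion > 0) 1 / design$depth_dispersion else Inf
    blocks <- lapply(design$genes, function(g) {
      m <- length(g$baseline)
      # per-line true proportion vectors with planted effects
      pline <- lapply(lines, function(l) {
        p <- g$baseline
        se <- g$subtype_effect
        if (!is.null(se) && design$subtype_assignment[[l]] == se$subtype)
          p <- shift_proportions(p, se$isoform, se$delta)
        ae <- g$aberrant_effect
        if (!is.null(ae) && l %in% ae$cell_lines)
          p <- shift_proportions(p, ae$isoform, ae$delta)
        p
      })
      names(pline) <- lines
      cnt <- matrix(0L, nrow = m, ncol = length(samples),
                    dimnames = list(names(g$baseline), samples))
      for (s in seq_along(samples)) {
        tot <- if (is.finite(size))
          rnbinom(1L, size = size, mu = design$depth_mean)
        else rpois(1L, design$depth_mean)
        if (tot == 0) next
        p <- rdirichlet1(design$proportion_concentration *
                           pline[[replicate_map[[samples[s]]]]])
        cnt[, s] <- rmultinom(1L, tot, p)
      }
      cnt
    })
    counts <- do.call(rbind, blocks)
    gene_ids <- rep(vapply(design$genes, function(g) g$gene_id, character(1)),
                    vapply(design$genes, function(g) length(g$baseline),
                           integer(1)))
    totals <- colSums(counts) / (1 - design$off_target_fraction)
    totals[totals == 0] <- 1   # keep CPM defined for empty columns
    cm <- count_matrix(counts, gene_ids, setNames(totals, samples),
                       replicate_map,
                       subtype_map = design$subtype_assignment)
    attr(cm, "design") <- design
    cm
  })
}

#' Spike-in concentration ladder
#'
#' A synthetic ladder in the spirit of the ERCC standards: `n_levels`
#' two-fold-spaced concentrations starting at `base` amol/ul (22 levels span
#' more than six orders of magnitude), `per_level` transcripts per level,
#' half of them flagged as capture targets.
#'
#' @param n_levels number of concentration levels.
#' @param per_level transcripts per level (targeted/untargeted alternate).
#' @param base lowest concentration, amol/ul.
#' @return Data frame with columns `transcript_id`, `concentration`,
#'   `targeted`.
#' @export
spikein_ladder <- function(n_levels = 22L, per_level = 4L, base = 0.18) {
  conc <- base * 2^(seq_len(n_levels) - 1L)
  data.frame(
    transcript_id = sprintf("SPIKE_%02d_%d", rep(seq_len(n_levels),
                                                 each = per_level),
                            rep(seq_len(per_level), n_levels)),
    concentration = rep(conc, each = per_level),
    targeted = rep(c(TRUE, FALSE), length.out = n_levels * per_level))
}

#' Simulate spike-in read counts under capture enrichment
#'
#' Expected reads are proportional to `concentration * enrichment_fold` for
#' targeted transcripts and to `concentration` otherwise, scaled so the
#' expected per-replicate total equals `depth`; observed counts are Poisson.
#'
#' @param ladder a [spikein_ladder()]-style data frame (`concentration > 0`).
#' @param enrichment_fold capture enrichment factor (>= 1).
#' @param depth expected total reads per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return List with `counts` (transcripts x replicates integer matrix) and
#'   `ladder` (the input table).
#' @export
gen_spikein_reads <- function(ladder, enrichment_fold = 1, depth = 1e5,
                              n_replicates = 3L, seed = 1L) {
  stopifnot(enrichment_fold >= 1, all(ladder$concentration > 0))
  with_seed(seed, {
    w <- ladder$concentration * ifelse(ladder$targeted, enrichment_fold, 1)
    mu <- if (depth > 0) depth * w / sum(w) else rep(0, length(w))
    counts <- matrix(rpois(length(mu) * n_replicates, rep(mu, n_replicates)),
                     ncol = n_replicates,
                     dimnames = list(ladder$transcript_id,
                                     paste0("rep", seq_len(n_replicates))))
    list(counts = counts, ladder = ladder)
  })
}

#' Simulate a per-read alignment summary
#'
#' Emits one row per read with a Bernoulli on-target flag and a mapping
#' quality drawn from `mapq_distribution`, the input consumed by
#' [on_target_rate()].
#'
#' @param on_target_fraction probability a read maps to a target gene.
#' @param mapq_distribution named numeric vector of probabilities over MAPQ
#'   values (names are the values); default 5% MAPQ 0, 95% MAPQ 60.
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return Data frame `read_id`, `target` (logical), `mapq` (integer).
#' @export
gen_alignment_summary <- function(on_target_fraction,
                                  mapq_distribution = c("0" = 0.05,
                                                        "60" = 0.95),
                                  n_reads = 1e5, seed = 1L) {
  stopifnot(on_target_fraction >= 0, on_target_fraction <= 1)
  with_seed(seed, {
    data.frame(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      target = runif(n_reads) < on_target_fraction,
      mapq = as.integer(sample(names(mapq_distribution), n_reads,
                               replace = TRUE, prob = mapq_distribution)))
  })
}

# ---- toy gene-model generator -----------------------------------------

# background sequence free of ATG so the only ORFs are the planted ones
background_seq <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  destroy_atg(s)
}

destroy_atg <- function(s, keep = integer(0)) {
  repeat {
    txt <- paste0(s, collapse = "")
    hits <- gregexpr("ATG", txt, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0 & !(hits %in% keep)]
    if (length(hits) == 0L) break
    s[hits + 2L] <- "C"   # ATG -> ATC; cannot create ATG or a stop codon
  }
  s
}

# spliced-position -> 0-based chromosome-position map (plus strand)
tx_map <- function(starts, ends) {
  unlist(mapply(function(a, b) seq.int(a, b - 1L), starts, ends,
                SIMPLIFY = FALSE))
}

is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# replace stop codons with CAC in the reading frame anchored at spliced
# position `atg` (0-based), over spliced codons fully inside [from, to)
clear_stops <- function(s, map, atg, from, to) {
  for (p in seq.int(atg, to - 3L, by = 3L)) {
    if (p < from) next
    idx <- map[(p + 1L):(p + 3L)] + 1L
    if (is_stop(paste0(s[idx], collapse = ""))) s[idx] <- c("C", "A", "C")
  }
  s
}

plant <- function(s, map, pos, codon) {
  s[map[(pos + 1L):(pos + nchar(codon))] + 1L] <-
    strsplit(codon, "")[[1L]]
  s
}

#' Generate toy gene models covering every AS category
#'
#' Builds one gene per alternative-splicing category -- exon skipping,
#' alternative 5'/3' splice site, mutually exclusive exons, intron
#' retention, alternative first/last exon -- plus one "complex" case, one
#' "combinatorial" case (two independent events), one retained-intron gene
#' whose intron carries an in-frame premature termination codon targeted by
#' the 50-nt NMD rule, and one single-exon gene. Each gene sits on its own
#' chromosome; background sequence is generated free of ATG and a single
#' deterministic ATG...stop ORF is planted per design, so longest-ORF ground
#' truth is exact.
#'
#' @param seed integer seed (backgrounds only; coordinates are fixed).
#' @return List with `models` (named list of [transcript_model()]),
#'   `genome` (a [Biostrings::DNAStringSet]), and `truth` (data frame:
#'   `gene_id`, `category`, `canonical_id`, `alt_id`).
#' @export
gen_annotation <- function(seed = 1L) {
  with_seed(seed, {
    specs <- list(
      list(gene = "g_es", category = "exon_skipping", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
           alt = list(c(100, 200), c(500, 600), c(700, 800))),
      list(gene = "g_a5", category = "alt_5ss", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
           alt = list(c(100, 230), c(300, 400), c(500, 600), c(700, 800))),
      list(gene = "g_a3", category = "alt_3ss", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
           alt = list(c(100, 200), c(330, 400), c(500, 600), c(700, 800))),
      list(gene = "g_mx", category = "mutually_exclusive_exons", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(700, 800)),
           alt = list(c(100, 200), c(500, 600), c(700, 800))),
      list(gene = "g_ir", category = "intron_retention", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
           alt = list(c(100, 200), c(300, 600), c(700, 800))),
      list(gene = "g_af", category = "alt_first_exon", len = 800L,
           canon = list(c(100, 200), c(300, 400), c(500, 600)),
           alt = list(c(0, 50), c(300, 400), c(500, 600))),
      list(gene = "g_al", category = "alt_last_exon", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600)),
           alt = list(c(100, 200), c(300, 400), c(700, 800))),
      list(gene = "g_cx", category = "complex", len = 1000L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
           alt = list(c(100, 200), c(320, 420), c(500, 600), c(700, 800))),
      list(gene = "g_cb", category = "combinatorial", len = 1100L,
           canon = list(c(100, 200), c(300, 400), c(500, 600), c(700, 800),
                        c(900, 1000)),
           alt = list(c(100, 200), c(500, 600), c(700, 1000))),
      list(gene = "g_ptc", category = "ptc_intron_retention", len = 900L,
           canon = list(c(100, 250), c(350, 500), c(600, 760)),
           alt = list(c(100, 500), c(600, 760))),
      list(gene = "g_se", category = "single_exon", len = 800L,
           canon = list(c(100, 700)), alt = NULL))
    models <- list()
    seqs <- character(0)
    truth <- list()
    for (sp in specs) {
      chrom <- paste0("chr_", sp$gene)
      s <- background_seq(sp$len)
      c_starts <- vapply(sp$canon, `[`, numeric(1), 1L)
      c_ends <- vapply(sp$canon, `[`, numeric(1), 2L)
      cmap <- tx_map(c_starts, c_ends)
      clen <- length(cmap)
      if (sp$gene == "g_ptc") {
        # ORF starts at spliced position 9 of both isoforms (shared exon 1).
        # In the retained-intron isoform the frame runs into the intron and
        # hits a TAA planted 247 nt upstream of its single junction; in the
        # canonical isoform the intron is spliced out and the ORF runs to a
        # stop planted near the transcript 3' end.
        a_starts <- vapply(sp$alt, `[`, numeric(1), 1L)
        a_ends <- vapply(sp$alt, `[`, numeric(1), 2L)
        amap <- tx_map(a_starts, a_ends)
        s <- plant(s, cmap, 9L, "ATG")
        s <- clear_stops(s, amap, 9L, 12L, 150L)           # exon 1 + into IR
        s <- plant(s, amap, 150L, "TAA")                   # inside the intron
        s <- clear_stops(s, cmap, 9L, 12L, 441L)           # canonical frame
        s <- plant(s, cmap, 441L, "TAA")
        s <- destroy_atg(s, keep = cmap[10L] + 1L)
        stopifnot(paste0(s[(cmap[10L] + 1L):(cmap[12L] + 1L)],
                         collapse = "") == "ATG")
      } else {
        stop_at <- 3L + 3L * ((clen - 33L) %/% 3L)
        s <- plant(s, cmap, 3L, "ATG")
        s <- clear_stops(s, cmap, 3L, 6L, stop_at)
        s <- plant(s, cmap, stop_at, "TAA")
        s <- destroy_atg(s, keep = cmap[4L] + 1L)
      }
      can_id <- paste0(sp$gene, "_canon")
      models[[can_id]] <- transcript_model(
        can_id, sp$gene, chrom, "+", c_starts, c_ends, is_canonical = TRUE,
        annotation_status = "annotated_basic_or_nmd")
      alt_id <- NA_character_
      if (!is.null(sp$alt)) {
        alt_id <- paste0(sp$gene, "_alt")
        models[[alt_id]] <- transcript_model(
          alt_id, sp$gene, chrom, "+",
          vapply(sp$alt, `[`, numeric(1), 1L),
          vapply(sp$alt, `[`, numeric(1), 2L),
          annotation_status = "novel")
      }
      seqs[chrom] <- paste0(s, collapse = "")
      truth[[sp$gene]] <- data.frame(gene_id = sp$gene,
                                     category = sp$category,
                                     canonical_id = can_id, alt_id = alt_id)
    }
    list(models = models, genome = Biostrings::DNAStringSet(seqs),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Simulation design over the toy annotation
#'
#' Convenience wrapper building a [sim_design()] whose genes are the
#' two-isoform genes of [gen_annotation()], with one planted aberrant
#' isoform and one planted subtype-associated isoform, for end-to-end
#' demonstrations.
#'
#' @param ann result of [gen_annotation()].
#' @param seed integer seed.
#' @param ... passed to [sim_design()].
#' @return A [sim_design()].
#' @export
demo_design <- function(ann, seed = 1L, ...) {
  two_iso <- ann$truth[!is.na(ann$truth$alt_id), ]
  genes <- lapply(seq_len(nrow(two_iso)), function(i) {
    g <- two_iso[i, ]
    baseline <- setNames(c(0.8, 0.2), c(g$canonical_id, g$alt_id))
    eff_ab <- if (g$gene_id == "g_ptc")
      list(isoform = g$alt_id, cell_lines = c("line05"), delta = 0.4)
    eff_st <- if (g$gene_id == "g_es")
      list(isoform = g$alt_id, subtype = "basalA", delta = 0.3)
    sim_gene(g$gene_id, baseline, subtype_effect = eff_st,
             aberrant_effect = eff_ab, canonical_isoform = g$canonical_id)
  })
  sim_design(genes, seed = seed, ...)
}
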