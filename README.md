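# isopanel

Downstream analysis of **targeted long-read RNA sequencing** of gene
panels. Capture-based long-read protocols sequence full-length cDNAs of a
few hundred preselected genes at high depth, which makes isoform-level
questions tractable that whole-transcriptome nanopore sequencing cannot
answer: which isoforms a gene expresses, in what proportions, which of
them are private outliers of individual samples, what splicing change
produced them, and whether they are predicted nonsense-mediated-decay
(NMD) targets. `isopanel` takes the output of a long-read isoform
quantifier — an isoform × sample read-count matrix plus per-sample mapped
totals, a GTF annotation, and genome FASTA — and provides the statistics
and sequence analyses for a multi-sample panel study, together with a
seeded synthetic-data generator that reproduces the statistical structure
every stage assumes.

## What it computes

* **Quantification** — CPM (`count / mapped_total × 10⁶`), gene CPM,
  isoform proportions (undefined, not zero, where a gene is unexpressed);
  on-target rate (MAPQ ≥ 1 in numerator and denominator), capture fold
  enrichment, and consistent spike-in detection limits.
* **Percent spliced in** — for a cassette exon, ψ = I/(I+S) where I sums
  CPM over isoforms carrying *both* inclusion junctions and S over
  isoforms carrying the skipping junction; a junction-count short-read
  surrogate; and a four-rule high-confidence event filter.
* **Subtype-associated isoforms** — per (isoform, subtype) two-sided
  Student's *t*-tests on replicate-level proportions, BH FDR ≤ 5%, and a
  ≥ 10% absolute proportion delta.
* **Tumor-aberrant isoforms** — a three-stage outlier procedure: per-gene
  chi-square homogeneity screen (FDR < 1%), exact one-tailed binomial
  post hoc per (isoform, sample) against the gene's overall proportion
  p₀ (FDR < 1%), then calls requiring *both* replicates of a line to pass
  with proportion ≥ p₀ + 0.10, recurrence in ≤ 10% of the panel, and a
  non-canonical isoform.
* **AS classification** — structural comparison against the canonical
  isoform into exon skipping, alt 5'/3' splice site, mutually exclusive
  exons, intron retention, alt first/last exon, "complex", or
  "combinatorial" (≥ 2 events).
* **NMD prediction** — longest sense-strand ORF (≥ 20 aa), then the 50-nt
  rule: ≥ 200 nt, ≥ 1 junction, stop ≥ 50 nt upstream of the last
  junction; plus TSG/OG/Other category-enrichment summaries (Fisher,
  paired Wilcoxon).
* **Probe design** — 1×-tiling of 120-nt capture-probe windows over each
  gene's exonic union, 150-nt synthesis oligos with a 30-nt universal
  adapter (reverse-complement identity enforced), and probe-yield
  reaction-capacity arithmetic.

## Worked example

The demo pipeline simulates a 40-cell-line, 2-replicate panel over toy
gene models (one gene per AS category) with one planted aberrant isoform
and one planted subtype-associated isoform, then recovers both:

```r
library(isopanel)
ann    <- gen_annotation(seed = 1)
design <- demo_design(ann, seed = 1, depth_mean = 1e4)
cm     <- gen_counts(design)
cm
#> <count_matrix> 20 isoforms (10 genes) x 80 samples, 40 cell line(s)

canon <- names(ann$models)[sapply(ann$models, `[[`, "is_canonical")]
find_aberrant_isoforms(cm, canonical_ids = canon)
#>   isoform_id gene_id cell_lines n_lines
#> 1  g_ptc_alt   g_ptc     line05       1
```

The planted outlier (`g_ptc_alt`, elevated by 0.40 in `line05` only) is
the only call: it passed the chi-square screen, the binomial post hoc in
both replicates of `line05`, and the ≥ 10% excess rule. Classifying it
against the canonical isoform and predicting NMD:

```r
classify_isoforms(ann$models, "g_ptc_alt")
#>   isoform_id gene_id           events            label
#> 1  g_ptc_alt   g_ptc intron_retention intron_retention

subset(predict_nmd(ann$models, ann$genome), isoform_id == "g_ptc_alt")
#>    isoform_id gene_id          route is_nmd reasons
#> 20  g_ptc_alt   g_ptc needs_orf_scan   TRUE
```

The aberrant isoform retains an intron carrying an in-frame premature
termination codon ≥ 50 nt upstream of its last junction, so it is
predicted NMD-targeted — the canonical mechanism by which an outlier
isoform silences its gene. The planted subtype shift is recovered by the
proportion *t*-tests:

```r
st <- find_subtype_associated(isoform_proportion(cpm(cm)),
                              cm$replicate_map, cm$subtype_map)
subset(st, called)[, c("isoform_id", "subtype", "delta", "fdr")]
#>   isoform_id subtype     delta          fdr
#> 3 g_es_canon    her2 0.1301323 1.204817e-03
#> 5   g_es_alt  basalA 0.3090656 3.209051e-55
```

`g_es_alt` was planted at +0.30 in the basalA subtype (delta 0.309,
FDR ~ 1e-55); the reciprocal depletion makes the canonical isoform
relatively elevated elsewhere, a real consequence of proportions summing
to one. Finally, the probe-yield arithmetic:

```r
reaction_capacity(25, 100, 2, 200)[c("reactions_per_synthesis", "total_reactions")]
#> $reactions_per_synthesis
#> [1] 250
#> $total_reactions
#> [1] 25000
```

25 µg of probe per synthesis at 100 ng per capture supports 250 capture
reactions; a 200-ng template pool at 2 ng per synthesis supports 25,000
reactions in total.

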