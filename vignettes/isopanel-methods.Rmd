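---
title: "Methods: targeted long-read isoform panel analysis with isopanel"
author: "isopanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted long-read isoform panel analysis with isopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopanel)
```

## Scope and data model

`isopanel` implements the downstream analysis of targeted long-read RNA
sequencing of gene panels: the input is an isoform-by-sample read-count
matrix (as produced by a long-read isoform quantifier), per-sample total
mapped-read counts, a transcript annotation (GTF), and, for sequence-level
analyses, genome FASTA. Everything upstream — basecalling, alignment, and
isoform discovery itself — is out of scope; the package starts where a
quantifier's count table ends.

Coordinates are 0-based half-open internally; GTF I/O converts to and from
the 1-based inclusive GTF convention, which makes BED emission direct and
keeps interval arithmetic unambiguous. Canonical flags and annotation
status are read from explicit GTF attributes (`canonical`,
`annotation_status`), so synthetic fixtures are self-contained and no
annotation-database lookups are needed.

## Quantification

Counts are normalized to CPM against each sample's **total mapped reads**,
not the column sum, so CPM column sums equal $10^6 \times$
(assigned/mapped) $\le 10^6$. An isoform's proportion is its CPM divided
by the summed CPM of its gene; where the gene is unexpressed the
proportion is *undefined* (`NA`), never zero — this distinction matters
downstream because undefined proportions are excluded from tests rather
than pulling group means toward zero.

On-target rate restricts both numerator and denominator to reads with
mapping quality at least 1; fold enrichment is the ratio of capture to
non-capture on-target rates. The spike-in detection limit is the smallest
ladder concentration $c$ such that *every* evaluated transcript at
concentration $\ge c$ has at least 2 raw reads in *every* replicate. This
is the strictest reading of "detected consistently across replicates"; it
yields a single well-defined threshold that is monotone in capture
enrichment. Log-scale abundance concordance uses a 1-CPM pseudo-count.

## Percent spliced in

For a cassette-exon event defined by its two inclusion introns and the
skipping intron, the long-read estimate is

$$\psi = \frac{I}{I+S}$$

where $I$ sums CPM over isoforms carrying *both* inclusion junctions
(exact intron-coordinate match) and $S$ over isoforms carrying the
skipping junction. Isoforms that include the exon through different
flanking junctions match neither pattern and are deliberately ignored:
junction identity, not exon overlap, defines the event. The short-read
surrogate is a plain junction-count ratio,
$\bar n_{inc} / (\bar n_{inc} + n_{skip})$; no effective-length
normalization is attempted, since the package does not re-implement a
short-read splicing caller.

The high-confidence event filter applies four rules with inclusive
boundaries: support $\ge 10$ on the inclusion average or the skip
junction; inclusion-balance ratio within $[0.2, 5]$ (a one-sided zero
junction fails; a double zero is left to rule 1); $\psi \in [0.01,
0.99]$; and no splice site shared with any other catalog event. The
boundary conventions are recorded so the filter is deterministic and
testable.

## Subtype-associated isoforms

Each (isoform, subtype) pair is tested by a two-sided Student's *t*-test
(pooled variance, per the test's classical definition; Welch is available
behind `var_equal = FALSE`) comparing replicate-level proportions in the
subtype against all other samples. Replicates are treated as independent
observations — the replicate-level group sizes in the motivating design
(18/26/22/14 over four subtypes of a 40-line panel) are twice the line
counts, which is what makes a 5-line subtype testable at all. BH
correction is applied across all executed tests as one family (the
per-subtype family is an option), and a call additionally requires the
subtype mean to exceed the out-group mean by at least 0.10 — an absolute
proportion floor that suppresses statistically significant but
biologically negligible shifts. Zero-variance degenerate fixtures get
$p = 1$ when the group means agree and $p = 0$ otherwise, avoiding 0/0
*t*-statistics.

## Tumor-aberrant isoforms

The three-stage outlier procedure works on per-gene isoform-by-sample
matrices of counts rounded half-away-from-zero (a deterministic "nearest
integer"). Genes with a single isoform or expression in at most one
sample are skipped; unexpressed samples are dropped per gene.

1. **Screen**: Pearson chi-square test of homogeneity on each gene's
   matrix, BH-adjusted over all tested genes, FDR < 1%. No continuity or
   small-count correction is applied — the plain test is the stated
   procedure and the m/sample exclusions are the only low-count guards.
2. **Post hoc**: for each (isoform, sample) pair of screened genes, an
   exact one-tailed binomial upper tail against the overall proportion
   $p_0$ (row sum over grand sum), BH-adjusted globally across all pairs
   (per-gene families behind a flag).
3. **Call**: a cell line qualifies only if *all* of its replicates were
   retained (at least two), each with adjusted $p < 1\%$ *and* proportion
   at least $p_0 + 0.10$. Proportions here are computed from the rounded
   count matrix (count over column total) so that they share a basis with
   $p_0$ and the binomial model — the CPM-based proportion table differs
   only by the assigned/mapped factor. An isoform is called when it
   qualifies in 1 to `max_lines` lines (default $\lceil 0.10 \times
   n_{lines}\rceil$, i.e. 4 of 40) and is not the canonical isoform.

The replicate requirement is the main false-positive guard: under
realistic replicate noise single-replicate excursions are common, but the
probability that both replicates of the same line exceed $p_0 + 0.10$ by
chance is negligible at panel scale (the null-calibration tests verify
zero calls in at least 95% of simulated null panels).

## AS-event classification

An isoform is compared to its gene's canonical isoform. Introns shared at
exact coordinates partition the comparison; each maximal run of
non-shared introns between consecutive shared anchors (or a transcript
terminus) is one local difference, classified independently by
strand-aware rules into exon skipping, alternative 5'/3' splice site,
mutually exclusive exons, intron retention, alternative first/last exon,
or — when no rule fits — "complex". Two or more local differences yield
"combinatorial". Conventions worth stating explicitly:

* one bridging intron spanning any number of whole canonical exons with
  matching outer splice sites is a *single* exon-skipping event (one
  junction, one local difference);
* pure terminal-end length differences with identical junction sets are
  no event — transcription start/poly(A) scatter in long reads is not an
  AS category;
* anchors are exact-coordinate matches, no fuzz window, since inputs are
  consolidated isoform models;
* alternative first/last exon is checked before alternative 5'/3' splice
  site when a region touches the relevant transcript terminus, with
  non-overlapping terminal exons discriminating the two.

Because the region partition is anchored only at shared introns, two
adjacent differences with no shared intron between them form a single
region and classify as complex; this is the package's explicit boundary
between "combinatorial" and "complex".

## NMD prediction

Transcripts annotated as full-length ("basic") coding or NMD-targeted
keep their annotated status; all others are scanned for ORFs on the sense
strand, ATG starts only. `aa_length` counts the codons strictly between
the initiator ATG and the stop codon, so `ATG + 20 codons + stop` sits
exactly at the 20-aa reportability floor; ties between equal-length ORFs
go to the 5'-most start. A transcript is predicted NMD-targeted iff it is
at least 200 nt long, has at least one junction, and the ORF stop lies at
least 50 nt upstream of the last junction — measured from one past the
stop codon to the 3'-most exon–exon boundary in transcript coordinates,
inclusive at 50. The category-enrichment summary counts, per gene
category (TSG/OG/Other, supplied as a table), the fraction of
sufficiently expressed genes (average CPM $\ge 1$ per line in $\ge 10$
lines) with at least one NMD-targeted aberrant isoform, compared by
two-sided Fisher exact tests and per-line paired Wilcoxon tests.

## Probe design

Probes tile the union of all annotated exons of a gene. "1x tiling" is
implemented as abutting 120-nt windows stepping by the probe length, with
the final window re-anchored to end at the block end, so every base of an
eligible block is covered once and at most twice. Blocks of 40–119 nt get
a single centered window extended into flanking genomic sequence; blocks
under 40 nt are skipped with a warning (the upstream design tool used in
practice is proprietary, so this deterministic layout is the package's
own convention and printed per-panel probe counts are not reproduction
targets). Synthesis oligos are the 120-nt target plus a 30-nt 3'
universal adapter; the amplification primer must be the adapter's reverse
complement, an identity `validate_adapters()` enforces. The capacity
arithmetic (`reaction_capacity()`) reproduces the yield bookkeeping: 25
µg of probe per synthesis at 100 ng per capture gives 250 reactions per
synthesis; a 50–200 ng template pool at 2 ng per synthesis gives
6,250–25,000 reactions in total.

## Synthetic data: what it emulates and what it does not

The generator exists so every downstream stage can be tested against
known ground truth at desk scale. Its defaults are fixed once as the
study conditions the package targets:

* 40 cell lines in 4 subtypes (9/13/11/7 lines), 2 replicates each;
* per-gene, per-sample read totals negative binomial with mean 2,000 and
  dispersion 0.1 (targeted panels yield high per-gene depth; dispersion
  is a free parameter, documented, not fitted to any dataset);
* isoform splits Dirichlet-multinomial with concentration 200, i.e.
  replicate proportion noise of roughly 3.5 percentage points at
  $p = 0.5$ — Dirichlet noise keeps proportions on the simplex, matching
  the proportion-based tests;
* baseline proportions dominant-canonical (0.70/0.20/0.07/0.03), the
  typical one-major-isoform gene;
* planted effects are additive on the proportion scale with the
  remaining mass rescaled proportionally, matching the "at least 10%
  higher" absolute-delta convention of the calling rules;
* an off-target read fraction of 0.3 links column sums to mapped totals
  (on-target rates near 70% are typical of captured libraries).

The toy annotation plants one gene per AS category plus complex and
combinatorial cases, a retained-intron gene whose intron carries an
in-frame PTC satisfying the 50-nt rule, and a single-exon gene.
Background sequence is generated free of ATG and a single ORF is planted
per design, so longest-ORF ground truth is exact by construction
(stop-codon clearing uses the replacement codon CAC, which cannot create
a stop codon or an ATG in any reading frame).

What the generator does **not** emulate: read-level errors and truncation
(no FASTQ), length- or GC-dependent capture bias, isoform-assignment
ambiguity in the upstream quantifier, batch structure, or correlated
biology between genes. Passing tests therefore demonstrate that the
statistical procedures behave as specified under their own model
assumptions — not that real nanopore panels meet those assumptions. The
headline numbers of the motivating study (hundreds of aberrant isoforms,
~280x enrichment) derive from real data at sequencing scale and are
context, not desk-scale reproduction targets.

## Numerical and design choices

* Rounding is half-away-from-zero, a deterministic "nearest integer".
* The BH families (one pooled family for subtype tests; global post-hoc
  family across screened genes) follow the single-adjustment reading of
  the procedures; per-subtype and per-gene families are exposed as
  options.
* `detection_limit()` returns `Inf` when no concentration is
  consistently detected, an explicit sentinel rather than `NA`.
* Degenerate gene matrices (all-zero isoform rows) drop the zero rows
  before the chi-square; genes degenerating to one row are skipped.
* Problem sizes in the test-suite simulations (e.g. 200 null panels of
  50 genes; 100 recovery replicates at depth $10^4$; planted-$\psi$
  recovery at depth $10^5$) were chosen as the smallest sizes at which
  the binomial/FDR machinery operates in its intended regime.

## Known limitations

* The chi-square screen assumes multinomial sampling; with
  Dirichlet-multinomial replicate noise it is anti-conservative at high
  depth and acts purely as a screen — the replicate-consistency and
  effect-size rules carry the error control, which is why calibration is
  asserted on final calls, not on screen p-values.
* Junction matching is exact; annotations with slightly shifted splice
  sites (common in error-prone long reads before consolidation) must be
  normalized upstream.
* NMD prediction is the 50-nt rule only; escape mechanisms (last-exon
  PTCs near the junction, long 3' UTRs, re-initiation) are not modeled.
* The probe tiler does no thermodynamic or off-target scoring.
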