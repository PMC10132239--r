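---
title: "Methods: integrating PAR-CLIP binding sites with expression and splicing"
author: "crosslinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating PAR-CLIP binding sites with expression and splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslinkr)
```

# Scope

crosslinkr implements the downstream analyses that connect PAR-CLIP
binding sites of an RNA-binding protein (RBP) to its regulatory output in
matched RNA-seq: where the protein binds (annotation categories, splice-site
metagene, sequence motifs), how reproducible the binding maps are, and what
binding strength predicts about mRNA abundance and alternative splicing
after knockdown. It deliberately consumes the outputs of the standard
upstream tools — cluster calls in a BED-like table, a TPM/fold-change table
from a differential-expression pipeline, an rMATS-style event table — and
never re-implements alignment, cluster calling, quantification or PSI
estimation.

A seeded synthetic-data generator emits all of those inputs with the
statistical structure the analyses assume, so the full pipeline can be
exercised, and its statistical behaviour verified, without any external
data.

# Coordinates and the gene model

Internally all intervals are 1-based closed, the IRanges/GenomicRanges
convention. GTF is read and written natively (also 1-based closed); the
BED-like cluster dialect (`contig, start, end, name, crosslink_reads,
strand, tc_conversions, gene_id`) is 0-based half-open in the file and
converted at the I/O boundary. Round-tripping either format is exact.

The gene model (`annotation_set`) holds genes, transcripts and exons as
validated data frames. Two derived views drive the analyses:

* **Region features** (`region_features()`): per transcript, exonic
  stretches are labelled `cds`, `five_prime_utr`, `three_prime_utr`
  (strand-aware, from the CDS span) or `noncoding_exon` (CDS-free
  transcripts); gaps between consecutive exons are `intron`.
* **Representative transcript** per gene: the transcript with the largest
  exon-union length, ties broken by the lexicographically smallest
  transcript id. Gene-level summaries (architecture, metagene boundaries)
  use it to avoid double-counting isoforms.

# Binding-site annotation

Each cluster is matched strand-aware against the region features. When a
site overlaps several features — across isoforms of one gene or across
genes — one category is chosen deterministically by the precedence

    cds > three_prime_utr > five_prime_utr > noncoding_exon > intron,

ties across genes broken by larger overlap, then smaller gene id. A site
straddling an exon–intron boundary therefore takes the exonic label
regardless of overlap fraction; determinism was preferred over
proportional assignment. Sites overlapping nothing are `intergenic` with
no host gene. The category distribution is reported per site by default;
a crosslink-read-weighted variant is available
(`region_distribution(weight = "reads")`).

A *target* is a gene with at least one assigned site in a replicate; the
*shared target set* is the intersection across replicates. Replicate
concordance compares per-gene sums of T-to-C conversions over the union
of bound genes (absent = 0) and reports both Spearman's rho on the raw
sums and squared Pearson r on log1p-transformed sums, since both
conventions are common. A replicate with zero variance yields NA, not 0.

# K-mer enrichment with matched backgrounds

Foreground counts pool every overlapping k-length window (default k = 5)
of every binding-site sequence; windows containing N are skipped, and T
and U are equivalent. The background is built by matching *each site*
with a random window of identical length drawn uniformly from the
site's region category within its host gene, excluding windows that
overlap the site itself; `B` such replicates (default 100) give an
empirical null count distribution per k-mer, and

$$Z = \frac{\mathrm{obs} - \mathrm{mean}_B}{\mathrm{sd}_B}.$$

Numerical choices:

* The default sd is the sample (divide-by-`B - 1`) estimator;
  `sd_method = "population"` divides by `B`.
* Zero background sd with observed equal to the mean gives Z = 0; zero sd
  with a different observed count gives signed infinity, flagged in a
  `degenerate` column rather than silently clipped.
* Fallback chain when the matched region cannot host a window: any
  feature of the same category in the gene is already the primary pool;
  next the whole gene span (flagged `fallback`); sites that still cannot
  be matched, and intergenic sites, are dropped with a warning.
* Counting pools windows across sites rather than scoring sites
  individually, and the background statistic aggregates each replicate
  before the mean/sd — per-site pairing is not preserved in the
  statistic.

The Z-score is calibrated only when clusters do not re-count shared
sequence: two overlapping foreground sites contribute the same genomic
text twice while their background windows are drawn independently, which
inflates the foreground variance and fattens the Z tails. Real
cluster-calling merges overlapping reads, so clusters are disjoint; the
synthetic generator reproduces that (below), and calibration experiments
use a genome with enough introns that sites stay sparse.

# Metagene profile at 3' splice sites

Eligible boundaries are the transcription-orientation starts of internal
exons (exons preceded by an intron) of each gene's representative
transcript. Around each boundary a window of `upstream` intronic
(default 300 nt, offsets −U..−1) plus `downstream` exonic (default 50 nt,
offsets 0..D−1) positions is laid out in transcript orientation; coverage
at an offset is the fraction of boundaries covered there by at least one
same-strand site. Windows truncated by the gene span contribute only to
their defined offsets, so denominators are per-offset. Coverage is
boolean per boundary by default; a read-weighted mode exists but is off.
No smoothing is applied. When site density saturates coverage, the
profile's argmax is a tie and carries no information — the calibrated
recovery experiment therefore uses sparse sites (below).

# Occupancy (NXPM), fold change, and architecture

Per-gene occupancy is
$$\mathrm{XPM} = \mathrm{reads} \cdot 10^6 / \mathrm{library\ total},
\qquad \mathrm{NXPM} = \mathrm{XPM} / \mathrm{TPM},$$
the crosslinked reads per million normalised by mRNA abundance. Genes
with control TPM below 1 are excluded (division stability; the floor is a
package choice and a parameter). Bins: non-target = zero sites; bound
genes fall into low (0, 20], mid (20, 50], high (50, ∞) — half-open on
the left so NXPM below 1 folds into the low bin. Each bound bin's log2
fold-change distribution is compared with the non-target bin by a
two-sided two-sample Kolmogorov–Smirnov test with asymptotic p-values
(no exact small-n enumeration); per-bin n is reported so users can judge.
The fold change comes from the input table — no DE model is fitted here.

Architecture correlates are Spearman correlations of per-gene site count
against transcript length, exon count, mean exon length, total intron
length and GC content, plus a one-sided Wilcoxon test of GC in the high
bin against non-targets. GC content is computed over the unspliced gene
body by default (configurable to the exon union); N bases count as
non-GC and stay in the denominator.

The qPCR utility computes ΔCt = mean(target) − mean(reference) per
condition, ΔΔCt = ΔCt(treated) − ΔCt(control), and returns 2^−ΔΔCt;
swapping conditions inverts the fold change exactly.

# Splicing-event filtering

Events are retained when total inclusion-plus-skipping junction reads
summed over both conditions are at least 5, |ΔPSI| ≥ 0.10, and FDR < 0.05
(strict). The read rule is configurable to a per-condition minimum, since
rMATS reports per-sample counts and either reading is defensible. ΔPSI is
knockdown minus control, so positive values mean exon inclusion upon
knockdown. The FDR is taken from the input table without re-adjustment;
MXE events use the reported inclusion-isoform PSI without special-casing.
Rows whose ΔPSI disagrees with the per-condition PSI difference beyond
0.01 are flagged, not dropped. The filter is idempotent and shrinks
monotonically as any threshold tightens; both properties are tested.

# The synthetic generator

One seeded configuration (`synthetic_config()`) drives four generators
(genome+annotation, cluster replicates, expression, splicing); a fixed
seed reproduces every output byte-for-byte, and per-module seeds are
derived from stream names so adding a stage never perturbs another.

What it emulates, with the defaults that define the study conditions:

* **Gene structure**: 2–8 exons per gene (uniform), negative-binomial
  exon (~150 nt) and intron (~1000 nt) lengths, 10% CDS-free genes,
  uniform base composition at GC 0.5 with target gene bodies shifted by
  −0.05 (AT-rich targets, as expected for an RRM-binding protein).
* **Binding sites**: half the genes are targets; 10,000 sites of 41 nt
  are allocated to targets in proportion to gene length; 70% intronic,
  with the gap between a site's 3' edge and the downstream exon start
  exponential with 30 nt decay (polypyrimidine-tract-proximal binding);
  exonic sites uniform. Placement is *hard-core*: each site retries
  against already-placed sites, then falls back to a uniform position,
  and only overlaps when a gene saturates — cluster callers merge
  overlapping reads, so real cluster lists are disjoint. Fallback draws
  are flagged (`placement_law`), because they follow a uniform, not
  exponential, law.
* **Motif**: a pyrimidine 5-mer (TCTTC) is written into the genome at
  30% of site centres, strand-aware, *before* the FASTA is emitted, so
  enrichment is discoverable from sequence exactly as in real data.
* **Reads**: per-site lognormal strength shared across the three
  replicates (this, not a tuned correlation, produces the high
  replicate concordance), negative-binomial per-replicate reads, 5%
  per-replicate site dropout, T-to-C conversions binomial with 70%
  specificity.
* **Expression**: lognormal TPM normalised to 10^6; log2 fold change
  −0.15 per occupancy bin (non-target, low, mid, high = 0..3) plus
  Gaussian noise (sd 0.4); adjusted p generated (uniform under null,
  left-skewed beta under effect) — a DE model is out of scope.
* **Splicing**: background events across all genes and five event types
  (SE-major) with near-zero ΔPSI and uniform FDR; planted skipped-exon
  events pass the filter by construction, live in bound genes with
  probability 0.75, and have positive ΔPSI with probability 0.66 when in
  a bound gene (sign-balanced otherwise).

**Balanced-bins mode.** Recovery experiments need equal genes per
occupancy bin. NXPM is invariant to rescaling the library, so planned
per-gene NXPM values cannot be reached by scaling reads alone; the
balanced mode instead constructs reads and TPM jointly — reads = NXPM ×
TPM with Σ(NXPM·TPM) over bound genes equal to 10^6 — which makes the
measured NXPM equal the planned in-bin draws exactly up to read noise.
In-bin draws keep a margin from the 20/50 edges so per-replicate read
noise cannot move a gene across a bin boundary.

What the generator does **not** emulate: genome composition beyond i.i.d.
bases (no repeats, no codon structure, no real polypyrimidine tracts
beyond the planted motif), alternative isoforms (one transcript per
gene), crosslink-site sequence bias, mapping artefacts, batch effects,
and any coupling between expression level and binding other than the
planted occupancy–fold-change slope. Passing recovery tests therefore
demonstrates that the *statistics* behave as designed — calibration of
the Z-score, exactness of the filter, monotonicity of the KS ordering —
not that the biology of any particular dataset will reproduce.

# Problem sizes and seeds used in the shipped experiments

The analysis drivers and the test suite use sizes chosen to make each
statistical property measurable while a full run stays comfortable on a
laptop:

* motif recovery: 700 genes / 10,000 sites / B = 100, 100 seeds (the
  sparse-cluster regime discussed above);
* region-distribution recovery: 120 genes / 10,000 sites, 20 seeds;
* metagene recovery: 150 genes / 500 sites of 25 nt, 100 seeds — short
  sparse sites keep the coverage peak sharp and interior to the window;
* occupancy recovery: 2000 genes (500 per bin), slope 0.15 and the null
  slope 0, 100 seeds each;
* inclusion-bias recovery: 1000 planted in-target events, 100 seeds.

# Known limitations

* Annotation and genome builds are opaque user inputs; no liftover or
  build reconciliation is attempted.
* The background sampler conditions on the called site set; it does not
  model cluster-calling biases.
* Asymptotic KS p-values are anti-conservative for very small bins; bin
  sizes are always reported alongside.
* Boolean metagene coverage ignores read depth by default; the weighted
  mode shifts the profile toward strong sites.
* The NXPM definition (reads-per-million divided by TPM) is stated and
  versioned here rather than asserted to be identical to any prior
  work's normalisation order.
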