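# crosslinkr

Downstream integration of PAR-CLIP binding sites with matched RNA-seq
expression and alternative-splicing data, for an RNA-binding protein
(RBP) studied by knockdown — the analysis layer that sits *after*
cluster calling (PARalyzer-style output), quantification (a TPM /
log2-fold-change table) and PSI estimation (an rMATS-style event table).

It is written for transcriptomics analysts who have those three standard
outputs in hand and want the connecting analyses:

* **Where does the protein bind?** Strand-aware assignment of every
  cluster to `cds` / UTRs / `noncoding_exon` / `intron` / `intergenic`
  with a fixed precedence, category distributions, and a metagene
  coverage profile around 3' splice sites.
* **Are the replicates consistent?** Target-set Venn cells and
  Spearman / squared-Pearson concordance of per-gene T-to-C-weighted
  signal.
* **What sequence does it prefer?** Region- and length-matched k-mer
  enrichment: every binding site is matched, in each of B background
  replicates, with a random same-length window from the same region of
  the same gene, giving per-k-mer Z-scores
  `Z = (obs − mean_B) / sd_B` and frequencies, shaded by pyrimidine
  content.
* **Does binding strength predict regulation?** Per-gene occupancy
  `NXPM = (crosslink reads per million) / TPM`, bins at 20 and 50,
  two-sample Kolmogorov–Smirnov comparison of knockdown log2
  fold-change distributions against non-targets, and architecture
  correlates (length, exon count, intron length, GC). A `2^-ΔΔCt`
  helper covers qPCR validation arithmetic.
* **Which splicing events respond?** The standard rMATS post-filter
  (total junction reads ≥ 5, |ΔPSI| ≥ 0.1, FDR < 0.05), event-type
  composition, and intersection with the bound-gene set, including the
  fraction of skipped-exon events showing inclusion upon knockdown
  (ΔPSI > 0).

A seeded synthetic-data generator (`synthetic_config()`,
`generate_dataset()`) emits a toy genome (FASTA), annotation (GTF),
replicate cluster files, expression and splicing tables with the
statistical structure these analyses assume — ~70% intronic sites
concentrated near 3' splice sites, a planted pyrimidine 5-mer,
occupancy-dependent down-regulation, inclusion-biased skipped exons in
bound genes — so everything can be run and tested end to end with no
external data.

## Worked example

The `analysis/` directory is a numbered walkthrough; each script reads
the files the previous one wrote under `results/`:

```sh
Rscript analysis/01_simulate_dataset.R     # genome, GTF, clusters, tables
Rscript analysis/02_annotate_sites.R       # categories, overlap, concordance
Rscript analysis/03_motif_enrichment.R     # 5-mer Z-scores
Rscript analysis/04_metagene.R             # 3' splice-site profile
Rscript analysis/05_occupancy_fold_change.R
Rscript analysis/06_splicing_events.R
```

A run of the default study (seed 42) prints, among other things:

```
intronic binding-site fraction: 70.3% (9998 pooled sites)
target genes shared by all three replicates: 350
mean pairwise Spearman rho of T-to-C signal: 0.874
top 5-mers by Z:
  TCTTC  Z =   49.9  freq = 0.0098  pyrimidines = 5
  CTTCT  Z =   27.2  freq = 0.0040  pyrimidines = 5
coverage peak at offset -41 nt (0 = first exonic base)
upstream decay trend: Spearman rho = -0.88, p = 8e-98
retained events in bound genes: 80.0% (240 / 300)
skipped-exon events in bound genes with exon inclusion: 67.5% (162 / 240)
```

Read: ~70% of clusters are intronic; the three replicates agree
(rho ≈ 0.87) and share 350 target genes; the planted pyrimidine 5-mer
TCTTC is the top-enriched word against its region-matched background;
binding piles up in the last ~40 intronic nucleotides before the 3'
splice site; and most filtered skipped-exon events in bound genes show
exon inclusion upon knockdown — the signature of a splicing repressor.

The balanced occupancy experiment in step 05 shows the dose dependence:
KS distance against non-targets grows from the low bin (D ≈ 0.17) to the
high bin (D ≈ 0.45) under a planted slope of −0.15 log2 units per bin.

The same computations are available programmatically via
`run_pipeline(pipeline_config(...), out_dir)`, in synthetic or user-data
mode; see the methods vignette
(`vignettes/clip-integration-methods.Rmd`) for the statistical design
and every numerical convention.

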