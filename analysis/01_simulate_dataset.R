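#!/usr/bin/env Rscript
## Simulate the synthetic PAR-CLIP / RNA-seq study that all downstream
## analysis steps consume: a toy genome and annotation, three replicate
## cluster files with a pyrimidine 5-mer planted at 30% of sites, an
## expression/DE table with occupancy-dependent knockdown response, and
## an rMATS-style splicing table with exon-inclusion bias in bound genes.

library(crosslinkr)

out <- "results/data"
cfg <- synthetic_config(
  seed = 42,
  n_genes = 700, n_sites = 10000, plant_rate = 0.3,
  exon_counts = 3:5, exon_length_mean = 150,
  intron_length_mean = 700, intron_length_min = 200, intergenic_gap = 100,
  n_null_events = 500, n_effect_events = 300)

ds <- generate_dataset(cfg, out)

message(sprintf("genome: %d contig(s), %.2f Mb",
                length(ds$genome), nchar(ds$genome[[1]]) / 1e6))
message(sprintf("annotation: %d genes (%d targets), %d exons",
                nrow(ds$annotation$genes), length(ds$targets),
                nrow(ds$annotation$exons)))
for (r in names(ds$sites$replicates))
  message(sprintf("%s: %d binding sites", r, nrow(ds$sites$replicates[[r]])))
message(sprintf("expression table: %d genes, TPM sum %.1f",
                nrow(ds$expression), sum(ds$expression$tpm_control)))
message(sprintf("splicing table: %d events", nrow(ds$splicing)))
message("wrote ", out)
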