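#!/usr/bin/env Rscript
## Assign every PAR-CLIP cluster to an annotation category and host
## gene, summarise the category distribution, and measure replicate
## agreement: target-set overlap and the correlation of per-gene
## T-to-C-weighted signal.

library(crosslinkr)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
ann <- read_gtf("results/data/annotation.gtf")
feats <- region_features(ann)
reps <- lapply(list(rep1 = "results/data/clusters_rep1.tsv",
                    rep2 = "results/data/clusters_rep2.tsv",
                    rep3 = "results/data/clusters_rep3.tsv"),
               function(p) assign_regions(read_binding_sites(p), ann,
                                          features = feats))

pooled <- merge_replicate_sites(reps)
dist <- region_distribution(pooled)
write.table(data.frame(region = names(dist), fraction = as.numeric(dist)),
            "results/tables/region_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("intronic binding-site fraction: %.1f%% (%d pooled sites)",
                100 * dist[["intron"]], nrow(pooled)))

ov <- replicate_overlap(lapply(reps, target_genes))
write.table(ov$cells, "results/tables/replicate_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("target genes shared by all three replicates: %d",
                length(ov$intersection)))
writeLines(ov$intersection, "results/tables/shared_targets.txt")

cc <- replicate_concordance(reps)
write.table(round(cc$spearman, 4), "results/tables/replicate_spearman.tsv",
            sep = "\t", quote = FALSE)
message(sprintf("mean pairwise Spearman rho of T-to-C signal: %.3f",
                mean(cc$spearman[upper.tri(cc$spearman)])))

for (r in names(reps))
  write_binding_sites(reps[[r]],
                      sprintf("results/tables/sites_annotated_%s.tsv", r))
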