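#!/usr/bin/env Rscript
## Alternative-splicing post-processing: filter rMATS-style events
## (>= 5 supporting reads, |dPSI| >= 0.1, FDR < 0.05), categorise the
## retained events by type, and intersect them with the shared PAR-CLIP
## target set from step 02.

library(crosslinkr)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
events <- read_splicing_table("results/data/splicing.tsv")
targets <- readLines("results/tables/shared_targets.txt")

retained <- filter_events(events, min_reads = 5, min_dpsi = 0.10,
                          max_fdr = 0.05)
write_splicing_table(retained, "results/tables/splicing_retained.tsv")
message(sprintf("events: %d total, %d retained by the filter",
                nrow(events), nrow(retained)))

categories <- categorize_events(retained)
write.table(categories, "results/tables/splicing_categories.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(categories)

ix <- intersect_with_targets(retained, targets)
message(sprintf("retained events in bound genes: %.1f%% (%d / %d)",
                100 * ix$target_fraction, ix$n_in_targets, ix$n_events))
message(sprintf(
  "skipped-exon events in bound genes with exon inclusion: %.1f%% (%d / %d)",
  100 * ix$inclusion_fraction, ix$n_se_inclusion, ix$n_se_in_targets))

## volcano-style table mirroring an FDR vs dPSI view with target flag
volcano <- data.frame(event_id = events$event_id, type = events$type,
                      dpsi = events$dpsi,
                      neg_log10_fdr = -log10(pmax(events$fdr, 1e-300)),
                      in_target = events$gene_id %in% targets,
                      retained = events$event_id %in% retained$event_id)
write.table(volcano, "results/tables/splicing_volcano.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
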