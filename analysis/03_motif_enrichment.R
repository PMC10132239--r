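#!/usr/bin/env Rscript
## Region- and length-matched 5-mer enrichment: count all 5-mer windows
## in the binding-site sequences and compare with 100 background
## replicates, each matching every site with a random same-length window
## from the same region of the same gene.

library(crosslinkr)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
genome <- read_genome("results/data/genome.fa")
ann <- read_gtf("results/data/annotation.gtf")
feats <- region_features(ann)
reps <- lapply(sprintf("results/data/clusters_rep%d.tsv", 1:3),
               function(p) assign_regions(read_binding_sites(p), ann,
                                          features = feats))
pooled <- merge_replicate_sites(reps)

tab <- kmer_enrichment_analysis(pooled, ann, genome, k = 5, B = 100,
                                seed = derive_seed(42, "kmer"),
                                features = feats)
tab <- tab[order(-tab$z), ]
write.table(tab, "results/tables/kmer_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- head(tab[is.finite(tab$z), ], 5)
message("top 5-mers by Z:")
for (i in seq_len(nrow(top)))
  message(sprintf("  %s  Z = %6.1f  freq = %.4f  pyrimidines = %d",
                  top$kmer[i], top$z[i], top$freq[i], top$n_pyrimidines[i]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave("results/figures/kmer_scatter.pdf",
                  plot_kmer_scatter(tab), width = 5, height = 4)
}
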