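test_that("a fixed seed reproduces every generated file byte for byte", {
  cfg <- synthetic_config(seed = 7, n_genes = 30, n_sites = 500,
                          n_null_events = 100, n_effect_events = 50)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("exon count fixed at 1 yields intronless genes", {
  cfg <- synthetic_config(seed = 3, n_genes = 20, exon_counts = 1,
                          n_sites = 100)
  sg <- generate_genome_annotation(cfg)
  arch <- gene_architecture(sg$annotation, sg$genome)
  expect_true(all(arch$intron_length == 0))
  expect_true(all(arch$exon_count == 1))
})

test_that("gene-body GC tracks the configured composition", {
  cfg <- synthetic_config(seed = 5, n_genes = 200, gc_content = 0.5,
                          target_gc_shift = 0)
  sg <- generate_genome_annotation(cfg)
  arch <- gene_architecture(sg$annotation, sg$genome)
  expect_lt(abs(mean(arch$gc_content) - 0.5), 0.02)

  ## and the target shift is realised
  cfg2 <- synthetic_config(seed = 5, n_genes = 200, gc_content = 0.5,
                           target_gc_shift = -0.05)
  sg2 <- generate_genome_annotation(cfg2)
  arch2 <- gene_architecture(sg2$annotation, sg2$genome)
  tgt <- sg2$annotation$genes$gene_id %in% sg2$targets
  expect_lt(mean(arch2$gc_content[tgt]), mean(arch2$gc_content[!tgt]) - 0.03)
})

test_that("intronic placement probability is recovered by recount", {
  cfg <- synthetic_config(seed = 1, n_genes = 120, n_sites = 10000)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  r1 <- assign_regions(sites$replicates$rep1, sg$annotation)
  fr <- region_distribution(r1)["intron"]
  expect_lt(abs(fr - 0.70), 0.02)
})

test_that("motif planting rate 0 leaves motif counts at background level", {
  cfg <- synthetic_config(seed = 13, n_genes = 80, n_sites = 3000,
                          plant_rate = 0)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  expect_identical(sites$genome, sg$genome)  # nothing written into genome
  pooled <- assign_regions(merge_replicate_sites(sites$replicates),
                           sg$annotation)
  fg <- count_kmers(site_sequences(pooled, sites$genome), 5)
  ## uniform base composition: each 5-mer ~ total/1024
  expect_lt(fg[["TCTTC"]], 3 * sum(fg) / 1024)
})

test_that("site-to-3'SS distances follow the configured exponential decay", {
  ## sparse: well under one site per intron, so the hard-core placement
  ## rarely interacts with an existing site and the marginal gap law is
  ## undistorted
  cfg <- synthetic_config(seed = 17, n_genes = 500, n_sites = 400,
                          target_fraction = 1, ss_decay = 30,
                          intronic_site_prob = 1,
                          intron_length_min = 600,
                          intron_length_mean = 1500)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  ## primary-law draws only: fallback placements (crowded introns) follow
  ## a uniform law by design and are flagged by the generator
  b <- sites$base[sites$base$placement == "intron" &
                    sites$base$placement_law == 0L, ]
  expect_gt(nrow(b) / sum(sites$base$placement == "intron"), 0.9)
  ex <- sg$annotation$exons
  ## gap between the site's transcript-3' edge and the downstream exon start
  d <- vapply(seq_len(nrow(b)), function(i) {
    e <- ex[ex$gene_id == b$gene_id[i], ]
    if (b$strand[i] == "+") min(e$start[e$start > b$end[i]]) - b$end[i] - 1L
    else b$start[i] - max(e$end[e$end < b$start[i]]) - 1L
  }, numeric(1))
  ## long introns, so truncation is negligible; compare with direct draws
  ref <- round(withr::with_seed(99, rexp(length(d), 1 / 30)))
  ks <- suppressWarnings(ks.test(d, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("TPM normalisation and fold-change slope recovery", {
  cfg <- synthetic_config(seed = 23, n_genes = 400, balanced_bins = TRUE,
                          lfc_slope = 0.1, lfc_sd = 0.2)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  expr <- generate_expression_table(sg, sites, cfg)
  expect_lt(abs(sum(expr$tpm_control) - 1e6), 0.5)
  bin <- attr(expr, "true_bin")[expr$gene_id]
  means <- tapply(expr$log2fc, bin, mean)
  ## slopes (0, 0.1, 0.2, 0.3): strictly decreasing bin means
  expect_true(all(diff(means) < 0))

  ## slope 0: per-bin means within 3 standard errors of zero
  cfg0 <- synthetic_config(seed = 23, n_genes = 400, balanced_bins = TRUE,
                           lfc_slope = 0, lfc_sd = 0.2)
  expr0 <- generate_expression_table(sg, generate_binding_sites(sg, cfg0),
                                     cfg0)
  bin0 <- attr(expr0, "true_bin")[expr0$gene_id]
  for (b in unique(bin0)) {
    x <- expr0$log2fc[bin0 == b]
    expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("splicing generator honours type proportions and planted effects", {
  ## SE proportion parameter 0.8 recovered at n = 2000 background events
  cfg <- synthetic_config(seed = 41, n_genes = 40, n_sites = 300,
                          n_null_events = 2000, n_effect_events = 0,
                          event_type_probs = c(SE = 0.8, A5SS = 0.05,
                                               A3SS = 0.05, MXE = 0.05,
                                               RI = 0.05))
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  ev <- generate_splicing_table(sg, sites, cfg)
  expect_lt(abs(mean(ev$type == "SE") - 0.8), 0.03)

  ## all planted events pass the filter by construction
  cfg1 <- synthetic_config(seed = 42, n_genes = 40, n_sites = 300,
                           n_null_events = 0, n_effect_events = 200)
  ev1 <- generate_splicing_table(sg, generate_binding_sites(sg, cfg1), cfg1)
  expect_equal(nrow(filter_events(ev1)), 200L)

  ## effect rate 0: retained background events are at most the FDR share
  cfg2 <- synthetic_config(seed = 43, n_genes = 40, n_sites = 300,
                           n_null_events = 2000, n_effect_events = 0)
  ev2 <- generate_splicing_table(sg, generate_binding_sites(sg, cfg2), cfg2)
  expect_lte(nrow(filter_events(ev2)), 0.05 * nrow(ev2))
})

test_that("generated splicing tables are internally consistent", {
  cfg <- synthetic_config(seed = 44, n_genes = 40, n_sites = 300)
  sg <- generate_genome_annotation(cfg)
  ev <- generate_splicing_table(sg, generate_binding_sites(sg, cfg), cfg)
  expect_true(all(ev$psi_control >= 0 & ev$psi_control <= 1))
  expect_true(all(ev$psi_kd >= 0 & ev$psi_kd <= 1))
  expect_equal(ev$dpsi, ev$psi_kd - ev$psi_control, tolerance = 1e-12)
  expect_true(all(ev$type %in% c("SE", "A5SS", "A3SS", "MXE", "RI")))
})

test_that("configuration validation catches impossible settings", {
  expect_error(synthetic_config(motif = "TCTTCTTTTTCTTCTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"),
               "longer than site length")
  expect_error(synthetic_config(motif = "TCXTC"), "DNA string")
  expect_error(synthetic_config(intronic_site_prob = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(balanced_bins = TRUE, n_genes = 202),
               "divisible by 4")
})
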