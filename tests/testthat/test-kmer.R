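test_that("k-mer window counting enumerates overlapping windows", {
  c1 <- count_kmers("AAAAA", 5)
  expect_equal(unname(c1[["AAAAA"]]), 1L)
  expect_equal(sum(c1), 1L)
  c2 <- count_kmers("TCTTCT", 5)
  expect_equal(unname(c2[["TCTTC"]]), 1L)
  expect_equal(unname(c2[["CTTCT"]]), 1L)
  expect_equal(sum(c2), 2L)
  ## U maps to T
  expect_equal(count_kmers("UCUUC", 5)[["TCTTC"]], 1L)
  ## windows containing N are skipped
  c3 <- count_kmers("AANAA", 2)
  expect_equal(sum(c3), 2L)  # AA at 1-2 and 4-5
  expect_error(count_kmers("ACGTX", 2), "outside")
  expect_warning(count_kmers("ACG", 5), "exceeds every sequence")
})

test_that("total counted windows equal the arithmetic identity", {
  seqs <- withr::with_seed(2, vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE), collapse = ""),
    character(1)))
  expect_equal(sum(count_kmers(seqs, 5)), 100L * 37L)
})

test_that("counts match exhaustive enumeration on random short sequences", {
  for (seed in 1:3) {
    seqs <- withr::with_seed(seed, vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), sample(3:9, 1),
                   replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
            collapse = ""), character(1)))
    for (k in c(1, 2, 3, 5)) {
      fast <- count_kmers(seqs, k)
      slow <- bf_count_kmers(seqs, k)
      expect_equal(fast[names(slow)], slow)
      expect_true(all(fast[setdiff(names(fast), names(slow))] == 0))
    }
  }
})

test_that("pyrimidine counting covers the RNA/DNA alphabet", {
  expect_equal(pyrimidine_count("TCTTC"), 5L)
  expect_equal(pyrimidine_count("GAGAG"), 0L)
  expect_equal(pyrimidine_count("ACGTU"), 3L)
  expect_equal(pyrimidine_count(c("AA", "CT")), c(0L, 2L))
  expect_error(pyrimidine_count("ACGTN"), "\\{A,C,G,T,U\\}")
})

## a single gene with one 1041-nt intron for enumeration checks
one_intron_ann <- function(intron_len = 1041L) {
  genes <- data.frame(gene_id = "g", contig = "c", start = 1L,
                      end = 100L + intron_len + 100L, strand = "+",
                      biotype = "noncoding")
  tx <- data.frame(transcript_id = "t", gene_id = "g")
  ex <- data.frame(transcript_id = c("t", "t"), gene_id = "g", contig = "c",
                   start = c(1L, 101L + intron_len),
                   end = c(100L, 200L + intron_len), strand = "+")
  annotation_set(genes, tx, ex)
}

test_that("background windows are drawn from the enumerated candidate set", {
  ann <- one_intron_ann()          # intron 101..1141 (1041 nt)
  site <- make_site("c", 101, 141, "+", gene_id = "g")
  site$region <- "intron"
  bg <- sample_background(site, ann, B = 200, seed = 4)
  cand <- bf_background_candidates(site, ann)
  ## site at the intron 5' edge: the remaining 1000 nt admit 960 windows
  expect_equal(length(cand), 1000L - 41L + 1L)
  expect_equal(bg$n_candidates, length(cand))
  expect_true(all(bg$starts %in% cand))
  expect_false(any(bg$fallback))
  ## matched windows keep the site's length and lie inside the intron
  expect_true(all(bg$starts >= 142 & bg$starts + bg$len - 1 <= 1141))

  ## a mid-intron site splits the candidate set around itself
  site2 <- make_site("c", 500, 540, "+", gene_id = "g")
  site2$region <- "intron"
  bg2 <- sample_background(site2, ann, B = 100, seed = 4)
  cand2 <- bf_background_candidates(site2, ann)
  expect_equal(bg2$n_candidates, length(cand2))
  expect_true(all(bg2$starts %in% cand2))
})

test_that("background sampling is deterministic under a seed", {
  ann <- one_intron_ann()
  site <- make_site("c", 300, 340, "+", gene_id = "g")
  site$region <- "intron"
  b1 <- sample_background(site, ann, B = 3, seed = 9)
  b2 <- sample_background(site, ann, B = 3, seed = 9)
  expect_identical(b1$starts, b2$starts)
})

test_that("degenerate sites fall back to whole-gene sampling or drop", {
  ## site occupying its entire region: fallback to the gene span, flagged
  ann <- one_intron_ann(intron_len = 41L)   # intron exactly site-sized
  site <- make_site("c", 101, 141, "+", gene_id = "g")
  site$region <- "intron"
  bg <- sample_background(site, ann, B = 10, seed = 2)
  expect_true(bg$fallback[1])
  expect_equal(nrow(bg$sites), 1L)
  ## intergenic sites are excluded with a warning
  s2 <- rbind({x <- make_site("c", 101, 141, "+", "a", gene_id = "g")
               x$region <- "intron"; x},
              {y <- make_site("c", 1, 30, "+", "b")
               y$region <- "intergenic"; y})
  expect_warning(bg2 <- sample_background(s2, ann, B = 5, seed = 2),
                 "intergenic")
  expect_equal(nrow(bg2$sites), 1L)
})

test_that("Z-scores follow the worked arithmetic and degenerate rules", {
  fg <- c(TT = 20L, AA = 10L)
  bg <- cbind(TT = c(8, 10, 12), AA = c(10, 10, 10))
  tab <- kmer_enrichment(fg, bg)
  ## sample sd of {8,10,12} is 2 -> Z = (20 - 10) / 2 = 5
  expect_equal(tab$z[tab$kmer == "TT"], 5)
  ## zero sd, observed equal to mean -> Z = 0
  expect_equal(tab$z[tab$kmer == "AA"], 0)
  expect_false(tab$degenerate[tab$kmer == "AA"])
  ## zero sd, observed above mean -> +Inf, flagged
  tab2 <- kmer_enrichment(c(TT = 20L), cbind(TT = c(10, 10, 10)))
  expect_equal(tab2$z, Inf)
  expect_true(tab2$degenerate)
  ## population variant divides by B
  tabp <- kmer_enrichment(fg, bg, sd_method = "population")
  expect_equal(tabp$z[tabp$kmer == "TT"], 10 / sqrt(8 / 3))
  ## foreground identical to every replicate -> all Z = 0
  tab0 <- kmer_enrichment(c(AC = 5L, GT = 7L),
                          rbind(c(AC = 5, GT = 7), c(AC = 5, GT = 7)))
  expect_true(all(tab0$z == 0))
  expect_error(kmer_enrichment(c(AC = 1L), rbind(c(AC = 1))), ">= 2")
})

test_that("foreground frequencies are order-invariant and sum to one", {
  seqs <- c("ACGTACGT", "TTTTCCCC", "GGGAAATT")
  f1 <- kmer_enrichment(count_kmers(seqs, 3),
                        rbind(count_kmers(seqs, 3), count_kmers(seqs, 3)))
  f2 <- kmer_enrichment(count_kmers(rev(seqs), 3),
                        rbind(count_kmers(seqs, 3), count_kmers(seqs, 3)))
  expect_equal(f1$freq, f2$freq)
  expect_equal(sum(f1$freq), 1, tolerance = 1e-9)
})

test_that("swapping foreground with a background replicate centres Z at zero", {
  cfg <- synthetic_config(seed = 8, n_genes = 60, n_sites = 2000,
                          plant_rate = 0)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  pooled <- assign_regions(merge_replicate_sites(sites$replicates),
                           sg$annotation)
  bg <- sample_background(pooled, sg$annotation, B = 30, seed = 5)
  m <- background_kmer_counts(bg, sites$genome, 5)
  ## use replicate 1 as the foreground against the remaining replicates
  tab <- kmer_enrichment(setNames(as.integer(m[1, ]), colnames(m)),
                         m[-1, , drop = FALSE])
  expect_lt(abs(mean(tab$z[is.finite(tab$z)])), 0.1)
})

test_that("planted pyrimidine motif is recovered as the top Z-score", {
  cfg <- synthetic_config(seed = 12, n_genes = 80, n_sites = 4000,
                          plant_rate = 0.3)
  sg <- generate_genome_annotation(cfg)
  sites <- generate_binding_sites(sg, cfg)
  pooled <- assign_regions(merge_replicate_sites(sites$replicates),
                           sg$annotation)
  tab <- kmer_enrichment_analysis(pooled, sg$annotation, sites$genome,
                                  k = 5, B = 50, seed = 6)
  expect_equal(tab$kmer[which.max(tab$z)], "TCTTC")
  expect_equal(tab$n_pyrimidines[tab$kmer == "TCTTC"], 5L)
})
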