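test_that("GTF coordinates keep the 1-based closed convention and lengths", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t11\t20\t.\t+\t.\tgene_id "g"; gene_biotype "protein_coding";',
    'chr1\tx\ttranscript\t11\t20\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t11\t20\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
    path)
  ann <- read_gtf(path)
  expect_equal(ann$exons$start, 11L)
  expect_equal(ann$exons$end, 20L)
  expect_equal(ann$exons$end - ann$exons$start + 1L, 10L)
})

test_that("out-of-order exons are stored sorted by start", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t200\t250\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t10\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
    path)
  ann <- read_gtf(path)
  expect_equal(ann$exons$start, c(10L, 200L))
})

test_that("a fixture GTF with 3 genes / 5 transcripts / 12 exons reports those counts", {
  exdef <- list(  # transcript_id, gene, exon intervals
    t1a = list("g1", rbind(c(1, 50), c(101, 150), c(201, 260))),
    t1b = list("g1", rbind(c(1, 50), c(201, 260))),
    t2a = list("g2", rbind(c(401, 470), c(551, 600), c(681, 700))),
    t2b = list("g2", rbind(c(401, 470), c(681, 700))),
    t3a = list("g3", rbind(c(801, 900), c(951, 980))))
  lines <- character(0)
  for (tx in names(exdef)) {
    gid <- exdef[[tx]][[1]]; m <- exdef[[tx]][[2]]
    lines <- c(lines, sprintf(
      'chr1\tx\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
      m[, 1], m[, 2], gid, tx))
  }
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(lines, path)
  ann <- read_gtf(path)
  expect_equal(nrow(ann$genes), 3L)
  expect_equal(nrow(ann$transcripts), 5L)
  expect_equal(nrow(ann$exons), 12L)
})

test_that("malformed GTF lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t10\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\tonly_three_fields\toops"),
    path)
  expect_error(read_gtf(path), "line 2")
})

test_that("exons outside the declared gene span name the offending gene", {
  genes <- data.frame(gene_id = "gX", contig = "chr1", start = 100L,
                      end = 200L, strand = "+", biotype = "protein_coding")
  tx <- data.frame(transcript_id = "t", gene_id = "gX")
  ex <- data.frame(transcript_id = "t", gene_id = "gX", contig = "chr1",
                   start = 90L, end = 150L, strand = "+")
  expect_error(annotation_set(genes, tx, ex), "gX")
})

test_that("extract_sequence honours strand and bounds", {
  g <- c(chr = "ACGT")
  expect_equal(extract_sequence(g, "chr", 1, 4, "+"), "ACGT")
  expect_equal(extract_sequence(g, "chr", 1, 4, "-"), "ACGT")  # palindrome
  g2 <- c(chr = "AAACCC")
  expect_equal(extract_sequence(g2, "chr", 2, 4, "-"), "GTT")
  expect_error(extract_sequence(g2, "chr", 0, 3), "out of bounds")
  expect_error(extract_sequence(g2, "chr", 5, 9), "out of bounds")
  expect_error(extract_sequence(g2, "nope", 1, 2), "unknown contig")
})

test_that("minus-strand extraction is the reverse complement of plus", {
  g <- toy_genome()
  for (iv in list(c(101, 150), c(260, 300), c(555, 700))) {
    plus <- extract_sequence(g, "chr1", iv[1], iv[2], "+")
    minus <- extract_sequence(g, "chr1", iv[1], iv[2], "-")
    expect_equal(minus, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus))))
  }
})

test_that("gene architecture arithmetic matches hand computation", {
  ## single gene, 2 exons of 50 and 30 nt inside a 200 nt span
  genes <- data.frame(gene_id = "g", contig = "chr1", start = 1L, end = 200L,
                      strand = "+", biotype = "noncoding")
  tx <- data.frame(transcript_id = "t", gene_id = "g")
  ex <- data.frame(transcript_id = c("t", "t"), gene_id = "g",
                   contig = "chr1", start = c(1L, 171L), end = c(50L, 200L),
                   strand = "+")
  ann <- annotation_set(genes, tx, ex)
  arch <- gene_architecture(ann, c(chr1 = toy_contig(200)))
  expect_equal(arch$transcript_length, 80L)
  expect_equal(arch$intron_length, 120L)
  expect_equal(arch$mean_exon_length, 40)
  expect_equal(arch$exon_count, 2L)

  ## single-exon gene: no intron
  ex1 <- data.frame(transcript_id = "t", gene_id = "g", contig = "chr1",
                    start = 1L, end = 200L, strand = "+")
  ann1 <- annotation_set(genes, tx, ex1)
  expect_equal(gene_architecture(ann1, c(chr1 = toy_contig(200)))$intron_length, 0L)

  ## all-G/C gene body
  annGC <- annotation_set(
    data.frame(gene_id = "g", contig = "c", start = 1L, end = 8L,
               strand = "+", biotype = "noncoding"),
    tx, data.frame(transcript_id = "t", gene_id = "g", contig = "c",
                   start = 1L, end = 8L, strand = "+"))
  expect_equal(gene_architecture(annGC, c(c = "GGCCGGCC"))$gc_content, 1.0)

  ## gene on a contig missing from the genome
  expect_error(gene_architecture(ann, c(other = "ACGT")), "g")
})

test_that("N bases count as non-GC but stay in the denominator", {
  ann <- annotation_set(
    data.frame(gene_id = "g", contig = "c", start = 1L, end = 10L,
               strand = "+", biotype = "noncoding"),
    data.frame(transcript_id = "t", gene_id = "g"),
    data.frame(transcript_id = "t", gene_id = "g", contig = "c",
               start = 1L, end = 10L, strand = "+"))
  expect_equal(gene_architecture(ann, c(c = "GGGGGNNNNN"))$gc_content, 0.5)
})

test_that("GTF round-trip reproduces the interval set exactly", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  ann2 <- read_gtf(path)
  for (tab in c("genes", "transcripts", "exons")) {
    a <- ann[[tab]][order(ann[[tab]][[1]]), ]
    b <- ann2[[tab]][order(ann2[[tab]][[1]]), names(a)]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("our GTF parsing agrees with rtracklayer on a fixture", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  ours <- ann$exons[order(ann$exons$start, ann$exons$transcript_id), ]
  theirs <- data.frame(start = GenomicRanges::start(ex),
                       end = GenomicRanges::end(ex),
                       tx = ex$transcript_id)
  theirs <- theirs[order(theirs$start, theirs$tx), ]
  expect_equal(ours$start, theirs$start)
  expect_equal(ours$end, theirs$end)
  expect_equal(ours$transcript_id, theirs$tx)
})

test_that("exon union plus intron length equals the gene span", {
  cfg <- synthetic_config(seed = 21, n_genes = 50)
  sg <- generate_genome_annotation(cfg)
  arch <- gene_architecture(sg$annotation, sg$genome)
  g <- sg$annotation$genes
  span <- g$end - g$start + 1L
  ## one transcript per gene, so the representative exon union is the
  ## gene-level union
  expect_equal(arch$transcript_length + arch$intron_length, span)
})

test_that("representative transcript is the longest exon union, ties to smaller id", {
  ann <- toy_annotation()
  rep <- representative_transcripts(ann)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "t1")  # 150 > 100 nt
  genes <- data.frame(gene_id = "g", contig = "c", start = 1L, end = 100L,
                      strand = "+", biotype = "noncoding")
  tx <- data.frame(transcript_id = c("tB", "tA"), gene_id = "g")
  ex <- data.frame(transcript_id = c("tB", "tA"), gene_id = "g",
                   contig = "c", start = c(1L, 1L), end = c(50L, 50L),
                   strand = "+")
  expect_equal(representative_transcripts(
    annotation_set(genes, tx, ex))$transcript_id, "tA")
})
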