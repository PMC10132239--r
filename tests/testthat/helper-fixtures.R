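## Hand-built fixtures and brute-force oracles shared across tests.

## Deterministic 1000-nt contig (fixed, not random, so expected
## sequences can be read off by eye where needed).
toy_contig <- function(len = 1000) {
  paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
}

## Two genes on opposite strands plus a second isoform of gene 1 whose
## skipped middle exon makes region precedence decidable by hand:
##   g1 '+', 101-400, coding. t1 exons 101-150 / 251-300 / 351-400,
##     CDS 131-380 (5'UTR 101-130, 3'UTR 381-400).
##     t1b exons 101-150 / 351-400 (middle exon skipped -> 151-350 is
##     intron in t1b).
##   g2 '-', 501-800, noncoding. t2 exons 501-560 / 701-800.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"), contig = "chr1",
    start = c(101L, 501L), end = c(400L, 800L),
    strand = c("+", "-"),
    biotype = c("protein_coding", "noncoding"),
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("t1", "t1b", "t2"),
    gene_id = c("g1", "g1", "g2"),
    cds_start = c(131L, NA, NA), cds_end = c(380L, NA, NA),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("t1", "t1", "t1", "t1b", "t1b", "t2", "t2"),
    gene_id = c("g1", "g1", "g1", "g1", "g1", "g2", "g2"),
    contig = "chr1",
    start = c(101L, 251L, 351L, 101L, 351L, 501L, 701L),
    end = c(150L, 300L, 400L, 150L, 400L, 560L, 800L),
    strand = c("+", "+", "+", "+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  annotation_set(genes, transcripts, exons)
}

toy_genome <- function() c(chr1 = toy_contig())

## one site row in the package-internal (1-based closed) convention
make_site <- function(contig, start, end, strand, name = "s1", reads = 10L,
                      tc = 5L, gene_id = NA_character_) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), name = name,
             crosslink_reads = as.integer(reads), strand = strand,
             tc_conversions = as.integer(tc), gene_id = gene_id,
             stringsAsFactors = FALSE)
}

## ---- brute-force oracles -------------------------------------------------

## windows enumerated one by one; N-containing windows skipped
bf_count_kmers <- function(seqs, k) {
  out <- new.env(parent = emptyenv())
  for (s in seqs) {
    s <- chartr("uU", "tT", toupper(s))
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      out[[w]] <- (if (is.null(out[[w]])) 0L else out[[w]]) + 1L
    }
  }
  v <- unlist(as.list(out))
  if (is.null(v)) integer(0) else v[order(names(v))]
}

bf_ecdf <- function(x, q) vapply(q, function(v) mean(x <= v), numeric(1))

## two-sample KS statistic as the sup over all sample points
bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(bf_ecdf(x, pts) - bf_ecdf(y, pts)))
}

## per-offset boolean coverage by naive interval overlap
bf_metagene <- function(sites, ann, U, D) {
  rep_tx <- representative_transcripts(ann)
  ex <- ann$exons[ann$exons$transcript_id %in% rep_tx$transcript_id, ]
  g <- ann$genes
  offsets <- seq(-U, D - 1)
  cov <- integer(length(offsets)); def <- integer(length(offsets))
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    strand <- e$strand[1]
    gi <- match(e$gene_id[1], g$gene_id)
    bpos <- if (strand == "+") e$start[-1] else e$end[-nrow(e)]
    for (p in bpos) {
      for (j in seq_along(offsets)) {
        o <- offsets[j]
        gp <- if (strand == "+") p + o else p - o
        if (gp < g$start[gi] || gp > g$end[gi]) next
        def[j] <- def[j] + 1L
        hit <- any(sites$strand == strand & sites$contig == e$contig[1] &
                     sites$start <= gp & sites$end >= gp)
        if (hit) cov[j] <- cov[j] + 1L
      }
    }
  }
  data.frame(offset = offsets, coverage = ifelse(def > 0, cov / def, NA),
             n_covered = cov, n_defined = def)
}

## all candidate background window starts for one site, by enumeration
bf_background_candidates <- function(site, ann, features = NULL) {
  feats <- features %||% region_features(ann)
  m <- S4Vectors::mcols(feats)
  keep <- m$gene_id == site$gene_id & m$region == site$region
  iv <- data.frame(start = GenomicRanges::start(feats)[keep],
                   end = GenomicRanges::end(feats)[keep])
  L <- site$end - site$start + 1
  cand <- integer(0)
  for (j in seq_len(nrow(iv))) {
    hi <- iv$end[j] - L + 1
    if (hi < iv$start[j]) next
    x <- iv$start[j]:hi
    x <- x[x > site$end | (x + L - 1) < site$start]
    cand <- c(cand, x)
  }
  sort(cand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
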