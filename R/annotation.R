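#' Construct an annotation set
#'
#' The package's gene model: plain data frames for genes, transcripts and
#' exons, validated against each other. Coordinates are 1-based closed
#' (IRanges convention); GTF files use the same convention natively and
#' BED-like files are converted at the I/O boundary.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`, `biotype` (`"protein_coding"` or `"noncoding"`).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   and optional `cds_start`, `cds_end` (NA when noncoding).
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, transcripts, exons) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_("%s table lacks column(s): %s", what, paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "contig", "start", "end", "strand", "biotype"), "gene")
  need(transcripts, c("transcript_id", "gene_id"), "transcript")
  need(exons, c("transcript_id", "gene_id", "contig", "start", "end", "strand"),
       "exon")
  if (!all(c("cds_start", "cds_end") %in% names(transcripts))) {
    transcripts$cds_start <- NA_integer_
    transcripts$cds_end <- NA_integer_
  }
  if (anyDuplicated(genes$gene_id))
    stop_("duplicate gene ids in gene table")
  if (anyDuplicated(transcripts$transcript_id))
    stop_("duplicate transcript ids")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop_("transcript rows reference unknown genes")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop_("exon rows reference unknown transcripts")
  if (any(exons$start > exons$end) || any(genes$start > genes$end))
    stop_("start > end in annotation intervals")
  if (!all(genes$strand %in% c("+", "-")))
    stop_("gene strand must be '+' or '-'")

  ## exons sorted by genomic start within transcript
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  ## per-transcript validation: >=1 exon, non-overlapping, inside gene span
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  no_ex <- setdiff(transcripts$transcript_id, names(sp))
  if (length(no_ex))
    stop_("transcript(s) without exons: %s", paste(no_ex, collapse = ", "))
  gidx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[gidx] | exons$end > genes$end[gidx])) {
    bad <- unique(exons$gene_id[exons$start < genes$start[gidx] |
                                  exons$end > genes$end[gidx]])
    stop_("exon outside declared gene span for gene(s): %s",
          paste(bad, collapse = ", "))
  }
  for (tx in names(sp)) {
    i <- sp[[tx]]
    if (length(i) > 1 && any(exons$start[i][-1] <= exons$end[i][-length(i)]))
      stop_("overlapping exons in transcript %s", tx)
  }
  ## CDS span inside exon union
  ti <- which(!is.na(transcripts$cds_start))
  for (j in ti) {
    i <- sp[[transcripts$transcript_id[j]]]
    if (transcripts$cds_start[j] < min(exons$start[i]) ||
        transcripts$cds_end[j] > max(exons$end[i]))
      stop_("CDS span outside exons for transcript %s",
            transcripts$transcript_id[j])
  }
  rownames(genes) <- NULL; rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d transcripts, %d exons on %d contig(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$contig))))
  invisible(x)
}

gtf_attr <- function(attr, key) {
  m <- stringi::stri_match_first_regex(attr,
         paste0(key, '\\s+"([^"]*)"'))
  m[, 2]
}

#' Read a GTF file into an annotation set
#'
#' Parses `gene`, `transcript`, `exon` and `CDS` features (other feature
#' types are ignored) with `key "value";` attributes. Missing gene or
#' transcript records are derived from the exon spans.
#'
#' @param path GTF file path.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_("empty GTF: %s", path)
  parts <- stringi::stri_split_fixed(lines, "\t")
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop_("malformed GTF line %d in %s: expected 9 tab-separated fields, got %d",
          lineno[which(nf != 9L)[1]], path, nf[nf != 9L][1])
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  type <- m[, 3]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop_("malformed GTF line %d in %s: bad coordinates", lineno[bad[1]], path)
  if (any(!m[, 7] %in% c("+", "-")))
    stop_("malformed GTF line %d: strand must be '+' or '-'",
          lineno[which(!m[, 7] %in% c("+", "-"))[1]])
  df <- data.frame(contig = m[, 1], type = type, start = start, end = end,
                   strand = m[, 7],
                   gene_id = gtf_attr(m[, 9], "gene_id"),
                   transcript_id = gtf_attr(m[, 9], "transcript_id"),
                   biotype = gtf_attr(m[, 9], "gene_biotype"),
                   stringsAsFactors = FALSE)
  if (anyNA(df$gene_id))
    stop_("malformed GTF line %d: missing gene_id attribute",
          lineno[which(is.na(df$gene_id))[1]])
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop_("GTF %s contains no exon features", path)
  if (anyNA(ex$transcript_id))
    stop_("exon feature without transcript_id in %s", path)

  ## transcripts: declared, else derived from exon spans
  txd <- df[df$type == "transcript" & !is.na(df$transcript_id), , drop = FALSE]
  tx_ids <- unique(ex$transcript_id)
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = ex$gene_id[match(tx_ids, ex$transcript_id)],
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE)
  cds <- df[df$type == "CDS" & !is.na(df$transcript_id), , drop = FALSE]
  if (nrow(cds)) {
    cs <- tapply(cds$start, cds$transcript_id, min)
    ce <- tapply(cds$end, cds$transcript_id, max)
    i <- match(names(cs), transcripts$transcript_id)
    transcripts$cds_start[i] <- as.integer(cs)
    transcripts$cds_end[i] <- as.integer(ce)
  }

  ## genes: declared, else derived from exon spans
  gd <- df[df$type == "gene", , drop = FALSE]
  gene_ids <- unique(ex$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    contig = ex$contig[match(gene_ids, ex$gene_id)],
    start = as.integer(tapply(ex$start, ex$gene_id, min)[gene_ids]),
    end = as.integer(tapply(ex$end, ex$gene_id, max)[gene_ids]),
    strand = ex$strand[match(gene_ids, ex$gene_id)],
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
  if (nrow(gd)) {
    i <- match(gd$gene_id, genes$gene_id)
    ok <- !is.na(i)
    genes$start[i[ok]] <- gd$start[ok]
    genes$end[i[ok]] <- gd$end[ok]
    genes$biotype[i[ok]] <- ifelse(is.na(gd$biotype[ok]), "protein_coding",
                                   gd$biotype[ok])
  }
  ## genes with declared CDS-free transcripts only are noncoding unless tagged
  exons <- ex[, c("transcript_id", "gene_id", "contig", "start", "end", "strand")]
  annotation_set(genes, transcripts, exons)
}

#' Write an annotation set to GTF
#'
#' Emits gene, transcript, exon and (where present) CDS features; reading
#' the result back with [read_gtf()] reproduces the interval set exactly.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons
  gl <- sprintf('%s\tcrosslinkr\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                g$contig, g$start, g$end, g$strand, g$gene_id, g$biotype)
  gi <- match(tx$gene_id, g$gene_id)
  tl <- sprintf('%s\tcrosslinkr\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                g$contig[gi],
                as.integer(tapply(ex$start, ex$transcript_id, min)[tx$transcript_id]),
                as.integer(tapply(ex$end, ex$transcript_id, max)[tx$transcript_id]),
                g$strand[gi], tx$gene_id, tx$transcript_id)
  el <- sprintf('%s\tcrosslinkr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                ex$contig, ex$start, ex$end, ex$strand, ex$gene_id,
                ex$transcript_id)
  has_cds <- !is.na(tx$cds_start)
  cl <- if (any(has_cds)) {
    sprintf('%s\tcrosslinkr\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            g$contig[gi][has_cds], tx$cds_start[has_cds], tx$cds_end[has_cds],
            g$strand[gi][has_cds], tx$gene_id[has_cds],
            tx$transcript_id[has_cds])
  } else character()
  writeLines(c(gl, tl, el, cl), path)
  invisible(path)
}

exons_granges <- function(ann) {
  GenomicRanges::GRanges(ann$exons$contig,
                         IRanges::IRanges(ann$exons$start, ann$exons$end),
                         strand = ann$exons$strand,
                         transcript_id = ann$exons$transcript_id,
                         gene_id = ann$exons$gene_id)
}

genes_granges <- function(ann) {
  GenomicRanges::GRanges(ann$genes$contig,
                         IRanges::IRanges(ann$genes$start, ann$genes$end),
                         strand = ann$genes$strand,
                         gene_id = ann$genes$gene_id)
}

#' Representative transcript per gene
#'
#' The transcript with the largest exon-union length; ties are broken by
#' the lexicographically smallest transcript id.
#'
#' @param ann an [annotation_set()].
#' @return data.frame with `gene_id`, `transcript_id`.
#' @export
representative_transcripts <- function(ann) {
  ex <- ann$exons
  w <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
  tx <- ann$transcripts
  tx$union_len <- as.integer(w[tx$transcript_id])
  tx <- tx[order(tx$gene_id, -tx$union_len, tx$transcript_id), , drop = FALSE]
  rep <- tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id")]
  rownames(rep) <- NULL
  rep
}

#' Decompose an annotation into labelled region features
#'
#' For each transcript: coding exonic stretches become `cds`, exonic
#' stretches outside the CDS span become `five_prime_utr` /
#' `three_prime_utr` (strand-aware), exons of CDS-free transcripts become
#' `noncoding_exon`, and gaps between consecutive exons become `intron`.
#'
#' @param ann an [annotation_set()].
#' @return A `GRanges` with metadata columns `gene_id` and `region`.
#' @export
region_features <- function(ann) {
  ex <- ann$exons[order(ann$exons$transcript_id, ann$exons$start), ,
                  drop = FALSE]
  tx <- ann$transcripts
  ti <- match(ex$transcript_id, tx$transcript_id)
  cs <- tx$cds_start[ti]; ce <- tx$cds_end[ti]

  pieces <- list()
  add <- function(contig, s, e, strand, gene, region) {
    keep <- !is.na(s) & !is.na(e) & s <= e
    if (!any(keep)) return()
    pieces[[length(pieces) + 1L]] <<- list(
      contig = contig[keep], start = s[keep], end = e[keep],
      strand = strand[keep], gene_id = gene[keep],
      region = if (length(region) == 1L) rep(region, sum(keep))
               else region[keep])
  }

  ## introns: gaps between consecutive exons of the same transcript
  n <- nrow(ex)
  if (n > 1L) {
    same <- ex$transcript_id[-n] == ex$transcript_id[-1L]
    add(ex$contig[-n][same], ex$end[-n][same] + 1L,
        ex$start[-1L][same] - 1L, ex$strand[-n][same],
        ex$gene_id[-n][same], "intron")
  }
  coding <- !is.na(cs)
  if (any(!coding))
    add(ex$contig[!coding], ex$start[!coding], ex$end[!coding],
        ex$strand[!coding], ex$gene_id[!coding], "noncoding_exon")
  if (any(coding)) {
    cc <- which(coding)
    add(ex$contig[cc], pmax(ex$start[cc], cs[cc]), pmin(ex$end[cc], ce[cc]),
        ex$strand[cc], ex$gene_id[cc], "cds")
    left <- ifelse(ex$strand[cc] == "+", "five_prime_utr", "three_prime_utr")
    right <- ifelse(ex$strand[cc] == "+", "three_prime_utr", "five_prime_utr")
    add(ex$contig[cc], ex$start[cc], pmin(ex$end[cc], cs[cc] - 1L),
        ex$strand[cc], ex$gene_id[cc], left)
    add(ex$contig[cc], pmax(ex$start[cc], ce[cc] + 1L), ex$end[cc],
        ex$strand[cc], ex$gene_id[cc], right)
  }
  cat_ <- function(f) unlist(lapply(pieces, `[[`, f), use.names = FALSE)
  GenomicRanges::GRanges(cat_("contig"),
                         IRanges::IRanges(cat_("start"), cat_("end")),
                         strand = cat_("strand"), gene_id = cat_("gene_id"),
                         region = cat_("region"))
}

#' Per-gene architectural features
#'
#' Transcript length, exon count and mean exon length come from the
#' representative transcript ([representative_transcripts()]); intron
#' length is the gene span minus the gene-level exon union; GC content is
#' computed over the unspliced gene body by default (`gc_on =
#' "exon_union"` restricts it to exonic sequence). N bases count as
#' non-GC and stay in the denominator.
#'
#' @param ann an [annotation_set()].
#' @param genome genome sequences (named character or `DNAStringSet`).
#' @param gc_on `"gene_body"` (default) or `"exon_union"`.
#' @return data.frame, one row per gene: `gene_id`, `transcript_length`,
#'   `exon_count`, `mean_exon_length`, `intron_length`, `gc_content`.
#' @export
gene_architecture <- function(ann, genome, gc_on = c("gene_body", "exon_union")) {
  gc_on <- match.arg(gc_on)
  genome <- as_genome(genome)
  missing_contig <- !(ann$genes$contig %in% names(genome))
  if (any(missing_contig))
    stop_("gene(s) on contig absent from genome: %s",
          paste(ann$genes$gene_id[missing_contig], collapse = ", "))
  rep <- representative_transcripts(ann)
  ex <- ann$exons
  rex <- ex[ex$transcript_id %in% rep$transcript_id, , drop = FALSE]
  exlen <- rex$end - rex$start + 1L
  tx_len <- tapply(exlen, rex$gene_id, sum)
  n_ex <- tapply(exlen, rex$gene_id, length)

  ## gene-level exon union for intron length
  exgr <- GenomicRanges::reduce(exons_granges(ann), ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(genes_granges(ann), exgr,
                                    ignore.strand = TRUE)
  union_w <- tapply(GenomicRanges::width(exgr)[S4Vectors::subjectHits(ov)],
                    ann$genes$gene_id[S4Vectors::queryHits(ov)], sum)
  g <- ann$genes
  span <- g$end - g$start + 1L
  uw <- as.integer(union_w[g$gene_id]); uw[is.na(uw)] <- 0L

  gc_frac <- function(seqs) {
    gcn <- stringi::stri_count_regex(seqs, "[GC]")
    gcn / nchar(seqs)
  }
  if (gc_on == "gene_body") {
    gc <- gc_frac(extract_sequence(genome, g$contig, g$start, g$end, "+"))
  } else {
    exseq <- extract_sequence(genome, rex$contig, rex$start, rex$end, "+")
    gcn <- tapply(stringi::stri_count_regex(exseq, "[GC]"), rex$gene_id, sum)
    gc <- as.numeric(gcn[g$gene_id]) / as.numeric(tx_len[g$gene_id])
  }
  data.frame(gene_id = g$gene_id,
             transcript_length = as.integer(tx_len[g$gene_id]),
             exon_count = as.integer(n_ex[g$gene_id]),
             mean_exon_length = as.numeric(tx_len[g$gene_id]) /
               as.numeric(n_ex[g$gene_id]),
             intron_length = span - uw,
             gc_content = gc,
             stringsAsFactors = FALSE)
}
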