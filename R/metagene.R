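#' Metagene binding profile around 3' splice sites
#'
#' For every internal exon of each gene's representative transcript (an
#' exon preceded by an intron in transcript orientation), a window of
#' `upstream` intronic plus `downstream` exonic positions is laid out in
#' transcript orientation, offset 0 being the first exonic base. The
#' profile reports, per offset, the fraction of eligible boundaries
#' covered by at least one same-strand binding site. Windows truncated by
#' the gene span contribute only to their defined offsets, so the
#' denominator is per-offset.
#'
#' @param sites site data.frame.
#' @param ann an [annotation_set()].
#' @param upstream intronic window extent U (nt, > 0); offsets -U..-1.
#' @param downstream exonic window extent D (nt, > 0); offsets 0..D-1.
#' @param weight `"boundary"` scores site presence per boundary
#'   (boolean); `"reads"` sums crosslink reads of covering sites.
#' @return data.frame of class `metagene_profile`: `offset`, `coverage`,
#'   `n_covered`, `n_defined`; total boundary count in attribute
#'   `"n_boundaries"`.
#' @export
metagene_profile <- function(sites, ann, upstream = 300, downstream = 50,
                             weight = c("boundary", "reads")) {
  weight <- match.arg(weight)
  if (!is_count(upstream) || !is_count(downstream) ||
      upstream <= 0 || downstream <= 0)
    stop_("upstream and downstream must be positive integers")
  U <- as.integer(upstream); D <- as.integer(downstream)

  rep <- representative_transcripts(ann)
  ex <- ann$exons[ann$exons$transcript_id %in% rep$transcript_id, ,
                  drop = FALSE]
  g <- ann$genes
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  blist <- lapply(sp, function(i) {
    if (length(i) < 2L) return(NULL)
    strand <- ex$strand[i][1]
    if (strand == "+") {
      pos <- ex$start[i][-1L]            # starts of exons 2..n
    } else {
      pos <- ex$end[i][-length(i)]       # transcript-internal exon starts
    }
    data.frame(contig = ex$contig[i][1], pos = pos, strand = strand,
               gene_id = ex$gene_id[i][1], stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, blist)
  if (is.null(b) || !nrow(b)) stop_("no eligible intron-exon boundaries")
  nb <- nrow(b)

  ## genomic window per boundary, truncated at the gene span
  gi <- match(b$gene_id, g$gene_id)
  plus <- b$strand == "+"
  win_start <- ifelse(plus, b$pos - U, b$pos - D + 1L)
  win_end <- ifelse(plus, b$pos + D - 1L, b$pos + U)
  def_start <- pmax(win_start, g$start[gi])
  def_end <- pmin(win_end, g$end[gi])

  ## offset of a genomic position p: '+': p - pos; '-': pos - p
  off_lo <- ifelse(plus, def_start - b$pos, b$pos - def_end)
  off_hi <- ifelse(plus, def_end - b$pos, b$pos - def_start)

  offsets <- seq(-U, D - 1L)
  n_def <- integer(length(offsets))
  ## per-offset defined-boundary counts via difference accumulation
  add_range <- function(acc, lo, hi, w = rep(1, length(lo))) {
    lo_i <- lo + U + 1L; hi_i <- hi + U + 1L
    d <- numeric(length(offsets) + 1L)
    for (j in seq_along(lo_i)) {
      d[lo_i[j]] <- d[lo_i[j]] + w[j]
      d[hi_i[j] + 1L] <- d[hi_i[j] + 1L] - w[j]
    }
    acc + cumsum(d)[seq_along(offsets)]
  }
  n_def <- add_range(numeric(length(offsets)), off_lo, off_hi)

  ## site overlap: same strand, genomic interval intersection
  bgr <- GenomicRanges::GRanges(b$contig,
                                IRanges::IRanges(def_start, def_end),
                                strand = b$strand)
  sgr <- sites_granges(sites)
  cov <- numeric(length(offsets))
  hits <- GenomicRanges::findOverlaps(bgr, sgr, ignore.strand = FALSE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
    is_s <- pmax(def_start[q], sites$start[sj])
    is_e <- pmin(def_end[q], sites$end[sj])
    o_lo <- ifelse(plus[q], is_s - b$pos[q], b$pos[q] - is_e)
    o_hi <- ifelse(plus[q], is_e - b$pos[q], b$pos[q] - is_s)
    if (weight == "reads") {
      cov <- add_range(cov, o_lo, o_hi, w = sites$crosslink_reads[sj])
    } else {
      ## boolean per boundary: union covered intervals within boundary
      ir <- IRanges::IRanges(o_lo + U + 1L, o_hi + U + 1L)
      red <- IRanges::reduce(S4Vectors::split(ir, q))
      flat <- unlist(red, use.names = FALSE)
      cov <- add_range(cov, IRanges::start(flat) - U - 1L,
                       IRanges::end(flat) - U - 1L)
    }
  }
  out <- data.frame(offset = offsets,
                    coverage = ifelse(n_def > 0, cov / n_def, NA_real_),
                    n_covered = cov, n_defined = as.integer(round(n_def)))
  attr(out, "n_boundaries") <- nb
  class(out) <- c("metagene_profile", "data.frame")
  out
}
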