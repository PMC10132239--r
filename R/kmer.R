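#' Count overlapping k-mer windows in a set of sequences
#'
#' All `length - k + 1` windows of every sequence are counted (pooled
#' across sequences); windows containing N are skipped. Counting is done
#' over the DNA alphabet; T and U are equivalent (U inputs are mapped to
#' T).
#'
#' @param sequences character vector of sequences over `{A,C,G,T,U,N}`.
#' @param k word length, `>= 1`.
#' @return Named integer vector of length `4^k` (all DNA k-mers, zeros
#'   included).
#' @export
count_kmers <- function(sequences, k = 5) {
  if (!is_count(k) || k < 1) stop_("k must be a positive integer")
  if (!length(sequences)) stop_("no sequences given")
  sequences <- chartr("uU", "tT", toupper(sequences))
  if (any(stringi::stri_detect_regex(sequences, "[^ACGTN]")))
    stop_("sequences contain characters outside {A,C,G,T,U,N}")
  if (all(nchar(sequences) < k))
    warn_("k = %d exceeds every sequence length; all counts zero", k)
  ## concatenate with N spacers so no window spans two sequences, then
  ## count in one pass; N-containing windows contribute to no word
  sep <- strrep("N", max(1L, k - 1L))
  big <- stringi::stri_join(sequences, collapse = sep)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(big),
                                                 width = k)
  storage.mode(counts) <- "integer"
  counts
}

#' Number of pyrimidines in a k-mer
#'
#' @param kmer character vector of k-mers over `{A,C,G,T,U}`.
#' @return Integer vector: count of C plus T/U per k-mer.
#' @export
pyrimidine_count <- function(kmer) {
  kmer <- toupper(kmer)
  if (any(stringi::stri_detect_regex(kmer, "[^ACGTU]")))
    stop_("k-mers must be over {A,C,G,T,U}")
  stringi::stri_count_regex(kmer, "[CTU]")
}

#' Sense-strand sequences of binding sites
#'
#' @param sites site data.frame (internal 1-based closed coordinates).
#' @param genome genome sequences.
#' @return Character vector of site sequences.
#' @export
site_sequences <- function(sites, genome) {
  extract_sequence(genome, sites$contig, sites$start, sites$end,
                   sites$strand)
}

#' Sample region- and length-matched background intervals
#'
#' For each annotated site, each of `B` background replicates draws one
#' interval uniformly among all windows of the same length inside the
#' site's region category within its host gene, excluding windows that
#' overlap the site itself. Sites whose matched region lacks capacity
#' fall back to whole-gene sampling (flagged); sites that still cannot be
#' matched, and intergenic sites, are dropped with a warning.
#'
#' @param sites annotated site data.frame (needs `region`, `gene_id`).
#' @param ann an [annotation_set()].
#' @param B number of background replicates, `>= 2`.
#' @param seed integer seed; fixed seed reproduces the draw exactly.
#' @param features optional precomputed [region_features()] of `ann`
#'   (computed internally when `NULL`).
#' @return A list of class `background_set`: `sites` (the retained site
#'   rows), `starts` (`n x B` integer matrix of interval start
#'   coordinates), `contig`, `strand`, `len`, `fallback` (logical),
#'   `n_candidates` (size of each site's candidate window set) and
#'   `dropped` (row indices of the `sites` input that were dropped).
#' @export
sample_background <- function(sites, ann, B = 100, seed = 1,
                              features = NULL) {
  if (!is_count(B) || B < 2) stop_("B must be an integer >= 2")
  if (!all(c("region", "gene_id") %in% names(sites)))
    stop_("sites must carry region and gene_id (run assign_regions first)")
  inter <- which(sites$region == "intergenic" | is.na(sites$gene_id))
  if (length(inter))
    warn_("%d intergenic site(s) excluded from background sampling",
          length(inter))
  keep <- setdiff(seq_len(nrow(sites)), inter)
  s <- sites[keep, , drop = FALSE]
  feats <- features %||% region_features(ann)
  fgene <- S4Vectors::mcols(feats)$gene_id
  fregion <- S4Vectors::mcols(feats)$region
  fstart <- GenomicRanges::start(feats)
  fend <- GenomicRanges::end(feats)
  fidx <- split(seq_along(fgene), paste(fgene, fregion))
  g <- ann$genes

  ## flatten each site's matched-interval list for the C++ sampler
  site_fid <- fidx[paste(s$gene_id, s$region)]
  iv <- unlist(site_fid, use.names = FALSE)
  iv_off <- c(0L, cumsum(lengths(site_fid)))
  site_gi <- match(s$gene_id, g$gene_id)
  res <- withr::with_seed(seed,
    sample_background_cpp(fstart[iv], fend[iv], iv_off,
                          as.integer(s$start), as.integer(s$end),
                          as.integer(g$start[site_gi]),
                          as.integer(g$end[site_gi]), as.integer(B)))
  drop_local <- res$dropped
  if (any(drop_local))
    warn_("%d site(s) dropped: no background window available",
          sum(drop_local))
  ok <- !drop_local
  structure(list(sites = s[ok, , drop = FALSE],
                 starts = res$starts[ok, , drop = FALSE],
                 contig = s$contig[ok], strand = s$strand[ok],
                 len = (s$end - s$start + 1L)[ok],
                 fallback = res$fallback[ok],
                 n_candidates = res$n_candidates[ok],
                 dropped = keep[drop_local]),
            class = "background_set")
}

## Rolling k-mer code per contig: position p holds the 0-based base-4
## code of the k-window starting at p (A=0,C=1,G=2,T=3; NA if the window
## contains N). Lexicographic order matches oligonucleotideFrequency.
kmer_code_genome <- function(genome, k) {
  lapply(genome, function(s) {
    r <- as.integer(charToRaw(s))
    code <- rep(NA_integer_, length(r))
    code[r == 65L] <- 0L; code[r == 67L] <- 1L
    code[r == 71L] <- 2L; code[r == 84L] <- 3L
    n <- length(code)
    if (n < k) return(integer(0))
    v <- code[seq_len(n - k + 1L)]
    for (i in seq_len(k - 1L))
      v <- v * 4L + code[(1L + i):(n - k + 1L + i)]
    v
  })
}

all_kmers <- function(k) Biostrings::mkAllStrings(DNA_BASES, k)

## window counts for a set of intervals on one contig, via the rolling
## code; `sense = FALSE` counts forward-strand windows as-is
tabulate_windows <- function(code, starts, len, k) {
  count_windows_cpp(code, as.integer(starts), as.integer(len),
                    as.integer(k), 4L^as.integer(k))
}

#' Aggregate k-mer counts of each background replicate
#'
#' Sense-strand window counts pooled over all matched intervals of each
#' background replicate, exactly equivalent to extracting the sequences
#' and running [count_kmers()] (minus-strand counts are obtained by the
#' reverse-complement permutation of forward-strand counts).
#'
#' @param bg a `background_set` from [sample_background()].
#' @param genome genome sequences.
#' @param k word length.
#' @param codes precomputed rolling-code list (internal caching).
#' @return `B x 4^k` integer matrix of pooled k-mer counts.
#' @export
background_kmer_counts <- function(bg, genome, k = 5, codes = NULL) {
  B <- ncol(bg$starts)
  kmers <- all_kmers(k)
  rc_perm <- match(revcomp(kmers), kmers)
  codes <- codes %||% kmer_code_genome(as_genome(genome), k)
  out <- matrix(0L, B, 4L^k, dimnames = list(NULL, kmers))
  for (ctg in unique(bg$contig)) {
    i <- which(bg$contig == ctg)
    plus <- i[bg$strand[i] == "+"]
    minus <- i[bg$strand[i] == "-"]
    code <- codes[[ctg]]
    if (length(plus)) {
      m <- count_windows_batch_cpp(code, bg$starts[plus, , drop = FALSE],
                                   bg$len[plus], as.integer(k), 4L^k)
      out <- out + m
    }
    if (length(minus)) {
      m <- count_windows_batch_cpp(code, bg$starts[minus, , drop = FALSE],
                                   bg$len[minus], as.integer(k), 4L^k)
      out <- out + m[, rc_perm, drop = FALSE]
    }
  }
  out
}

## foreground counts via the same rolling-code route
foreground_kmer_counts <- function(sites, genome, k, codes = NULL) {
  kmers <- all_kmers(k)
  rc_perm <- match(revcomp(kmers), kmers)
  codes <- codes %||% kmer_code_genome(as_genome(genome), k)
  cnt <- integer(4L^k)
  for (ctg in unique(sites$contig)) {
    i <- which(sites$contig == ctg)
    len <- sites$end[i] - sites$start[i] + 1L
    plus <- sites$strand[i] == "+"
    code <- codes[[ctg]]
    if (any(plus))
      cnt <- cnt + tabulate_windows(code, sites$start[i][plus],
                                    len[plus], k)
    if (any(!plus))
      cnt <- cnt + tabulate_windows(code, sites$start[i][!plus],
                                    len[!plus], k)[rc_perm]
  }
  stats::setNames(as.integer(cnt), kmers)
}

#' Per-k-mer enrichment Z-scores against matched backgrounds
#'
#' For each k-mer, `Z = (observed - mean_B(background)) / sd_B(background)`
#' over the `B` background replicates. The default standard deviation is
#' the sample (divide-by-`B - 1`) estimator; `sd_method = "population"`
#' divides by `B`. K-mers with zero background sd and observed equal to
#' the mean get `Z = 0`; zero sd with a different observed count gets
#' signed infinity and is flagged. Frequencies are the foreground counts
#' over all counted foreground windows.
#'
#' @param fg_counts named foreground count vector ([count_kmers()]).
#' @param bg_counts `B x 4^k` background count matrix
#'   ([background_kmer_counts()]), `B >= 2`.
#' @param sd_method `"sample"` (default) or `"population"`.
#' @return data.frame of class `kmer_enrichment`: `kmer`, `count`,
#'   `freq`, `bg_mean`, `bg_sd`, `z`, `n_pyrimidines`, `degenerate`.
#' @export
kmer_enrichment <- function(fg_counts, bg_counts,
                            sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  if (is.null(dim(bg_counts)) || nrow(bg_counts) < 2)
    stop_("need >= 2 background replicates")
  if (sum(fg_counts) == 0) stop_("empty foreground")
  kmers <- names(fg_counts)
  if (!identical(kmers, colnames(bg_counts)))
    bg_counts <- bg_counts[, kmers, drop = FALSE]
  mu <- colMeans(bg_counts)
  B <- nrow(bg_counts)
  sdev <- sqrt(colMeans(bg_counts^2) - mu^2)   # population sd
  if (sd_method == "sample") sdev <- sdev * sqrt(B / (B - 1))
  obs <- as.numeric(fg_counts)
  z <- (obs - mu) / sdev
  degen <- sdev == 0
  z[degen & obs == mu] <- 0
  z[degen & obs > mu] <- Inf
  z[degen & obs < mu] <- -Inf
  out <- data.frame(kmer = kmers, count = as.integer(obs),
                    freq = obs / sum(obs), bg_mean = mu, bg_sd = sdev,
                    z = z, n_pyrimidines = pyrimidine_count(kmers),
                    degenerate = degen & obs != mu,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("kmer_enrichment", "data.frame")
  out
}

#' End-to-end k-mer enrichment for a set of annotated sites
#'
#' Extracts foreground site sequences, samples `B` region- and
#' length-matched background replicates and returns the per-k-mer
#' enrichment table.
#'
#' @param sites annotated site data.frame.
#' @param ann an [annotation_set()].
#' @param genome genome sequences.
#' @param k word length (default 5).
#' @param B background replicates (default 100).
#' @param seed integer seed for background sampling.
#' @param features optional precomputed [region_features()] of `ann`.
#' @return A `kmer_enrichment` data.frame (see [kmer_enrichment()]).
#' @export
kmer_enrichment_analysis <- function(sites, ann, genome, k = 5, B = 100,
                                     seed = 1, features = NULL) {
  genome <- as_genome(genome)
  bg <- sample_background(sites, ann, B = B, seed = seed,
                          features = features)
  codes <- kmer_code_genome(genome, k)
  fg <- foreground_kmer_counts(bg$sites, genome, k, codes = codes)
  kmer_enrichment(fg, background_kmer_counts(bg, genome, k, codes = codes))
}
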