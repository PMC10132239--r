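#' Read a genome FASTA into a named character vector
#'
#' Contig sequences are held as upper-case character strings keyed by
#' contig name (the first whitespace-delimited token of the FASTA header).
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  validate_genome(seqs)
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

## Normalise genome inputs (DNAStringSet or named character) to a named
## upper-case character vector.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- toupper(as.character(genome))
    names(g) <- sub("\\s.*$", "", names(genome))
    genome <- g
  }
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) ||
      anyNA(genome) || any(!nzchar(genome)))
    stop_("genome must be a non-empty named character vector of sequences")
  bad <- stringi::stri_detect_regex(genome, "[^ACGTN]")
  if (any(bad))
    stop_("contig(s) %s contain characters outside {A,C,G,T,N}",
          paste(names(genome)[bad], collapse = ", "))
  invisible(genome)
}

#' Extract the sense-strand sequence of a genomic interval
#'
#' Coordinates are 1-based closed (the package-internal convention).
#' For `strand == "-"` the reverse complement of the forward slice is
#' returned, i.e. the sequence as read by the transcription machinery.
#' All arguments are vectorised and recycled to a common length.
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param contig contig name(s).
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of sequences, `end - start + 1` nt each.
#' @export
extract_sequence <- function(genome, contig, start, end, strand = "+") {
  genome <- as_genome(genome)
  n <- max(length(contig), length(start), length(end), length(strand))
  contig <- rep_len(contig, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-")))
    stop_("strand must be '+' or '-'")
  unknown <- !(contig %in% names(genome))
  if (any(unknown))
    stop_("unknown contig(s): %s", paste(unique(contig[unknown]), collapse = ", "))
  len <- nchar(genome)[contig]
  if (any(start < 1 | end > len | start > end))
    stop_("interval out of bounds for its contig")
  out <- stringi::stri_sub(genome[contig], from = start, to = end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

## GRanges-based convenience wrapper used internally.
extract_granges_sequence <- function(genome, gr) {
  extract_sequence(genome,
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr),
                   as.character(GenomicRanges::strand(gr)))
}

#' @importFrom methods is
NULL
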