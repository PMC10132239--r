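#' @importFrom stats rnorm rbinom rpois runif rexp rlnorm rnbinom rgamma
#'   rbeta rmultinom cor cor.test ks.test wilcox.test ecdf sd setNames
#'   quantile
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib crosslinkr, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## non-standard-evaluation columns used in ggplot calls
utils::globalVariables(c("z", "freq", "n_pyrimidines", "kmer", "offset",
                         "coverage", "log2fc", "bin"))

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

#' Derive a reproducible sub-seed from a base seed and a stream name
#'
#' Module streams are decoupled so that adding a pipeline stage never
#' perturbs the random numbers seen by existing stages.
#'
#' @param seed integer base seed.
#' @param name character scalar naming the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) %% 2147483629 + h) %% 2147483629 + 1L)
}

## Reverse complement of a character vector of DNA strings (A,C,G,T,N).
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

DNA_BASES <- c("A", "C", "G", "T")

REGION_LEVELS <- c("five_prime_utr", "cds", "three_prime_utr",
                   "noncoding_exon", "intron", "intergenic")

## Assignment precedence: exonic categories outrank intron outranks
## intergenic; among exonic, cds > 3'UTR > 5'UTR > noncoding exon.
REGION_PRECEDENCE <- c(cds = 1, three_prime_utr = 2, five_prime_utr = 3,
                       noncoding_exon = 4, intron = 5, intergenic = 6)
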