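#' Per-gene crosslink occupancy (XPM / NXPM)
#'
#' XPM is crosslink reads per million library crosslink reads:
#' `reads * 1e6 / library_total`. NXPM normalises XPM by mRNA abundance:
#' `NXPM = XPM / TPM`. Genes with control TPM below `tpm_floor` are
#' excluded (division stability); expressed genes without a single
#' assigned site are the non-targets. Bound genes missing from the
#' expression table are excluded with a warning.
#'
#' @param sites annotated site data.frame (one table; pool replicates
#'   first if desired).
#' @param expr expression table (`gene_id`, `tpm_control`, `log2fc`,
#'   `padj`).
#' @param library_total total library crosslink reads; defaults to the
#'   sum over `sites`.
#' @param tpm_floor minimum control TPM (default 1).
#' @return data.frame of gene binding profiles: `gene_id`, `n_sites`,
#'   `crosslink_reads`, `tpm`, `xpm`, `nxpm`, `log2fc`, `padj`.
#' @export
compute_nxpm <- function(sites, expr, library_total = NULL, tpm_floor = 1) {
  sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
  library_total <- library_total %||% sum(sites$crosslink_reads)
  if (library_total <= 0) stop_("library crosslink total must be positive")
  reads <- tapply(sites$crosslink_reads, sites$gene_id, sum)
  nsite <- tapply(sites$gene_id, sites$gene_id, length)
  bound_missing <- setdiff(names(reads), expr$gene_id)
  if (length(bound_missing))
    warn_("%d bound gene(s) missing from the expression table; excluded",
          length(bound_missing))
  df <- expr[expr$tpm_control >= tpm_floor, , drop = FALSE]
  r <- as.numeric(reads[df$gene_id]); r[is.na(r)] <- 0
  ns <- as.integer(nsite[df$gene_id]); ns[is.na(ns)] <- 0L
  xpm <- r * 1e6 / library_total
  out <- data.frame(gene_id = df$gene_id, n_sites = ns,
                    crosslink_reads = as.integer(r), tpm = df$tpm_control,
                    xpm = xpm, nxpm = xpm / df$tpm_control,
                    log2fc = df$log2fc, padj = df$padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin gene profiles by NXPM occupancy
#'
#' Non-target means zero assigned sites; bound genes fall into
#' `low = (0, e1]`, `mid = (e1, e2]`, `high = (e2, Inf)` with default
#' edges 20 and 50 (half-open on the left, closed on the right; NXPM
#' below 1 folds into the low bin).
#'
#' @param profiles output of [compute_nxpm()].
#' @param edges two increasing positive bin edges.
#' @return `profiles` with an ordered factor column `bin` (levels
#'   `non_target`, `low`, `mid`, `high`).
#' @export
bin_by_nxpm <- function(profiles, edges = c(20, 50)) {
  if (length(edges) != 2 || is.unsorted(edges, strictly = TRUE) ||
      any(edges <= 0))
    stop_("edges must be two strictly increasing positive values")
  lv <- c("non_target", "low", "mid", "high")
  idx <- ifelse(profiles$n_sites == 0, 0L,
                findInterval(profiles$nxpm, c(0, edges), left.open = TRUE))
  profiles$bin <- factor(lv[idx + 1L], levels = lv, ordered = TRUE)
  profiles
}

#' Compare knockdown fold-change distributions across occupancy bins
#'
#' Each bound bin is compared with the non-target bin by a two-sided
#' two-sample Kolmogorov-Smirnov test (asymptotic p-values); the ECDFs
#' themselves are returned for plotting. Bins below `min_n` genes are
#' skipped with a warning.
#'
#' @param profiles binned profiles ([bin_by_nxpm()]).
#' @param min_n minimum genes per compared bin (default 5).
#' @return List of class `fc_comparison`: `tests` (data.frame `bin`,
#'   `n`, `D`, `p`), `ecdf` (named list of ECDF functions incl.
#'   non-target), `n_non_target`.
#' @export
fold_change_cdf_compare <- function(profiles, min_n = 5) {
  if (!"bin" %in% names(profiles)) stop_("profiles are not binned")
  ref <- profiles$log2fc[profiles$bin == "non_target"]
  if (length(ref) < min_n) stop_("non-target bin has fewer than %d genes", min_n)
  bins <- c("low", "mid", "high")
  tests <- data.frame(bin = bins, n = NA_integer_, D = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  ec <- list(non_target = stats::ecdf(ref))
  for (i in seq_along(bins)) {
    x <- profiles$log2fc[profiles$bin == bins[i]]
    tests$n[i] <- length(x)
    if (length(x) < min_n) {
      warn_("bin %s has %d < %d genes; comparison skipped", bins[i],
            length(x), min_n)
      next
    }
    kt <- suppressWarnings(stats::ks.test(x, ref, exact = FALSE))
    tests$D[i] <- unname(kt$statistic)
    tests$p[i] <- kt$p.value
    ec[[bins[i]]] <- stats::ecdf(x)
  }
  structure(list(tests = tests, ecdf = ec, n_non_target = length(ref)),
            class = "fc_comparison")
}

#' Correlate binding with gene architecture
#'
#' Spearman correlation of per-gene binding-site count against each
#' architectural feature, plus a one-sided rank test (Wilcoxon) of GC
#' content in the high-occupancy bin against non-targets (alternative:
#' high-bin GC is lower).
#'
#' @param profiles binned profiles ([bin_by_nxpm()]).
#' @param architecture output of [gene_architecture()].
#' @return List of class `architecture_report`: `correlations`
#'   (data.frame `feature`, `rho`, `p`), `gc_test` (list `p`,
#'   `n_high`, `n_non_target`), `n_genes`.
#' @export
correlate_architecture <- function(profiles, architecture) {
  df <- merge(profiles, architecture, by = "gene_id")
  if (nrow(df) < 10) stop_("fewer than 10 genes shared between tables")
  feats <- c("transcript_length", "exon_count", "mean_exon_length",
             "intron_length", "gc_content")
  cors <- lapply(feats, function(f) {
    ct <- suppressWarnings(stats::cor.test(df$n_sites, df[[f]],
                                           method = "spearman"))
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  gc_hi <- df$gc_content[df$bin == "high"]
  gc_nt <- df$gc_content[df$bin == "non_target"]
  gc_test <- list(p = NA_real_, n_high = length(gc_hi),
                  n_non_target = length(gc_nt))
  if (length(gc_hi) >= 3 && length(gc_nt) >= 3)
    gc_test$p <- suppressWarnings(
      stats::wilcox.test(gc_hi, gc_nt, alternative = "less"))$p.value
  structure(list(correlations = do.call(rbind, cors), gc_test = gc_test,
                 n_genes = nrow(df)),
            class = "architecture_report")
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` per condition;
#' `ddCt = dCt(treated) - dCt(control)`; the returned fold change is
#' `2^-ddCt`. Swapping treated and control inverts the fold change.
#'
#' @param target_treated,reference_treated,target_control,reference_control
#'   numeric Ct replicate vectors (finite, non-empty).
#' @return List: `dct_treated`, `dct_control`, `ddct`, `fold_change`.
#' @export
relative_expression_ddct <- function(target_treated, reference_treated,
                                     target_control, reference_control) {
  vals <- list(target_treated, reference_treated, target_control,
               reference_control)
  if (any(!vapply(vals, function(v) length(v) > 0 && all(is.finite(v)),
                  logical(1))))
    stop_("all four Ct vectors must be non-empty and finite")
  dct_t <- mean(target_treated) - mean(reference_treated)
  dct_c <- mean(target_control) - mean(reference_control)
  ddct <- dct_t - dct_c
  list(dct_treated = dct_t, dct_control = dct_c, ddct = ddct,
       fold_change = 2^-ddct)
}
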