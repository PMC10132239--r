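need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_("ggplot2 is required for plotting")
}

#' Z-score vs frequency scatter of k-mer enrichment
#'
#' Mirrors the classic enrichment scatter: Z on x, foreground frequency
#' on y, points shaded by pyrimidine count.
#'
#' @param tab a `kmer_enrichment` table.
#' @param label_top label the top n k-mers by Z (default 5).
#' @return A ggplot object.
#' @export
plot_kmer_scatter <- function(tab, label_top = 5) {
  need_ggplot()
  tab <- tab[is.finite(tab$z), , drop = FALSE]
  top <- tab[order(-tab$z), ][seq_len(min(label_top, nrow(tab))), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = z, y = freq,
                                    colour = n_pyrimidines)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = kmer),
                       vjust = -0.6, size = 3, colour = "black") +
    ggplot2::scale_colour_gradient(low = "grey85", high = "darkgreen",
                                   name = "pyrimidines") +
    ggplot2::labs(x = "Z score", y = "frequency of occurrence")
}

#' Metagene coverage line plot
#'
#' @param profile a `metagene_profile` table.
#' @return A ggplot object.
#' @export
plot_metagene_profile <- function(profile) {
  need_ggplot()
  ggplot2::ggplot(profile, ggplot2::aes(x = offset, y = coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "position relative to 3' splice site (nt)",
                  y = "fraction of boundaries covered")
}

#' Cumulative fold-change distributions by occupancy bin
#'
#' @param profiles binned gene profiles ([bin_by_nxpm()]).
#' @return A ggplot object.
#' @export
plot_fold_change_ecdf <- function(profiles) {
  need_ggplot()
  ggplot2::ggplot(profiles, ggplot2::aes(x = log2fc,
                                         colour = bin)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "log2 fold change (knockdown / control)",
                  y = "cumulative fraction", colour = "NXPM bin")
}
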