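EVENT_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")

#' Read an rMATS-style alternative-splicing event table
#'
#' Expected columns: `event_id`, `type`, `gene_id`, `ijc_control`,
#' `sjc_control`, `ijc_kd`, `sjc_kd`, `psi_control`, `psi_kd`, `dpsi`,
#' `fdr`. Delta-PSI is knockdown minus control (positive = inclusion upon
#' knockdown). PSI values must lie in [0, 1]; rows whose `dpsi` disagrees
#' with `psi_kd - psi_control` beyond `tol` are flagged in a
#' `consistent` column, not dropped.
#'
#' @param path TSV path.
#' @param tol delta-PSI consistency tolerance (default 0.01).
#' @return data.frame of events.
#' @export
read_splicing_table <- function(path, tol = 0.01) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "type", "gene_id", "ijc_control", "sjc_control",
            "ijc_kd", "sjc_kd", "psi_control", "psi_kd", "dpsi", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("splicing table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$type), EVENT_TYPES)
  if (length(bad))
    stop_("unknown event type(s): %s", paste(bad, collapse = ", "))
  if (any(df$psi_control < 0 | df$psi_control > 1 |
          df$psi_kd < 0 | df$psi_kd > 1, na.rm = TRUE))
    stop_("PSI outside [0, 1] in %s", path)
  if (any(abs(df$dpsi) > 1, na.rm = TRUE))
    stop_("|dpsi| > 1 in %s", path)
  if (any(df$ijc_control < 0 | df$sjc_control < 0 | df$ijc_kd < 0 |
          df$sjc_kd < 0))
    stop_("negative junction read counts in %s", path)
  df$consistent <- abs(df$dpsi - (df$psi_kd - df$psi_control)) <= tol
  if (any(!df$consistent))
    warn_("%d event(s) with dpsi inconsistent with per-condition PSI (flagged)",
          sum(!df$consistent))
  df
}

#' Filter splicing events by read support, effect size and FDR
#'
#' Retains events with total supporting junction reads at or above
#' `min_reads`, `|dpsi| >= min_dpsi` and `fdr < max_fdr`. "Supporting
#' reads" defaults to inclusion plus skipping junction reads summed over
#' both conditions (`reads_rule = "total"`); `"per_condition"` instead
#' requires each condition to reach `min_reads` on its own. The filter is
#' idempotent and shrinks monotonically as any threshold tightens.
#'
#' @param events event data.frame ([read_splicing_table()]).
#' @param min_reads minimum supporting reads (default 5).
#' @param min_dpsi minimum |delta-PSI| (default 0.10).
#' @param max_fdr FDR bound, strict (default 0.05).
#' @param reads_rule `"total"` or `"per_condition"`.
#' @return The retained rows of `events`.
#' @export
filter_events <- function(events, min_reads = 5, min_dpsi = 0.10,
                          max_fdr = 0.05,
                          reads_rule = c("total", "per_condition")) {
  reads_rule <- match.arg(reads_rule)
  if (min_reads < 0 || min_dpsi < 0 || min_dpsi > 1 || max_fdr < 0)
    stop_("thresholds must be non-negative (min_dpsi <= 1)")
  rc <- events$ijc_control + events$sjc_control
  rk <- events$ijc_kd + events$sjc_kd
  ok_reads <- if (reads_rule == "total") (rc + rk) >= min_reads
              else rc >= min_reads & rk >= min_reads
  keep <- ok_reads & abs(events$dpsi) >= min_dpsi & events$fdr < max_fdr
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count and fraction of retained events per type
#'
#' @param events retained event data.frame.
#' @return data.frame `type`, `count`, `fraction` over the closed event
#'   vocabulary; fractions sum to 1.
#' @export
categorize_events <- function(events) {
  if (!nrow(events)) stop_("no events to categorise")
  counts <- table(factor(events$type, levels = EVENT_TYPES))
  data.frame(type = EVENT_TYPES, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(events),
             stringsAsFactors = FALSE)
}

#' Intersect splicing events with the binding target set
#'
#' Reports the fraction of events hosted in target genes and, among
#' skipped-exon events in targets, the fraction with positive delta-PSI
#' (exon inclusion upon knockdown).
#'
#' @param events retained event data.frame.
#' @param targets character vector of target gene ids (non-empty).
#' @return List: `n_events`, `n_in_targets`, `target_fraction`,
#'   `n_se_in_targets`, `n_se_inclusion`, `inclusion_fraction`.
#' @export
intersect_with_targets <- function(events, targets) {
  if (!length(targets)) stop_("empty target gene set")
  if (!nrow(events)) stop_("no events given")
  in_t <- events$gene_id %in% targets
  se_t <- events[in_t & events$type == "SE", , drop = FALSE]
  n_inc <- sum(se_t$dpsi > 0)
  list(n_events = nrow(events),
       n_in_targets = sum(in_t),
       target_fraction = mean(in_t),
       n_se_in_targets = nrow(se_t),
       n_se_inclusion = n_inc,
       inclusion_fraction = if (nrow(se_t)) n_inc / nrow(se_t) else NA_real_)
}
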