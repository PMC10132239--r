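#' Read a BED-like binding-site cluster file
#'
#' Expected columns (tab-separated, with header): `contig`, `start`,
#' `end`, `name`, `crosslink_reads`, `strand`, `tc_conversions`,
#' `gene_id`. File coordinates are 0-based half-open (BED convention) and
#' are converted to the package-internal 1-based closed convention on
#' read. `gene_id` may be empty/NA for unassigned sites.
#'
#' @param path cluster TSV path.
#' @param max_conversion_ratio validation bound: `tc_conversions` may not
#'   exceed this multiple of `crosslink_reads`.
#' @return data.frame of sites (1-based closed `start`/`end`).
#' @export
read_binding_sites <- function(path, max_conversion_ratio = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "name", "crosslink_reads", "strand",
            "tc_conversions")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("cluster file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop_("cluster file %s: end <= start at row(s) %s", path,
          paste(bad, collapse = ", "))
  bad <- which(df$crosslink_reads < 0 | df$tc_conversions < 0)
  if (length(bad))
    stop_("cluster file %s: negative counts at row(s) %s", path,
          paste(bad, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop_("cluster file %s: strand must be '+' or '-'", path)
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop_("cluster file %s: duplicate site id(s): %s", path,
          paste(unique(dup), collapse = ", "))
  bad <- which(df$tc_conversions > max_conversion_ratio * df$crosslink_reads)
  if (length(bad))
    stop_("cluster file %s: conversions exceed %g x reads at row(s) %s",
          path, max_conversion_ratio, paste(bad, collapse = ", "))
  df$start <- as.integer(df$start) + 1L   # 0-based half-open -> 1-based closed
  df$end <- as.integer(df$end)
  df
}

#' Write binding sites to a BED-like cluster TSV
#'
#' Inverse of [read_binding_sites()]: internal 1-based closed coordinates
#' are written 0-based half-open.
#'
#' @param sites site data.frame (internal convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binding_sites <- function(sites, path) {
  out <- sites[, intersect(c("contig", "start", "end", "name",
                             "crosslink_reads", "strand", "tc_conversions",
                             "gene_id", "region"), names(sites)),
               drop = FALSE]
  out$start <- as.integer(out$start) - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$contig,
                         IRanges::IRanges(sites$start, sites$end),
                         strand = sites$strand)
}

#' Assign each binding site to an annotation region and host gene
#'
#' A site is matched strand-aware against the region features of the
#' annotation ([region_features()]). When a site overlaps several
#' features (across isoforms or genes) one category is chosen
#' deterministically by precedence `cds > three_prime_utr >
#' five_prime_utr > noncoding_exon > intron`; ties across genes are
#' broken by larger overlap, then smaller gene id. A site straddling an
#' exon-intron boundary therefore takes the exonic category. Sites
#' overlapping nothing are `intergenic` with `gene_id` NA.
#'
#' @param sites site data.frame (from [read_binding_sites()] or a
#'   generator).
#' @param ann an [annotation_set()].
#' @param features optional precomputed [region_features()] of `ann`.
#' @return `sites` with columns `region` and `gene_id` (re)filled.
#' @export
assign_regions <- function(sites, ann, features = NULL) {
  feats <- features %||% region_features(ann)
  gr <- sites_granges(sites)
  hits <- GenomicRanges::findOverlaps(gr, feats, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  region <- rep("intergenic", nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  if (length(q)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[q], feats[s]))
    cand <- data.frame(q = q,
                       region = S4Vectors::mcols(feats)$region[s],
                       gene_id = S4Vectors::mcols(feats)$gene_id[s],
                       ov = ov, stringsAsFactors = FALSE)
    cand$prec <- REGION_PRECEDENCE[cand$region]
    cand <- cand[order(cand$q, cand$prec, -cand$ov, cand$gene_id), ,
                 drop = FALSE]
    best <- cand[!duplicated(cand$q), , drop = FALSE]
    region[best$q] <- best$region
    gene[best$q] <- best$gene_id
  }
  sites$region <- region
  sites$gene_id <- gene
  sites
}

#' Fraction of binding sites per annotation category
#'
#' @param sites site data.frame with a `region` column (see
#'   [assign_regions()]).
#' @param weight `"site"` counts each site once; `"reads"` weights each
#'   site by its crosslink reads.
#' @return Named numeric vector over the region vocabulary; sums to 1.
#' @export
region_distribution <- function(sites, weight = c("site", "reads")) {
  weight <- match.arg(weight)
  if (!nrow(sites)) stop_("no sites given")
  if (!"region" %in% names(sites)) stop_("sites lack a region column")
  w <- if (weight == "site") rep(1, nrow(sites)) else sites$crosslink_reads
  tot <- tapply(w, factor(sites$region, levels = REGION_LEVELS), sum,
                default = 0)
  stats::setNames(as.vector(tot / sum(tot)), REGION_LEVELS)
}

#' Target genes of a replicate
#'
#' A target is a gene with at least one assigned binding site.
#'
#' @param sites annotated site data.frame.
#' @return Character vector of gene ids.
#' @export
target_genes <- function(sites) {
  sort(unique(sites$gene_id[!is.na(sites$gene_id)]))
}

#' Replicate target-set overlap (Venn cells)
#'
#' @param target_sets named list (length >= 2) of per-replicate target
#'   gene id vectors.
#' @return List with `cells` (data.frame: one row per non-empty replicate
#'   subset, membership pattern, exclusive count) and
#'   `intersection` (genes present in every replicate).
#' @export
replicate_overlap <- function(target_sets) {
  if (length(target_sets) < 2) stop_("need at least 2 replicates")
  if (is.null(names(target_sets)) || anyDuplicated(names(target_sets)))
    stop_("target sets must have unique names")
  labs <- names(target_sets)
  all_genes <- unique(unlist(target_sets))
  member <- vapply(target_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, labs))
  pattern <- apply(member, 1, function(z) paste(labs[z], collapse = "&"))
  combos <- unlist(lapply(seq_along(labs), function(m)
    utils::combn(labs, m, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = combos))
  cells <- data.frame(subset = combos,
                      n_replicates = lengths(strsplit(combos, "&", fixed = TRUE)),
                      exclusive_count = as.integer(counts),
                      stringsAsFactors = FALSE)
  inter <- Reduce(intersect, target_sets)
  list(cells = cells, intersection = sort(inter))
}

#' Replicate concordance of crosslinked read signal
#'
#' Per-gene T-to-C-weighted read totals (the sum of `tc_conversions` per
#' gene) are compared between every pair of replicates over the union of
#' genes bound in any replicate (absent = 0). Both Spearman's rho (on raw
#' counts) and squared Pearson r on log1p-transformed counts are
#' reported. A replicate with zero variance yields NA (flagged), not 0.
#'
#' @param site_tables named list of >= 2 annotated site data.frames.
#' @return List with matrices `spearman` and `pearson_r2_log1p`, the
#'   per-gene count matrix `counts`, and `n_genes`.
#' @export
replicate_concordance <- function(site_tables) {
  if (length(site_tables) < 2) stop_("need at least 2 replicates")
  labs <- names(site_tables)
  per_gene <- lapply(site_tables, function(df) {
    df <- df[!is.na(df$gene_id), , drop = FALSE]
    tapply(df$tc_conversions, df$gene_id, sum)
  })
  genes <- sort(unique(unlist(lapply(per_gene, names))))
  if (!length(genes)) stop_("no genes with assigned sites")
  m <- vapply(per_gene, function(v) {
    x <- as.numeric(v[genes]); x[is.na(x)] <- 0; x
  }, numeric(length(genes)))
  rownames(m) <- genes; colnames(m) <- labs
  zero_var <- apply(m, 2, stats::sd) == 0
  sp <- suppressWarnings(stats::cor(m, method = "spearman"))
  pe <- suppressWarnings(stats::cor(log1p(m), method = "pearson"))^2
  sp[zero_var, ] <- NA; sp[, zero_var] <- NA
  pe[zero_var, ] <- NA; pe[, zero_var] <- NA
  diag(sp)[!zero_var] <- 1; diag(pe)[!zero_var] <- 1
  if (any(zero_var))
    warn_("replicate(s) with zero variance: %s",
          paste(labs[zero_var], collapse = ", "))
  list(spearman = sp, pearson_r2_log1p = pe, counts = m,
       n_genes = length(genes))
}
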