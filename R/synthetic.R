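#' Configuration for the synthetic PAR-CLIP / RNA-seq dataset
#'
#' One seeded configuration drives every generator, so the whole pipeline
#' can be reproduced byte-for-byte from this object alone. Defaults encode
#' the structure the downstream analyses assume: ~70% of binding sites
#' intronic, positions concentrated near 3' splice sites with an
#' exponential decay, a planted pyrimidine 5-mer at a fraction of sites,
#' occupancy-dependent down-regulation upon knockdown, and an excess of
#' exon-inclusion (positive delta-PSI) skipped-exon events in bound genes.
#'
#' @param n_genes number of genes on the toy genome.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param noncoding_fraction fraction of genes without a CDS.
#' @param exon_counts integer vector of possible exon counts per gene.
#' @param exon_count_probs sampling weights for `exon_counts` (uniform
#'   when `NULL`).
#' @param exon_length_mean,exon_length_min,exon_length_size negative
#'   binomial exon-length model (nt): `min + NB(mu = mean - min, size)`.
#' @param intron_length_mean,intron_length_min,intron_length_size same
#'   model for intron lengths (nt).
#' @param utr5_length,utr3_length target UTR lengths (nt) for coding genes.
#' @param intergenic_gap gap between consecutive genes (nt).
#' @param gc_content background GC fraction of gene bodies.
#' @param target_gc_shift additive GC shift applied to target gene bodies
#'   (negative = AT-rich targets).
#' @param target_fraction fraction of genes that are bound targets.
#' @param n_sites total binding sites in the base (pre-dropout) site set.
#' @param site_length cluster length (nt).
#' @param intronic_site_prob probability a site is placed in an intron.
#' @param ss_decay exponential decay length (nt) of the gap between a
#'   site's 3' edge and the downstream exon start.
#' @param motif planted k-mer (DNA alphabet, written on the gene strand).
#' @param plant_rate fraction of sites whose centre receives the motif.
#' @param n_replicates number of PAR-CLIP replicates.
#' @param replicate_dropout per-replicate probability a base site is
#'   missing from that replicate.
#' @param site_strength_meanlog,site_strength_sdlog lognormal per-site
#'   strength shared across replicates (drives concordance).
#' @param reads_size negative binomial size for per-replicate crosslink
#'   reads around the site strength.
#' @param conversion_specificity binomial probability a crosslink read
#'   carries a T-to-C conversion.
#' @param tpm_meanlog,tpm_sdlog lognormal TPM model (normalised to 1e6).
#' @param tpm_floor control-TPM floor under which genes are dropped from
#'   occupancy binning.
#' @param lfc_slope mean log2 fold-change decrease per occupancy bin
#'   (non-target, low, mid, high = 0..3 bin index).
#' @param lfc_sd Gaussian noise sd on log2 fold change.
#' @param nxpm_edges NXPM bin edges (low/mid and mid/high).
#' @param balanced_bins when `TRUE`, genes are assigned to the four
#'   occupancy bins in equal numbers (`n_genes` divisible by 4) and reads
#'   are drawn to match the assigned NXPM; used for calibrated recovery
#'   experiments.
#' @param sites_per_target_mean mean extra sites per target gene in
#'   balanced mode.
#' @param n_null_events,n_effect_events numbers of background and planted
#'   splicing events.
#' @param target_event_fraction probability a planted event is hosted in
#'   a bound (target) gene rather than a non-target.
#' @param inclusion_bias probability a planted skipped-exon event in a
#'   target gene has positive delta-PSI (inclusion upon knockdown);
#'   planted events in non-targets are sign-balanced.
#' @param event_type_probs named sampling weights over event types
#'   `SE, A5SS, A3SS, MXE, RI` for background events.
#' @param effect_dpsi_min,effect_dpsi_max |delta-PSI| range of planted
#'   events.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200,
                             seed = 1,
                             noncoding_fraction = 0.10,
                             exon_counts = 2:8,
                             exon_count_probs = NULL,
                             exon_length_mean = 150,
                             exon_length_min = 30,
                             exon_length_size = 3,
                             intron_length_mean = 1000,
                             intron_length_min = 150,
                             intron_length_size = 2,
                             utr5_length = 50,
                             utr3_length = 150,
                             intergenic_gap = 300,
                             gc_content = 0.5,
                             target_gc_shift = -0.05,
                             target_fraction = 0.5,
                             n_sites = 10000,
                             site_length = 41,
                             intronic_site_prob = 0.70,
                             ss_decay = 30,
                             motif = "TCTTC",
                             plant_rate = 0.30,
                             n_replicates = 3,
                             replicate_dropout = 0.05,
                             site_strength_meanlog = log(12),
                             site_strength_sdlog = 0.9,
                             reads_size = 5,
                             conversion_specificity = 0.7,
                             tpm_meanlog = log(20),
                             tpm_sdlog = 1.2,
                             tpm_floor = 1,
                             lfc_slope = 0.15,
                             lfc_sd = 0.4,
                             nxpm_edges = c(20, 50),
                             balanced_bins = FALSE,
                             sites_per_target_mean = 3,
                             n_null_events = 500,
                             n_effect_events = 300,
                             target_event_fraction = 0.75,
                             inclusion_bias = 0.66,
                             event_type_probs = c(SE = 0.70, A5SS = 0.08,
                                                  A3SS = 0.08, MXE = 0.07,
                                                  RI = 0.07),
                             effect_dpsi_min = 0.12,
                             effect_dpsi_max = 0.50) {
  cfg <- as.list(environment())
  probs <- c(cfg$noncoding_fraction, cfg$target_fraction,
             cfg$intronic_site_prob, cfg$plant_rate,
             cfg$replicate_dropout, cfg$conversion_specificity,
             cfg$target_event_fraction, cfg$inclusion_bias)
  if (any(probs < 0 | probs > 1))
    stop_("all probability parameters must lie in [0, 1]")
  if (!grepl("^[ACGT]+$", cfg$motif))
    stop_("motif must be a DNA string over {A,C,G,T}")
  if (nchar(cfg$motif) > cfg$site_length)
    stop_("motif (%d nt) longer than site length (%d nt)",
          nchar(cfg$motif), cfg$site_length)
  if (cfg$n_genes < 2 || cfg$n_replicates < 1)
    stop_("need at least 2 genes and 1 replicate")
  if (any(cfg$exon_counts < 1))
    stop_("exon counts must be positive")
  if (cfg$balanced_bins && cfg$n_genes %% 4L != 0L)
    stop_("balanced_bins requires n_genes divisible by 4")
  if (is.unsorted(cfg$nxpm_edges, strictly = TRUE) || any(cfg$nxpm_edges <= 0))
    stop_("nxpm_edges must be strictly increasing and positive")
  class(cfg) <- "synthetic_config"
  cfg
}

rlen <- function(n, mean, size, min) {
  min + stats::rnbinom(n, mu = max(mean - min, 1), size = size)
}

rand_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ## codepoints of A, C, G, T
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = p)])
}

## transcript-coordinate -> genomic coordinate for one transcript
tx_to_genomic <- function(pos, starts, ends, strand) {
  lens <- ends - starts + 1L
  cum <- cumsum(lens)
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends)
                       lens <- rev(lens); cum <- cumsum(lens) }
  vapply(pos, function(p) {
    j <- which(p <= cum)[1]
    off <- p - c(0L, cum)[j] - 1L
    if (strand == "+") starts[j] + off else ends[j] - off
  }, numeric(1))
}

#' Generate a toy genome and matching annotation
#'
#' Genes are laid out non-overlapping on a single contig with fixed
#' intergenic gaps; exon/intron structure, strand, biotype and the target
#' flag are drawn per gene; gene-body base composition is i.i.d. with the
#' configured GC (target genes receive `target_gc_shift`).
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_genome` with elements `genome`
#'   (named character), `annotation` ([annotation_set()]), `targets`
#'   (character vector of target gene ids) and `config`.
#' @export
generate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(derive_seed(cfg$seed, "genome"), {
    n <- cfg$n_genes
    ids <- sprintf("gene_%04d", seq_len(n))
    n_ex <- sample(cfg$exon_counts, n, replace = TRUE,
                   prob = cfg$exon_count_probs)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    coding <- stats::runif(n) >= cfg$noncoding_fraction
    targets <- sort(sample(ids, round(cfg$target_fraction * n)))
    is_target <- ids %in% targets

    gap <- cfg$intergenic_gap
    pieces <- character(2L * n + 1L)
    pieces[1] <- rand_dna(gap, 0.5)
    offset <- gap
    txids <- sprintf("tx_%04d", seq_len(n))
    g_start <- integer(n); g_end <- integer(n)
    cds_start <- rep(NA_integer_, n); cds_end <- rep(NA_integer_, n)
    ex_acc <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_ex[i]
      exl <- rlen(k, cfg$exon_length_mean, cfg$exon_length_size,
                  cfg$exon_length_min)
      inl <- if (k > 1)
        rlen(k - 1L, cfg$intron_length_mean, cfg$intron_length_size,
             cfg$intron_length_min) else integer()
      glen <- sum(exl) + sum(inl)
      gstart <- offset + 1L
      ex_start <- gstart + cumsum(c(0L, head(exl, -1) + inl))
      ex_end <- ex_start + exl - 1L
      gend <- gstart + glen - 1L
      gc <- cfg$gc_content + if (is_target[i]) cfg$target_gc_shift else 0
      gc <- min(max(gc, 0.05), 0.95)
      pieces[2L * i] <- rand_dna(glen, gc)
      pieces[2L * i + 1L] <- rand_dna(gap, 0.5)
      offset <- gend + gap
      g_start[i] <- gstart; g_end[i] <- gend
      if (coding[i]) {
        L <- sum(exl)
        u5 <- min(cfg$utr5_length, floor(L * 0.2))
        u3 <- min(cfg$utr3_length, floor(L * 0.3))
        if (L - u5 - u3 < 3L) { u5 <- 0L; u3 <- 0L }
        g2 <- tx_to_genomic(c(u5 + 1L, L - u3), ex_start, ex_end, strand[i])
        cds_start[i] <- min(g2); cds_end[i] <- max(g2)
      }
      ex_acc[[i]] <- cbind(i, ex_start, ex_end)
    }
    exm <- do.call(rbind, ex_acc)
    genome <- c(chrS = stringi::stri_join(pieces, collapse = ""))
    genes_df <- data.frame(gene_id = ids, contig = "chrS", start = g_start,
                           end = g_end, strand = strand,
                           biotype = ifelse(coding, "protein_coding",
                                            "noncoding"),
                           stringsAsFactors = FALSE)
    tx_df <- data.frame(transcript_id = txids, gene_id = ids,
                        cds_start = cds_start, cds_end = cds_end,
                        stringsAsFactors = FALSE)
    ex_df <- data.frame(transcript_id = txids[exm[, 1]],
                        gene_id = ids[exm[, 1]], contig = "chrS",
                        start = exm[, 2], end = exm[, 3],
                        strand = strand[exm[, 1]], stringsAsFactors = FALSE)
    ann <- annotation_set(genes_df, tx_df, ex_df)
    structure(list(genome = genome, annotation = ann, targets = targets,
                   config = cfg),
              class = "synthetic_genome")
  })
}

## draw TPM for all genes (sums to 1e6)
draw_tpm <- function(sg, cfg) {
  withr::with_seed(derive_seed(cfg$seed, "tpm"), {
    ids <- sg$annotation$genes$gene_id
    x <- stats::rlnorm(length(ids), cfg$tpm_meanlog, cfg$tpm_sdlog)
    stats::setNames(x / sum(x) * 1e6, ids)
  })
}

## Hard-core placement within one gene (see place_gene_sites_cpp):
## clusters called from overlapping reads are disjoint in real PAR-CLIP
## output, so each site retries against already-placed sites, falls back
## to a uniform draw in the same feature class, and only accepts an
## overlap when the gene is saturated.
place_sites_in_gene <- function(gene_ex, strand, gspan, n_intronic, n_exonic,
                                L, decay, max_tries = 10L) {
  s <- gene_ex$start; e <- gene_ex$end
  if (length(s) > 1L) {
    is_ <- e[-length(e)] + 1L; ie_ <- s[-1L] - 1L
  } else {
    is_ <- integer(0); ie_ <- integer(0)
  }
  res <- place_gene_sites_cpp(is_, ie_, s, e, gspan[1], gspan[2],
                              as.integer(n_intronic), as.integer(n_exonic),
                              as.integer(L), decay, as.integer(max_tries),
                              as.integer(strand == "+"))
  list(start = res$start, end = res$end,
       placement = ifelse(res$intronic == 1L, "intron", "exon"),
       law = res$law)
}

#' Generate PAR-CLIP-like binding-site replicates
#'
#' Sites are placed on target genes (intronic with probability
#' `intronic_site_prob`, intron positions decaying exponentially away from
#' the downstream exon start; otherwise uniformly on exons). The planted
#' motif is written into the genome at a `plant_rate` fraction of site
#' centres before the FASTA is emitted, so sequence enrichment is
#' discoverable downstream. Per-replicate crosslink reads share a per-site
#' lognormal strength; T-to-C conversions are
#' `Binomial(reads, conversion_specificity)`.
#'
#' @param sg a `synthetic_genome` from [generate_genome_annotation()].
#' @param cfg the same [synthetic_config()].
#' @param tpm optional named TPM vector (ignored in balanced-bins mode,
#'   where TPM is constructed jointly with reads so that measured NXPM
#'   matches the per-bin draws; the joint TPM is stored in `truth`).
#' @return A list of class `site_replicates`: `replicates` (named list of
#'   per-replicate site data.frames with 1-based closed coordinates),
#'   `base` (pre-dropout site table), `targets`, `genome` (the
#'   motif-planted genome to write out), and `truth` (per-gene true bin
#'   table in balanced mode).
#' @export
generate_binding_sites <- function(sg, cfg = sg$config, tpm = NULL) {
  stopifnot(inherits(sg, "synthetic_genome"), inherits(cfg, "synthetic_config"))
  withr::with_seed(derive_seed(cfg$seed, "sites"), {
    ann <- sg$annotation
    g <- ann$genes
    L <- cfg$site_length
    truth <- NULL

    if (cfg$balanced_bins) {
      ## joint reads/TPM construction: NXPM is invariant to rescaling the
      ## library, so measured NXPM = reads * 1e6 / (library * TPM) equals
      ## the planned value exactly when reads = nxpm * tpm and
      ## sum(nxpm * tpm) over bound genes is 1e6. Bin draws keep a margin
      ## from the edges to absorb per-replicate read noise.
      ids <- g$gene_id
      bins <- sample(rep(0:3, each = length(ids) / 4L))
      targets <- sort(ids[bins > 0])
      nxpm_true <- numeric(length(ids))
      nxpm_true[bins == 1] <- stats::runif(sum(bins == 1), 2, 19)
      nxpm_true[bins == 2] <- stats::runif(sum(bins == 2), 22, 48)
      nxpm_true[bins == 3] <- 55 * exp(stats::runif(sum(bins == 3), 0, 1.5))
      t0 <- pmin(pmax(exp(stats::rnorm(length(ids), 0, 0.8)), 0.25), 8)
      tt <- bins > 0
      tpm_g <- numeric(length(ids))
      tpm_g[tt] <- t0[tt] * 1e6 / sum(nxpm_true[tt] * t0[tt])
      remainder <- 1e6 - sum(tpm_g[tt])
      tpm_g[!tt] <- t0[!tt] / sum(t0[!tt]) * remainder
      gene_reads <- ifelse(tt, pmax(1, round(nxpm_true * tpm_g)), 0)
      n_sites_g <- ifelse(tt, 1L + stats::rpois(length(ids),
                                                cfg$sites_per_target_mean),
                          0L)
      site_gene <- rep(ids, n_sites_g)
      truth <- data.frame(gene_id = ids, true_bin = bins,
                          true_nxpm = nxpm_true, tpm = tpm_g,
                          stringsAsFactors = FALSE)
    } else {
      targets <- sg$targets
      ti <- match(targets, g$gene_id)
      span <- g$end[ti] - g$start[ti] + 1L
      site_gene <- sample(targets, cfg$n_sites, replace = TRUE, prob = span)
    }

    ## genomic placement, per gene
    ex <- ann$exons
    ex_by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
    site_by_gene <- split(seq_along(site_gene), site_gene)
    intronic <- stats::runif(length(site_gene)) < cfg$intronic_site_prob
    acc_s <- integer(0); acc_e <- integer(0)
    acc_pl <- character(0); acc_gene <- character(0); acc_str <- character(0)
    acc_law <- integer(0)
    for (gid in names(site_by_gene)) {
      i <- site_by_gene[[gid]]
      ei <- ex_by_gene[[gid]]
      gi <- match(gid, g$gene_id)
      gex <- list(start = ex$start[ei], end = ex$end[ei])
      has_intron <- length(ei) > 1L
      n_in <- if (has_intron) sum(intronic[i]) else 0L
      n_ex_ <- length(i) - n_in
      p <- place_sites_in_gene(gex, g$strand[gi], c(g$start[gi], g$end[gi]),
                               n_in, n_ex_, L, cfg$ss_decay)
      acc_s <- c(acc_s, p$start); acc_e <- c(acc_e, p$end)
      acc_pl <- c(acc_pl, p$placement)
      acc_law <- c(acc_law, p$law)
      acc_gene <- c(acc_gene, rep(gid, length(p$start)))
      acc_str <- c(acc_str, rep(g$strand[gi], length(p$start)))
    }
    base <- data.frame(start = acc_s, end = acc_e, placement = acc_pl,
                       placement_law = acc_law, gene_id = acc_gene,
                       strand = acc_str, contig = "chrS",
                       stringsAsFactors = FALSE)
    base <- base[sample.int(nrow(base)), , drop = FALSE]  # shuffle order
    rownames(base) <- NULL
    base$name <- sprintf("site_%06d", seq_len(nrow(base)))

    ## plant the motif at site centres (gene-strand aware)
    genome <- sg$genome
    k <- nchar(cfg$motif)
    plant <- which(stats::runif(nrow(base)) < cfg$plant_rate)
    base$planted <- FALSE
    if (length(plant)) {
      base$planted[plant] <- TRUE
      cstart <- base$start[plant] + floor((L - k) / 2)
      mot <- ifelse(base$strand[plant] == "+", cfg$motif, revcomp(cfg$motif))
      chars <- stringi::stri_sub(genome[["chrS"]],
                                 seq_len(nchar(genome[["chrS"]])), length = 1)
      idx <- rep(cstart, each = k) + rep(0:(k - 1), length(cstart))
      chars[idx] <- unlist(stringi::stri_split_boundaries(mot,
                                                          type = "character"))
      genome[["chrS"]] <- stringi::stri_join(chars, collapse = "")
    }

    ## per-site strength shared across replicates
    n_base <- nrow(base)
    if (cfg$balanced_bins) {
      gr <- stats::setNames(gene_reads, ids)
      strength <- numeric(n_base)
      for (gid in unique(base$gene_id)) {
        i <- which(base$gene_id == gid)
        strength[i] <- as.vector(stats::rmultinom(1, gr[[gid]],
                                                  rep(1, length(i)))) + 0.5
      }
    } else {
      strength <- stats::rlnorm(n_base, cfg$site_strength_meanlog,
                                cfg$site_strength_sdlog)
    }

    reps <- vector("list", cfg$n_replicates)
    names(reps) <- sprintf("rep%d", seq_len(cfg$n_replicates))
    for (r in seq_len(cfg$n_replicates)) {
      keep <- stats::runif(n_base) >= cfg$replicate_dropout
      reads <- if (cfg$balanced_bins) {
        pmax(1L, round(strength[keep] * stats::runif(sum(keep), 0.85, 1.15)))
      } else {
        stats::rnbinom(sum(keep), size = cfg$reads_size,
                       mu = strength[keep]) + 1L
      }
      tc <- stats::rbinom(sum(keep), reads, cfg$conversion_specificity)
      reps[[r]] <- data.frame(
        contig = base$contig[keep], start = base$start[keep],
        end = base$end[keep], name = base$name[keep],
        crosslink_reads = as.integer(reads), strand = base$strand[keep],
        tc_conversions = as.integer(tc), gene_id = base$gene_id[keep],
        stringsAsFactors = FALSE)
      rownames(reps[[r]]) <- NULL
    }
    structure(list(replicates = reps, base = base, targets = targets,
                   genome = genome, truth = truth, config = cfg),
              class = "site_replicates")
  })
}

## pooled site table across replicates (per-replicate rows concatenated,
## names made unique per replicate)
pool_replicates <- function(sites) {
  reps <- sites$replicates
  out <- do.call(rbind, Map(function(df, nm) {
    df$name <- paste0(df$name, "_", nm); df
  }, reps, names(reps)))
  rownames(out) <- NULL
  out
}

#' Generate the expression / differential-expression table
#'
#' TPM is lognormal (normalised to sum to 1e6). The knockdown log2 fold
#' change decreases with the gene's occupancy bin: mean
#' `-lfc_slope * bin_index` (bins non-target, low, mid, high = 0..3)
#' plus Gaussian noise. Adjusted p-values are generated, not fitted:
#' uniform for non-targets, left-skewed for bound bins.
#'
#' @param sg a `synthetic_genome`.
#' @param sites a `site_replicates`.
#' @param cfg the shared [synthetic_config()].
#' @param tpm optional named TPM vector (drawn internally when omitted;
#'   pass the same vector used for balanced-bin site generation).
#' @return data.frame with columns `gene_id`, `tpm_control`, `log2fc`,
#'   `padj`; the generating bin is attached as attribute `"true_bin"`.
#' @export
generate_expression_table <- function(sg, sites, cfg = sg$config, tpm = NULL) {
  stopifnot(inherits(sg, "synthetic_genome"), inherits(sites, "site_replicates"))
  if (is.null(tpm)) tpm <- draw_tpm(sg, cfg)
  withr::with_seed(derive_seed(cfg$seed, "expression"), {
    ids <- sg$annotation$genes$gene_id
    pooled <- pool_replicates(sites)
    reads <- tapply(pooled$crosslink_reads, pooled$gene_id, sum)
    gr <- as.numeric(reads[ids]); gr[is.na(gr)] <- 0
    if (!is.null(sites$truth)) {
      i <- match(ids, sites$truth$gene_id)
      bin <- sites$truth$true_bin[i]
      tpm <- stats::setNames(sites$truth$tpm[i], ids)
    } else {
      lib <- sum(gr)
      nxpm <- ifelse(tpm[ids] > 0, gr * 1e6 / lib / tpm[ids], 0)
      bin <- ifelse(gr == 0, 0L,
                    findInterval(nxpm, c(0, cfg$nxpm_edges),
                                 left.open = TRUE))
    }
    lfc <- -cfg$lfc_slope * bin + stats::rnorm(length(ids), 0, cfg$lfc_sd)
    padj <- ifelse(bin == 0, stats::runif(length(ids)),
                   stats::rbeta(length(ids), 0.2, 4))
    out <- data.frame(gene_id = ids, tpm_control = as.numeric(tpm[ids]),
                      log2fc = lfc, padj = padj, stringsAsFactors = FALSE)
    attr(out, "true_bin") <- stats::setNames(bin, ids)
    out
  })
}

#' Generate an rMATS-style alternative-splicing event table
#'
#' Background events span all genes and event types with near-zero
#' delta-PSI and uniform FDR. Planted events are skipped-exon events with
#' |delta-PSI| above the filter threshold, small FDR and ample read
#' support, hosted in bound genes with probability
#' `target_event_fraction`; those in bound genes have positive sign
#' (inclusion upon knockdown) with probability `inclusion_bias`, the
#' rest are sign-balanced.
#'
#' @inheritParams generate_expression_table
#' @return data.frame with columns `event_id`, `type`, `gene_id`,
#'   `ijc_control`, `sjc_control`, `ijc_kd`, `sjc_kd`, `psi_control`,
#'   `psi_kd`, `dpsi`, `fdr`.
#' @export
generate_splicing_table <- function(sg, sites, cfg = sg$config) {
  stopifnot(inherits(sg, "synthetic_genome"), inherits(sites, "site_replicates"))
  withr::with_seed(derive_seed(cfg$seed, "splicing"), {
    ids <- sg$annotation$genes$gene_id
    targets <- sites$targets
    mk_reads <- function(n, psi) {
      tot <- stats::rnbinom(n, mu = 25, size = 3) + 2L
      ijc <- stats::rbinom(n, tot, psi)
      cbind(ijc = ijc, sjc = tot - ijc)
    }
    ## background events
    n0 <- cfg$n_null_events
    null <- NULL
    if (n0 > 0) {
      psi_c <- stats::runif(n0, 0.05, 0.95)
      psi_k <- pmin(pmax(psi_c + stats::rnorm(n0, 0, 0.03), 0), 1)
      rc <- mk_reads(n0, psi_c); rk <- mk_reads(n0, psi_k)
      null <- data.frame(
        type = sample(names(cfg$event_type_probs), n0, replace = TRUE,
                      prob = cfg$event_type_probs),
        gene_id = sample(ids, n0, replace = TRUE),
        ijc_control = rc[, 1], sjc_control = rc[, 2],
        ijc_kd = rk[, 1], sjc_kd = rk[, 2],
        psi_control = psi_c, psi_kd = psi_k,
        dpsi = psi_k - psi_c, fdr = stats::runif(n0),
        stringsAsFactors = FALSE)
    }
    ## planted skipped-exon events in targets
    n1 <- cfg$n_effect_events
    eff <- NULL
    if (n1 > 0) {
      if (!length(targets)) stop_("no target genes to plant events in")
      in_target <- stats::runif(n1) < cfg$target_event_fraction
      non_targets <- setdiff(ids, targets)
      if (!length(non_targets)) in_target[] <- TRUE
      host <- character(n1)
      host[in_target] <- sample(targets, sum(in_target), replace = TRUE)
      host[!in_target] <- sample(non_targets, sum(!in_target),
                                 replace = TRUE)
      p_inc <- ifelse(in_target, cfg$inclusion_bias, 0.5)
      sign <- ifelse(stats::runif(n1) < p_inc, 1, -1)
      mag <- stats::runif(n1, cfg$effect_dpsi_min, cfg$effect_dpsi_max)
      psi_c <- ifelse(sign > 0,
                      stats::runif(n1, 0.05, 1 - 0.05) * (1 - mag - 0.02),
                      mag + 0.02 + stats::runif(n1) * (1 - mag - 0.04))
      psi_k <- psi_c + sign * mag
      rc <- mk_reads(n1, psi_c); rk <- mk_reads(n1, psi_k)
      eff <- data.frame(
        type = "SE",
        gene_id = host,
        ijc_control = rc[, 1], sjc_control = rc[, 2],
        ijc_kd = rk[, 1], sjc_kd = rk[, 2],
        psi_control = psi_c, psi_kd = psi_k,
        dpsi = psi_k - psi_c,
        fdr = 10^-stats::runif(n1, 1.5, 6),
        stringsAsFactors = FALSE)
    }
    ev <- rbind(null, eff)
    if (is.null(ev) || !nrow(ev)) stop_("no events requested")
    ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    ev <- cbind(event_id = sprintf("ev_%05d", seq_len(nrow(ev))), ev,
                stringsAsFactors = FALSE)
    rownames(ev) <- NULL
    ev
  })
}

#' Generate the full synthetic dataset, optionally writing all files
#'
#' Runs the four generators in order under the single seeded
#' configuration. With `out_dir`, writes `genome.fa`, `annotation.gtf`,
#' one BED-like cluster TSV per replicate (0-based half-open),
#' `expression.tsv` and `splicing.tsv`.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir optional output directory (created if needed).
#' @return List with `genome`, `annotation`, `sites`, `expression`,
#'   `splicing`, `targets`, and (when written) `paths`.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  sg <- generate_genome_annotation(cfg)
  tpm <- draw_tpm(sg, cfg)
  sites <- generate_binding_sites(sg, cfg, tpm = tpm)
  expr <- generate_expression_table(sg, sites, cfg, tpm = tpm)
  spl <- generate_splicing_table(sg, sites, cfg)
  res <- list(genome = sites$genome, annotation = sg$annotation,
              sites = sites, expression = expr, splicing = spl,
              targets = sites$targets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      annotation = file.path(out_dir, "annotation.gtf"),
      expression = file.path(out_dir, "expression.tsv"),
      splicing = file.path(out_dir, "splicing.tsv"))
    write_genome(res$genome, paths$genome)
    write_gtf(res$annotation, paths$annotation)
    write_expression_table(expr, paths$expression)
    write_splicing_table(spl, paths$splicing)
    paths$clusters <- stats::setNames(
      file.path(out_dir, sprintf("clusters_%s.tsv", names(sites$replicates))),
      names(sites$replicates))
    for (r in names(sites$replicates))
      write_binding_sites(sites$replicates[[r]], paths$clusters[[r]])
    res$paths <- paths
  }
  res
}
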