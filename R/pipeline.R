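#' Merge replicate site tables into one pooled site set
#'
#' Sites sharing name, position and strand across replicates (the same
#' cluster observed in several replicates) are collapsed to one row with
#' summed crosslink reads and conversions. Distinct clusters that happen
#' to share coordinates remain separate rows.
#'
#' @param site_tables named list of site data.frames.
#' @return One pooled site data.frame.
#' @export
merge_replicate_sites <- function(site_tables) {
  all <- do.call(rbind, unname(site_tables))
  key <- paste(all$name, all$contig, all$start, all$end, all$strand)
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  ukey <- key[first]
  out$crosslink_reads <- as.integer(tapply(all$crosslink_reads, key,
                                           sum)[ukey])
  out$tc_conversions <- as.integer(tapply(all$tc_conversions, key,
                                          sum)[ukey])
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every stage's parameters plus file paths (user-data mode) or
#' a [synthetic_config()] (synthetic mode) under a single global seed.
#'
#' @param mode `"synthetic"` or `"user"`.
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param paths named list for user mode: `genome`, `annotation`,
#'   `clusters` (named vector), `expression`, `splicing`.
#' @param k,B k-mer length and background replicate count.
#' @param upstream,downstream metagene window (nt).
#' @param nxpm_edges NXPM bin edges.
#' @param tpm_floor expression floor for occupancy binning.
#' @param min_reads,min_dpsi,max_fdr splicing-event filter thresholds.
#' @param seed global seed; per-stage streams are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "user"),
                            synthetic = synthetic_config(),
                            paths = NULL,
                            k = 5, B = 100,
                            upstream = 300, downstream = 50,
                            nxpm_edges = c(20, 50), tpm_floor = 1,
                            min_reads = 5, min_dpsi = 0.10, max_fdr = 0.05,
                            seed = 1) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  if (mode == "user") {
    need <- c("genome", "annotation", "clusters", "expression", "splicing")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop_("user-data mode needs path(s): %s", paste(miss, collapse = ", "))
    files <- c(paths$genome, paths$annotation, paths$clusters,
               paths$expression, paths$splicing)
    absent <- files[!file.exists(files)]
    if (length(absent))
      stop_("input file(s) not found: %s", paste(absent, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Stages, in dependency order: (synthetic mode only) data generation;
#' site annotation and region distribution; replicate overlap and
#' concordance; k-mer enrichment; metagene profile; NXPM binning with
#' fold-change CDF comparison and architecture correlation; splicing
#' event filtering, categorisation and target intersection. Each stage
#' writes its table(s) under `out_dir`; a JSON manifest records the
#' package version, seed, parameters and row counts. All randomness is
#' derived from the config seed, so a fixed config reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return A report list with each stage's summary object.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    ds <- generate_dataset(config$synthetic, file.path(out_dir, "data"))
    paths <- list(genome = ds$paths$genome, annotation = ds$paths$annotation,
                  clusters = ds$paths$clusters,
                  expression = ds$paths$expression,
                  splicing = ds$paths$splicing)
  } else {
    paths <- config$paths
  }

  genome <- read_genome(paths$genome)
  ann <- read_gtf(paths$annotation)
  reps <- lapply(paths$clusters, read_binding_sites)
  if (is.null(names(reps)) || any(!nzchar(names(reps))))
    names(reps) <- sprintf("rep%d", seq_along(reps))
  reps <- lapply(reps, assign_regions, ann = ann)
  expr <- read_expression_table(paths$expression)
  events <- read_splicing_table(paths$splicing)

  ## stage 1: region distribution (pooled sites)
  pooled <- merge_replicate_sites(reps)
  region_dist <- region_distribution(pooled)
  write_tsv(data.frame(region = names(region_dist),
                       fraction = as.numeric(region_dist)),
            file.path(out_dir, "region_distribution.tsv"))
  for (r in names(reps))
    write_tsv(reps[[r]], file.path(out_dir, sprintf("sites_annotated_%s.tsv", r)))

  ## stage 2: replicate overlap + concordance
  tsets <- lapply(reps, target_genes)
  overlap <- replicate_overlap(tsets)
  concord <- replicate_concordance(reps)
  write_tsv(overlap$cells, file.path(out_dir, "replicate_overlap.tsv"))
  write_tsv(as.data.frame(concord$spearman),
            file.path(out_dir, "replicate_spearman.tsv"))
  shared_targets <- overlap$intersection

  ## stage 3: k-mer enrichment
  kmers <- kmer_enrichment_analysis(pooled, ann, genome, k = config$k,
                                    B = config$B,
                                    seed = derive_seed(config$seed, "kmer"))
  write_tsv(kmers, file.path(out_dir, "kmer_enrichment.tsv"))

  ## stage 4: metagene profile
  profile <- metagene_profile(pooled, ann, upstream = config$upstream,
                              downstream = config$downstream)
  write_tsv(profile, file.path(out_dir, "metagene_profile.tsv"))

  ## stage 5: occupancy binning + fold-change comparison + architecture
  prof <- compute_nxpm(pooled, expr, tpm_floor = config$tpm_floor)
  prof <- bin_by_nxpm(prof, edges = config$nxpm_edges)
  fc <- fold_change_cdf_compare(prof)
  arch <- gene_architecture(ann, genome)
  arch_rep <- correlate_architecture(prof, arch)
  write_tsv(prof, file.path(out_dir, "gene_binding_profiles.tsv"))
  write_tsv(fc$tests, file.path(out_dir, "fold_change_ks.tsv"))
  write_tsv(arch_rep$correlations,
            file.path(out_dir, "architecture_correlations.tsv"))

  ## stage 6: splicing events
  retained <- filter_events(events, min_reads = config$min_reads,
                            min_dpsi = config$min_dpsi,
                            max_fdr = config$max_fdr)
  categories <- categorize_events(retained)
  target_ix <- intersect_with_targets(retained, shared_targets)
  write_tsv(retained, file.path(out_dir, "splicing_retained.tsv"))
  write_tsv(categories, file.path(out_dir, "splicing_categories.tsv"))

  report <- list(region_distribution = region_dist,
                 replicate_overlap = overlap,
                 replicate_concordance = concord,
                 kmer_enrichment = kmers,
                 metagene = profile,
                 fold_change = fc,
                 architecture = arch_rep,
                 splicing = list(retained = retained,
                                 categories = categories,
                                 targets = target_ix))
  manifest <- list(
    package = "crosslinkr",
    version = as.character(utils::packageVersion("crosslinkr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, mode = config$mode,
    parameters = config[c("k", "B", "upstream", "downstream", "nxpm_edges",
                          "tpm_floor", "min_reads", "min_dpsi", "max_fdr")],
    rows = list(sites = nrow(pooled),
                genes = nrow(ann$genes),
                profiles = nrow(prof),
                events_total = nrow(events),
                events_retained = nrow(retained)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}
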