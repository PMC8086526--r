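# End-to-end orchestration: fst -> regions -> enrichment -> targets ->
# gene sets, with a file contract (TSV/JSON/BED) between stages so each
# stage can be re-run on its own.

#' Assemble and validate a pipeline configuration
#'
#' @param vcf,samples_pop1,samples_pop2,gff,peaks,chrom_sizes,gmt Input
#'   file paths (`peaks` is a character vector of one or more BED files).
#' @param out_dir Output directory.
#' @param estimator F_ST estimator (`"weir_cockerham"` or `"hudson"`).
#' @param quantile Top-quantile HD selection fraction (default 0.01).
#' @param bin_edges Interior F_ST bin edges.
#' @param promoter_up,promoter_down Promoter window in bases.
#' @param min_density Enhancer HD-variant density threshold (default
#'   `1/500`).
#' @param basal_up,basal_down,max_extension Regulatory-domain parameters.
#' @param fdr Gene-set report FDR threshold (default 0.05).
#' @param max_terms Cap on enriched terms kept for the clustering tree
#'   (default 30).
#' @param linkage Tree linkage (default `"average"`).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, samples_pop1, samples_pop2, gff, peaks,
                            chrom_sizes, gmt, out_dir,
                            estimator = "weir_cockerham", quantile = 0.01,
                            bin_edges = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            promoter_up = 1000, promoter_down = 500,
                            min_density = 1 / 500,
                            basal_up = 5000, basal_down = 1000,
                            max_extension = 1e6,
                            fdr = 0.05, max_terms = 30,
                            linkage = "average", seed = 1) {
  cfg <- list(vcf = vcf, samples_pop1 = samples_pop1,
              samples_pop2 = samples_pop2, gff = gff,
              peaks = unlist(peaks), chrom_sizes = chrom_sizes, gmt = gmt,
              out_dir = out_dir, estimator = estimator, quantile = quantile,
              bin_edges = bin_edges, promoter_up = promoter_up,
              promoter_down = promoter_down, min_density = min_density,
              basal_up = basal_up, basal_down = basal_down,
              max_extension = max_extension, fdr = fdr,
              max_terms = max_terms, linkage = linkage, seed = seed)
  inputs <- c(cfg$vcf, cfg$samples_pop1, cfg$samples_pop2, cfg$gff,
              cfg$peaks, cfg$chrom_sizes, cfg$gmt)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("configuration error: input file(s) not found: ",
         paste(missing, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.out <- function(cfg, name) file.path(cfg$out_dir, name)

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: per-site F_ST and HD selection
#'
#' Writes `fst_sites.tsv` (all tested sites with estimator components,
#' clamped F_ST, HD flag and F_ST bin) and `fst_summary.json` (counts,
#' realized threshold, drop reasons).
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the `fst_records` and `hd_selection`.
#' @export
stage_fst <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- allele_counts_from_vcf(cfg$vcf,
                                   read_sample_list(cfg$samples_pop1),
                                   read_sample_list(cfg$samples_pop2))
  fst <- compute_fst(counts, cfg$estimator)
  hd <- select_hd(fst, cfg$quantile)
  sites <- fst
  sites$hd <- sites$fst >= hd$threshold
  sites$bin <- as.character(bin_fst(sites$fst, cfg$bin_edges))
  .write_tsv(sites, .out(cfg, "fst_sites.tsv"))
  .write_json(list(
    estimator = cfg$estimator,
    n_sites_tested = nrow(fst),
    n_monomorphic_dropped = attr(counts, "n_monomorphic_dropped"),
    n_nonbiallelic_skipped = attr(counts, "n_nonbiallelic_skipped"),
    n_low_call_dropped = attr(fst, "n_low_call"),
    n_zero_denominator_dropped = attr(fst, "n_zero_denominator"),
    quantile = cfg$quantile,
    hd_threshold = hd$threshold,
    n_hd_nominal = hd$n_nominal,
    n_hd_selected = hd$n_selected,
    ties_at_threshold = hd$ties
  ), .out(cfg, "fst_summary.json"))
  invisible(list(fst = fst, hd = hd))
}

#' Pipeline stage: region classes
#'
#' Builds promoters, enhancers and coding exons and writes one BED per
#' class, the per-TSS promoter windows and a JSON coverage report.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the named list of region sets (promoter set carries
#'   `windows`).
#' @export
stage_regions <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- read_gene_models(cfg$gff)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  promoters <- build_promoters(models, sizes, cfg$promoter_up,
                               cfg$promoter_down)
  enhancers <- build_enhancers(lapply(cfg$peaks, read_bed), promoters)
  exons <- build_exons(models)
  rs <- list(promoter = promoters, enhancer = enhancers, exon = exons)
  for (nm in names(rs)) {
    write_bed(rs[[nm]]$intervals, .out(cfg, paste0(nm, "s.bed")))
  }
  .write_tsv(promoters$windows, .out(cfg, "promoter_windows.tsv"))
  .write_json(list(
    n_promoter_windows = nrow(promoters$windows),
    coverage = lapply(rs, function(r) {
      list(n_intervals = nrow(r$intervals),
           bases = interval_width(r$intervals),
           genome_fraction = genome_fraction(r, sizes))
    })
  ), .out(cfg, "regions_coverage.json"))
  invisible(rs)
}

.read_fst_sites <- function(cfg) {
  sites <- utils::read.table(.out(cfg, "fst_sites.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  class(sites) <- c("fst_records", "data.frame")
  sites
}

.read_region_sets <- function(cfg) {
  rs <- lapply(stats::setNames(nm = c("promoter", "enhancer", "exon")),
               function(nm) {
                 region_set(nm, read_bed(.out(cfg, paste0(nm, "s.bed"))))
               })
  rs$promoter$windows <- utils::read.table(.out(cfg, "promoter_windows.tsv"),
                                           header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
  rs
}

.hd_from_sites <- function(cfg, sites) {
  variants <- sites[sites$hd, , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(quantile = cfg$quantile, threshold = min(variants$fst),
                 n_total = nrow(sites),
                 n_nominal = ceiling(cfg$quantile * nrow(sites)),
                 n_selected = nrow(variants),
                 ties = nrow(variants) > ceiling(cfg$quantile * nrow(sites)),
                 variants = variants),
            class = "hd_selection")
}

#' Pipeline stage: HD enrichment per region class and F_ST stratum
#'
#' Consumes `fst_sites.tsv` and the region BEDs; writes `enrichment.tsv`
#' and `enrichment.json`.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the `hd_enrichment` table.
#' @export
stage_enrichment <- function(cfg) {
  sites <- .read_fst_sites(cfg)
  rs <- .read_region_sets(cfg)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  enr <- binned_enrichment(sites, .hd_from_sites(cfg, sites), rs,
                           edges = cfg$bin_edges, chrom_sizes = sizes)
  .write_tsv(enr, .out(cfg, "enrichment.tsv"))
  .write_json(enr, .out(cfg, "enrichment.json"))
  invisible(enr)
}

#' Pipeline stage: enhancer target assignment and promoter gene list
#'
#' Density-filters enhancers on HD variants, builds basal-plus-extension
#' regulatory domains, assigns targets, and collects genes whose promoters
#' contain HD variants. Writes `enhancers_filtered.bed` (score = HD
#' count), `enhancer_gene_edges.tsv` and three gene lists
#' (`genes_enhancer.txt`, `genes_promoter.txt`, `genes_union.txt`).
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the filtered enhancers, assignment and
#'   promoter-gene results.
#' @export
stage_targets <- function(cfg) {
  sites <- .read_fst_sites(cfg)
  rs <- .read_region_sets(cfg)
  hd_variants <- sites[sites$hd, c("chrom", "pos")]
  models <- read_gene_models(cfg$gff)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  filtered <- density_filter(rs$enhancer, hd_variants, cfg$min_density)
  domains <- build_regulatory_domains(models, sizes, cfg$basal_up,
                                      cfg$basal_down, cfg$max_extension)
  assignment <- assign_enhancer_targets(filtered, domains)
  prom_genes <- promoter_hd_genes(rs$promoter$windows, hd_variants)
  bed <- filtered[, c("chrom", "start", "end")]
  bed$name <- sprintf("enh%05d", seq_len(nrow(bed)))
  bed$score <- filtered$hd_count
  write_bed(bed, .out(cfg, "enhancers_filtered.bed"))
  .write_tsv(assignment$edges, .out(cfg, "enhancer_gene_edges.tsv"))
  union_genes <- sort(union(assignment$genes, prom_genes$genes))
  writeLines(assignment$genes, .out(cfg, "genes_enhancer.txt"))
  writeLines(prom_genes$genes, .out(cfg, "genes_promoter.txt"))
  writeLines(union_genes, .out(cfg, "genes_union.txt"))
  .write_json(list(
    n_enhancers_tested = nrow(.as_intervals(rs$enhancer)),
    n_enhancers_kept = nrow(filtered),
    n_enhancer_target_genes = length(assignment$genes),
    n_unassigned_enhancers = nrow(assignment$unassigned),
    n_promoters_with_hd = prom_genes$n_promoters,
    n_promoter_genes = length(prom_genes$genes),
    n_genes_union = length(union_genes)
  ), .out(cfg, "targets_summary.json"))
  invisible(list(filtered = filtered, domains = domains,
                 assignment = assignment, promoter_genes = prom_genes))
}

#' Gene universe for enrichment testing
#'
#' The genes eligible for selection: those with at least one tested
#' variant in their promoter windows, their coding exons or their extended
#' regulatory domain. This matches the frame in which the query gene lists
#' were selected; enrichment results are sensitive to the universe choice.
#'
#' @param sites All tested variants (`chrom`, `pos`).
#' @param promoter_windows Per-TSS windows with `gene_id`.
#' @param models A [gene_models].
#' @param domains Regulatory domains from [build_regulatory_domains()].
#' @return Sorted character vector of gene ids.
#' @export
variant_gene_universe <- function(sites, promoter_windows, models, domains) {
  vgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  hit_genes <- function(iv, ids) {
    if (nrow(iv) == 0) return(character(0))
    g <- .iv_to_gr(iv)
    lv <- union(GenomeInfoDb::seqlevels(vgr), GenomeInfoDb::seqlevels(g))
    GenomeInfoDb::seqlevels(g) <- lv
    v <- vgr
    GenomeInfoDb::seqlevels(v) <- lv
    unique(ids[GenomicRanges::countOverlaps(g, v) > 0])
  }
  sort(unique(c(
    hit_genes(promoter_windows[, c("chrom", "start", "end")],
              promoter_windows$gene_id),
    hit_genes(models$cds[, c("chrom", "start", "end")], models$cds$gene_id),
    hit_genes(data.frame(chrom = domains$chrom, start = domains$ext_start,
                         end = domains$ext_end), domains$gene_id)
  )))
}

#' Pipeline stage: gene-set enrichment and term clustering
#'
#' Tests the union gene list against the GMT collection, writes
#' `genesets.tsv`, a newick tree of the enriched terms (`terms.nwk`, when
#' at least two terms pass), and `genesets_summary.json`.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the `term_enrichment` table.
#' @export
stage_genesets <- function(cfg) {
  sites <- .read_fst_sites(cfg)
  rs <- .read_region_sets(cfg)
  models <- read_gene_models(cfg$gff)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  domains <- build_regulatory_domains(models, sizes, cfg$basal_up,
                                      cfg$basal_down, cfg$max_extension)
  universe <- variant_gene_universe(sites, rs$promoter$windows, models,
                                    domains)
  query <- read_sample_list(.out(cfg, "genes_union.txt"))
  collection <- read_gmt(cfg$gmt)
  enr <- geneset_enrichment(query, collection, universe, fdr = cfg$fdr,
                            max_terms = cfg$max_terms)
  .write_tsv(enr, .out(cfg, "genesets.tsv"))
  tree <- jaccard_tree(enr, linkage = cfg$linkage)
  if (!is.null(tree)) ape::write.tree(tree, .out(cfg, "terms.nwk"))
  .write_json(list(
    n_terms_tested = nrow(enr),
    n_terms_enriched = sum(enr$enriched),
    universe_size = length(universe),
    query_size = length(query),
    fdr = cfg$fdr,
    tree_written = !is.null(tree)
  ), .out(cfg, "genesets_summary.json"))
  invisible(enr)
}

#' Run the full pipeline
#'
#' Executes fst -> regions -> enrichment -> targets -> gene sets and
#' writes a JSON manifest with the configuration, package version, row
#' counts and an md5 checksum of every output file. On a stage failure a
#' `FAILED` marker naming the stage is left in the output directory and
#' the error is re-raised.
#'
#' @param cfg A `pipeline_config` (or a path to a YAML config).
#' @return Invisibly, a list of per-stage results.
#' @export
run_hdscan <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(fst = stage_fst, regions = stage_regions,
                 enrichment = stage_enrichment, targets = stage_targets,
                 genesets = stage_genesets)
  results <- list()
  for (nm in names(stages)) {
    results[[nm]] <- tryCatch(stages[[nm]](cfg), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
                 .out(cfg, "FAILED"))
      stop(e)
    })
  }
  outputs <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                     .out(cfg, "manifest.json"))
  .write_json(list(
    package = "hdscan",
    version = as.character(utils::packageVersion("hdscan")),
    config = unclass(cfg),
    checksums = as.list(tools::md5sum(outputs)),
    row_counts = list(
      sites = results$fst$hd$n_total,
      hd = results$fst$hd$n_selected,
      enrichment_rows = nrow(results$enrichment),
      terms = nrow(results$genesets)
    )
  ), .out(cfg, "manifest.json"))
  invisible(results)
}

#' One-command synthetic demo
#'
#' Generates a self-contained synthetic dataset with a planted divergence
#' excess in regulatory elements (F = 0.6 in promoters and 0.5 in
#' enhancers vs 0.2 background) and runs the full pipeline on it.
#'
#' @param out_dir Output directory; inputs go to `out_dir/data`, results
#'   to `out_dir/results`.
#' @param seed Integer seed.
#' @param config Optional [synth_config] overriding the demo defaults.
#' @return Invisibly, a list with the dataset paths and pipeline results.
#' @export
hdscan_demo <- function(out_dir, seed = 7, config = NULL) {
  if (is.null(config)) {
    config <- synth_config(n_chromosomes = 2, chrom_length = 2.5e6,
                           n_genes = 60, n_sites = 4e4,
                           f_by_class = list(promoter = 0.6, enhancer = 0.5),
                           missing_rate = 0.02, seed = seed)
  }
  data_dir <- file.path(out_dir, "data")
  ds <- simulate_hd_dataset(config, data_dir)
  cfg <- pipeline_config(
    vcf = ds$vcf, samples_pop1 = ds$samples_pop1,
    samples_pop2 = ds$samples_pop2, gff = ds$gff, peaks = ds$peaks,
    chrom_sizes = ds$chrom_sizes, gmt = ds$gmt,
    out_dir = file.path(out_dir, "results"),
    promoter_up = config$promoter_up, promoter_down = config$promoter_down,
    seed = seed
  )
  results <- run_hdscan(cfg)
  invisible(list(dataset = ds, config = cfg, results = results))
}
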