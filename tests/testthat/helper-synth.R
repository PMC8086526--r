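# Shared fixture builders (everything generated in code at test time).

small_synth_config <- function(...) {
  args <- list(n_chromosomes = 1, chrom_length = 1e6, n_genes = 15,
               n_sites = 4000, n_samples_pop1 = 10, n_samples_pop2 = 10,
               seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# in-memory run of the generator + fst, skipping file I/O
sim_in_memory <- function(config, estimator = "hudson") {
  ann <- simulate_annotation(config)
  truth <- simulate_site_frequencies(config, ann)
  geno <- simulate_genotypes(truth, config)
  counts <- allele_counts_from_dosage(geno)
  fst <- compute_fst(counts, estimator)
  list(ann = ann, truth = truth, geno = geno, counts = counts, fst = fst,
       regions = attr(truth, "regions"))
}

# minimal hand-built gene models for geometric tests
toy_models <- function(tss, strand, chrom = "chr1",
                       gene_id = sprintf("g%d", seq_along(tss))) {
  gene_models(
    transcripts = data.frame(
      tx_id = paste0(gene_id, ".t1"), gene_id = gene_id, chrom = chrom,
      strand = strand, tss = tss, coding = TRUE, stringsAsFactors = FALSE
    ),
    cds = data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), tx_id = character(0),
                     gene_id = character(0), stringsAsFactors = FALSE)
  )
}
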