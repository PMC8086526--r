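test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(f_background = 0), "f_background")
  expect_error(synth_config(f_by_class = list(promoter = 1.2)), "f_by_class")
  expect_error(synth_config(ancestral_freq_range = c(0, 0.9)),
               "ancestral_freq_range")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_sites = 0), "counts")
})

test_that("annotation respects bounds, strands and exon structure", {
  cfg <- small_synth_config(n_genes = 10, seed = 7)
  ann <- simulate_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 10)
  expect_true(all(g$start >= 0 & g$end <= 1e6))
  expect_true(all(g$strand %in% c("+", "-")))
  # non-overlapping gene bodies
  o <- g[order(g$start), ]
  expect_true(all(utils::head(o$end, -1) <= utils::tail(o$start, -1)))
  # every gene has at least one coding exon inside its body
  for (i in seq_len(nrow(g))) {
    e <- ann$cds[ann$cds$gene_id == g$gene_id[i], ]
    expect_gte(nrow(e), 1)
    expect_true(all(e$start >= g$start[i] & e$end <= g$end[i]))
  }
  # peaks within chromosome bounds
  for (p in ann$peaks) {
    expect_true(all(p$start >= 0 & p$end <= 1e6))
  }
})

test_that("infeasible gene placement raises an explicit error", {
  cfg <- small_synth_config(chrom_length = 20000, n_genes = 10)
  expect_error(simulate_annotation(cfg), "infeasible")
})

test_that("same config and seed give byte-identical files", {
  cfg <- small_synth_config(n_sites = 300, n_genes = 8, missing_rate = 0.05,
                            f_by_class = list(promoter = 0.6))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_hd_dataset(cfg, d1)
  p2 <- simulate_hd_dataset(cfg, d2)
  files <- c("variants.vcf", "annotation.gff3", "atac.bed", "h3k27ac.bed",
             "chrom_sizes.tsv", "samples_pop1.txt", "samples_pop2.txt",
             "gene_sets.gmt", "planted_truth.tsv")
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("peak coverage calibration hits its target on a 10 Mb genome", {
  cfg <- synth_config(n_chromosomes = 2, chrom_length = 5e6,
                      peak_density = peak_density_for_coverage(0.054),
                      seed = 13)
  ann <- simulate_annotation(cfg)
  pooled <- rbind(ann$peaks$atac[, 1:3], ann$peaks$h3k27ac[, 1:3])
  frac <- genome_fraction(merge_intervals(pooled), ann$chrom_sizes)
  expect_lt(abs(frac - 0.054), 0.005)
})

test_that("Balding-Nichols frequencies have the planted moments", {
  # p = 0.5, F = 0.5: mean 0.5, variance p(1-p)F = 0.125
  # (Beta(a,b) with a = b = (1-F)/(2F) = 0.5: var = ab/((a+b)^2 (a+b+1))
  #  = 0.25/(1*2) = 0.125, confirming the closed form)
  cfg <- small_synth_config(n_sites = 20000, chrom_length = 5e6,
                            f_background = 0.5,
                            ancestral_freq_range = c(0.4999, 0.5001),
                            seed = 5)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  n <- nrow(truth)
  # 3 Monte-Carlo standard errors; se(var) uses the arcsine 4th moment 3/128
  expect_lt(abs(mean(truth$p1) - 0.5), 3 * sqrt(0.125 / n))
  se_var <- sqrt((3 / 128 - (1 / 8)^2) / n)
  expect_lt(abs(stats::var(truth$p1) - 0.125), 3 * se_var)
  expect_lt(abs(stats::var(truth$p2) - 0.125), 3 * se_var)
})

test_that("population frequencies collapse to the ancestral value as F -> 0", {
  cfg <- small_synth_config(n_sites = 2000, f_background = 1e-4, seed = 9)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  # sd per site is sqrt(p(1-p)F) <= 0.005
  expect_lt(mean(abs(truth$p1 - truth$p_anc)), 0.01)
  expect_lt(mean(abs(truth$p2 - truth$p_anc)), 0.01)
})

test_that("planted class divergence is recorded per site", {
  cfg <- small_synth_config(f_by_class = list(promoter = 0.8), seed = 3)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  expect_true(all(truth$f[truth$class == "promoter"] == 0.8))
  expect_true(all(truth$f[truth$class != "promoter"] == 0.2))
  # class labels consistent with the emitted annotation
  rs <- attr(truth, "regions")
  mem <- classify_variants(truth, rs)
  expect_true(all(mem[truth$class == "promoter", "promoter"]))
  expect_true(all(!mem[truth$class == "background", "promoter"] &
                    !mem[truth$class == "background", "enhancer"] &
                    !mem[truth$class == "background", "exon"]))
})

test_that("genotypes reflect fixed differences and sample sizes", {
  truth <- structure(
    data.frame(chrom = "chr1", pos = c(100, 200), class = "background",
               p_anc = 0.5, f = 0.2, p1 = c(1, 0.5), p2 = c(0, 0.5),
               stringsAsFactors = FALSE),
    class = c("planted_truth", "data.frame"))
  cfg <- synth_config(n_samples_pop1 = 38, n_samples_pop2 = 41, seed = 1)
  geno <- simulate_genotypes(truth, cfg)
  expect_equal(ncol(geno$dosage), 79)
  expect_false(anyNA(geno$dosage))          # missing_rate 0
  expect_true(all(geno$dosage[1, geno$samples_pop1] == 2))
  expect_true(all(geno$dosage[1, geno$samples_pop2] == 0))
})

test_that("genotype allele frequencies converge to the planted truth", {
  # 1000 haplotypes (500 + 500 diploids), tolerance 0.05
  cfg <- small_synth_config(n_sites = 200, n_samples_pop1 = 500,
                            n_samples_pop2 = 500, seed = 21)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  geno <- simulate_genotypes(truth, cfg)
  counts <- allele_counts_from_dosage(geno)
  key <- paste(truth$chrom, truth$pos)
  i <- match(paste(counts$chrom, counts$pos), key)
  expect_true(all(abs(counts$alt1 / counts$called1 - truth$p1[i]) < 0.05))
  expect_true(all(abs(counts$alt2 / counts$called2 - truth$p2[i]) < 0.05))
})

test_that("missingness is applied at the configured rate", {
  cfg <- small_synth_config(n_sites = 1000, missing_rate = 0.1, seed = 33)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  geno <- simulate_genotypes(truth, cfg)
  rate <- mean(is.na(geno$dosage))
  expect_lt(abs(rate - 0.1), 0.01)
})
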