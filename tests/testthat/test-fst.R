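test_that("allele counting handles heterozygotes, missing and monomorphic sites", {
  # pop1 = {0/1, 1/1}, pop2 = {0/0} at site 1; a ./. at site 2;
  # site 3 monomorphic reference in both populations
  dosage <- matrix(c(1L, 2L, 0L,
                     1L, NA, 0L,
                     0L, 0L, 0L), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b", "c")))
  geno <- list(chrom = rep("chr1", 3), pos = c(100, 200, 300),
               dosage = dosage)
  cc <- allele_counts_from_dosage(geno, pop1 = c("a", "b"), pop2 = "c")
  expect_equal(nrow(cc), 2)                      # monomorphic site dropped
  expect_equal(attr(cc, "n_monomorphic_dropped"), 1L)
  expect_equal(cc$alt1[1], 3)
  expect_equal(cc$called1[1], 4)
  expect_equal(cc$alt2[1], 0)
  expect_equal(cc$called2[1], 2)
  # ./. contributes nothing to alt or called
  expect_equal(cc$alt1[2], 1)
  expect_equal(cc$called1[2], 2)
  expect_error(allele_counts_from_dosage(geno, pop1 = "zz", pop2 = "c"),
               "absent")
})

test_that("VCF round trip reproduces in-memory allele counts", {
  cfg <- small_synth_config(n_sites = 300, missing_rate = 0.05, seed = 17)
  ann <- simulate_annotation(cfg)
  truth <- simulate_site_frequencies(cfg, ann)
  geno <- simulate_genotypes(truth, cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, ann$chrom_sizes, vcf)
  from_vcf <- allele_counts_from_vcf(vcf, geno$samples_pop1,
                                     geno$samples_pop2)
  direct <- allele_counts_from_dosage(geno)
  expect_equal(as.data.frame(from_vcf), as.data.frame(direct),
               ignore_attr = TRUE)
  expect_error(allele_counts_from_vcf(vcf, "nope", geno$samples_pop2),
               "absent from VCF header")
})

test_that("non-biallelic records are skipped with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t30\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0"
  ), vcf)
  expect_warning(cc <- allele_counts_from_vcf(vcf, "s1", "s2"),
                 "non-biallelic")
  expect_equal(attr(cc, "n_nonbiallelic_skipped"), 2L)
  expect_equal(cc$pos, 10)
})

test_that("both estimators hit the fixation and no-differentiation anchors", {
  cc <- allele_counts(chrom = c("chr1", "chr1"), pos = c(1, 2),
                      alt1 = c(76, 38), called1 = c(76, 76),
                      alt2 = c(0, 41), called2 = c(82, 82))
  for (est in c("weir_cockerham", "hudson")) {
    f <- compute_fst(cc, est)
    expect_equal(f$fst[1], 1)                       # opposite fixation
    expect_equal(f$fst[2], 0)                       # p1 = p2 = 0.5, clamped
    expect_lte(f$fst_raw[2], 0)
  }
})

test_that("estimators reproduce frozen dual-route oracle constants", {
  cc <- allele_counts("chr1", 1, alt1 = 16, called1 = 20,
                      alt2 = 4, called2 = 20)
  expect_equal(fst_weir_cockerham(cc)$fst, 0.504643962848, tolerance = 1e-10)
  expect_equal(fst_hudson(cc)$fst, 0.504643962848, tolerance = 1e-10)
  # unequal sample sizes separate the two estimators
  cc2 <- allele_counts("chr1", 1, alt1 = 16, called1 = 20,
                       alt2 = 6, called2 = 30)
  wc2 <- oracle_fst_wc(c(16, 6), c(20, 30))
  hu2 <- oracle_fst_hudson(16, 20, 6, 30)
  expect_equal(fst_weir_cockerham(cc2)$fst, unname(wc2["fst"]),
               tolerance = 1e-12)
  expect_equal(fst_hudson(cc2)$fst, unname(hu2["fst"]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(wc2[["fst"]], hu2[["fst"]])))
})

test_that("clamping preserves the raw ratio and the [0,1] bounds", {
  set.seed(61)
  n1 <- sample(4:60, 200, replace = TRUE)
  n2 <- sample(4:60, 200, replace = TRUE)
  cc <- allele_counts("chr1", seq_len(200),
                      alt1 = vapply(n1, function(n) sample(0:n, 1), 0),
                      called1 = n1,
                      alt2 = vapply(n2, function(n) sample(0:n, 1), 0),
                      called2 = n2)
  for (est in c("weir_cockerham", "hudson")) {
    f <- compute_fst(cc, est)
    expect_true(all(f$fst >= 0 & f$fst <= 1))
    expect_equal(f$fst_raw, f$numerator / f$denominator)
    expect_equal(f$fst, pmin(1, pmax(0, f$fst_raw)))
  }
})

test_that("low-call sites are dropped, not imputed", {
  cc <- allele_counts(chrom = c("chr1", "chr1"), pos = 1:2,
                      alt1 = c(1, 5), called1 = c(1, 10),
                      alt2 = c(3, 2), called2 = c(10, 10))
  f <- fst_hudson(cc)
  expect_equal(nrow(f), 1)
  expect_equal(f$pos, 2)
  expect_equal(attr(f, "n_low_call"), 1L)
})

test_that("F_ST is monotone in the frequency gap at fixed sample sizes", {
  p2 <- 0.3
  alt1 <- seq(6, 20)                       # p1 from 0.3 to 1.0, n = 20
  cc <- allele_counts("chr1", seq_along(alt1), alt1 = alt1, called1 = 20,
                      alt2 = 6, called2 = 20)
  for (est in c("weir_cockerham", "hudson")) {
    f <- compute_fst(cc, est)
    expect_true(all(diff(f$fst) >= -1e-12))
  }
})

test_that("top-quantile selection reports threshold and handles ties", {
  set.seed(2)
  f <- structure(data.frame(chrom = "chr1", pos = 1:1000,
                            fst = sample(seq(0.001, 1, length.out = 1000))),
                 class = c("fst_records", "data.frame"))
  hd <- select_hd(f, 0.01)
  expect_equal(hd$n_selected, 10)
  expect_equal(hd$threshold, sort(f$fst, decreasing = TRUE)[10])
  expect_true(all(hd$variants$fst >= hd$threshold))
  # all tied at 1: everything selected, with a warning
  ft <- structure(data.frame(chrom = "chr1", pos = 1:200, fst = 1),
                  class = c("fst_records", "data.frame"))
  expect_warning(hdt <- select_hd(ft, 0.01), "tied")
  expect_equal(hdt$n_selected, 200)
  expect_true(hdt$ties)
  expect_error(select_hd(f[0, ], 0.01), "no F_ST records")
})

test_that("F_ST bins keep complete fixation separate and are left-closed", {
  b <- bin_fst(c(1.0, 0.95, 0.9, 0.2, 0.5))
  expect_equal(as.character(b),
               c("=1", "[0.9,1)", "[0.9,1)", "[0,0.5)", "[0.5,0.6)"))
  expect_error(bin_fst(c(0.5), edges = c(0.9, 0.5)), "strictly increasing")
  expect_error(bin_fst(c(1.2)), "post-clamp")
})

test_that("ratio-of-averages Hudson F_ST recovers the planted divergence", {
  cfg <- small_synth_config(n_sites = 12000, chrom_length = 4e6,
                            n_samples_pop1 = 38, n_samples_pop2 = 41,
                            f_background = 0.2, seed = 29)
  sim <- sim_in_memory(cfg, "hudson")
  est <- fst_ratio_of_averages(sim$fst)
  # leave-one-out jackknife standard error of the ratio
  sn <- sum(sim$fst$numerator)
  sd_ <- sum(sim$fst$denominator)
  loo <- (sn - sim$fst$numerator) / (sd_ - sim$fst$denominator)
  n <- length(loo)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  expect_lt(abs(est - 0.2), 3 * se)
})
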