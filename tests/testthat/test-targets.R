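test_that("density filter applies the one-per-500-bases rate with boundary equality", {
  enh <- data.frame(chrom = "chr1",
                    start = c(0, 2000, 4000),
                    end = c(1000, 3000, 4499))
  hd <- data.frame(chrom = "chr1",
                   pos = c(100, 900,          # 2 in [0,1000): 0.002, kept
                           2500,              # 1 in [2000,3000): 0.001, dropped
                           4100))             # 1 in 499 bases: kept
  f <- density_filter(enh, hd, min_density = 1 / 500)
  expect_equal(f$start, c(0, 4000))
  expect_equal(f$hd_count, c(2, 1))
  expect_equal(attr(f, "n_dropped"), 1L)
  # zero-HD enhancers always dropped
  f0 <- density_filter(data.frame(chrom = "chr1", start = 0, end = 10),
                       hd[0, ], min_density = 1 / 500)
  expect_equal(nrow(f0), 0)
})

test_that("sliding-window mode requires every 500-base window to be hit", {
  enh <- data.frame(chrom = "chr1", start = 0, end = 1000)
  ok <- data.frame(chrom = "chr1", pos = c(100, 400, 900))
  gap <- data.frame(chrom = "chr1", pos = c(100, 900))  # 799-base hole
  expect_equal(nrow(density_filter(enh, ok, sliding_window = TRUE)), 1)
  expect_equal(nrow(density_filter(enh, gap, sliding_window = TRUE)), 0)
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  sizes <- c(chr1 = 1e7)
  lone <- build_regulatory_domains(toy_models(2e6, "+"), sizes)
  expect_equal(lone$basal_start, 1995000)
  expect_equal(lone$basal_end, 2001000)
  expect_equal(lone$ext_start, 995000)
  expect_equal(lone$ext_end, 3001000)
  # extension truncates at the neighbor's basal domain
  two <- build_regulatory_domains(toy_models(c(1e5, 2e5), c("+", "+")), sizes)
  expect_equal(two$basal_start, c(95000, 195000))
  expect_equal(two$ext_end[1], 195000)
  expect_equal(two$ext_start[2], 101000)
  # chromosome clipping
  edge <- build_regulatory_domains(toy_models(3000, "+"), sizes)
  expect_equal(edge$basal_start, 0)
  expect_equal(edge$ext_start, 0)
  # minus strand mirrors the window
  minus <- build_regulatory_domains(toy_models(10000, "-"), sizes)
  expect_equal(minus$basal_start, 9001)
  expect_equal(minus$basal_end, 15001)
})

test_that("no extended domain overlaps a foreign basal domain (bitmap check)", {
  set.seed(53)
  for (rep in 1:10) {
    L <- 1e5
    tss <- sort(sample(seq(5000, L - 5000), 6))
    d <- build_regulatory_domains(
      toy_models(tss, sample(c("+", "-"), 6, replace = TRUE)),
      c(chr1 = L), max_extension = 2e4)
    for (j in seq_len(nrow(d))) {
      ext <- data.frame(chrom = "chr1", start = d$ext_start[j],
                        end = d$ext_end[j])
      foreign <- data.frame(chrom = "chr1",
                            start = d$basal_start[-j], end = d$basal_end[-j])
      bm_ext <- bm_from_iv(ext, L)
      bm_for <- bm_from_iv(foreign, L)
      bm_own <- bm_from_iv(data.frame(chrom = "chr1",
                                      start = d$basal_start[j],
                                      end = d$basal_end[j]), L)
      # only bases of the gene's own basal window may coincide with a
      # neighbor's basal territory (when basal windows themselves overlap)
      expect_false(any(bm_ext & bm_for & !bm_own))
      # basal is always contained in extended
      expect_true(all(!bm_own | bm_ext))
      expect_true(d$ext_start[j] <= d$basal_start[j] &&
                    d$ext_end[j] >= d$basal_end[j])
    }
  }
})

test_that("enhancer-target edges require a one-base overlap", {
  sizes <- c(chr1 = 1e7)
  d <- build_regulatory_domains(toy_models(c(1e5, 2e5), c("+", "+")), sizes,
                                max_extension = 5e4)
  # d: gene1 ext [45000,151000), gene2 ext [145000,251000)
  enh <- data.frame(chrom = "chr1",
                    start = c(60000, 150000, 5e6),
                    end = c(60500, 150500, 5000500))
  res <- assign_enhancer_targets(enh, d)
  g1 <- res$edges$gene_id[res$edges$start == 60000]
  expect_equal(g1, "g1")
  g_both <- sort(res$edges$gene_id[res$edges$start == 150000])
  expect_equal(g_both, c("g1", "g2"))       # spans two extended domains
  expect_equal(nrow(res$unassigned), 1)     # domain desert
  expect_equal(res$genes, c("g1", "g2"))
})

test_that("promoter HD genes are counted per gene with promoter-level detail", {
  w <- data.frame(chrom = "chr1",
                  start = c(1000, 5000, 9000),
                  end = c(2500, 6500, 10500),
                  gene_id = c("gA", "gA", "gB"),
                  tx_id = c("gA.t1", "gA.t2", "gB.t1"))
  hd <- data.frame(chrom = "chr1", pos = c(1001, 9600))
  res <- promoter_hd_genes(w, hd)
  expect_equal(res$genes, c("gA", "gB"))
  expect_equal(res$n_promoters, 2)          # one window per gene qualified
  # window-edge inclusion: pos0 = start is inside, pos0 = end is not
  edge_in <- promoter_hd_genes(w, data.frame(chrom = "chr1", pos = 1001))
  expect_equal(edge_in$genes, "gA")
  edge_out <- promoter_hd_genes(w, data.frame(chrom = "chr1", pos = 2501))
  expect_equal(edge_out$genes, character(0))
  none <- promoter_hd_genes(w, hd[0, ])
  expect_equal(none$genes, character(0))
})
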