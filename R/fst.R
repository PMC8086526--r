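# Per-site F_ST between two populations, HD selection and binning.

#' Build per-site allele counts
#'
#' The substrate of both F_ST estimators: per site, the alternate-allele
#' count and the number of successfully genotyped chromosomes in each
#' population. Sites monomorphic across both populations combined are
#' dropped (F_ST is undefined there); the count is recorded in the
#' `n_monomorphic_dropped` attribute.
#'
#' @param chrom,pos Site coordinates (`pos` 1-based).
#' @param alt1,called1,alt2,called2 Alternate-allele and called-chromosome
#'   counts per population.
#' @param drop_monomorphic Drop combined-monomorphic sites (default `TRUE`).
#' @return An `allele_counts` data frame.
#' @export
allele_counts <- function(chrom, pos, alt1, called1, alt2, called2,
                          drop_monomorphic = TRUE) {
  if (any(alt1 < 0 | alt2 < 0 | alt1 > called1 | alt2 > called2)) {
    stop("need 0 <= alt <= called in each population")
  }
  df <- data.frame(chrom = chrom, pos = pos, alt1 = alt1, called1 = called1,
                   alt2 = alt2, called2 = called2, stringsAsFactors = FALSE)
  n_mono <- 0L
  if (drop_monomorphic) {
    tot_alt <- df$alt1 + df$alt2
    tot_called <- df$called1 + df$called2
    mono <- tot_called == 0 | tot_alt == 0 | tot_alt == tot_called
    n_mono <- sum(mono)
    df <- df[!mono, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("allele_counts", "data.frame"),
            n_monomorphic_dropped = n_mono)
}

#' Allele counts from a dosage matrix
#'
#' @param geno A `synth_genotypes` object, or any list with `chrom`, `pos`
#'   and an integer alt-dosage matrix `dosage` (`NA` = missing).
#' @param pop1,pop2 Column names (sample ids) of the two populations.
#' @return An `allele_counts` data frame.
#' @export
allele_counts_from_dosage <- function(geno, pop1 = geno$samples_pop1,
                                      pop2 = geno$samples_pop2) {
  miss <- setdiff(c(pop1, pop2), colnames(geno$dosage))
  if (length(miss)) {
    stop("samples absent from genotype matrix: ", paste(miss, collapse = ", "))
  }
  d1 <- geno$dosage[, pop1, drop = FALSE]
  d2 <- geno$dosage[, pop2, drop = FALSE]
  allele_counts(
    chrom = geno$chrom, pos = geno$pos,
    alt1 = rowSums(d1, na.rm = TRUE), called1 = 2 * rowSums(!is.na(d1)),
    alt2 = rowSums(d2, na.rm = TRUE), called2 = 2 * rowSums(!is.na(d2))
  )
}

.GT_DOSAGE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)

#' Allele counts from a VCF file
#'
#' Reads a multi-sample VCF (vcfR), restricts to biallelic SNPs (others are
#' skipped with a warning counter), translates diploid `GT` fields to
#' alternate-allele dosages -- half-calls and anything unparsable count as
#' fully missing -- and tallies per-population allele counts. Non-autosomal
#' chromosomes (`chrX`/`X`, `chrY`/`Y`, `chrM`/`MT`) are excluded by
#' default.
#'
#' @param path Path to a VCF file.
#' @param pop1,pop2 Character vectors of sample ids (or paths are accepted
#'   via [read_sample_list()] upstream). Every id must be present in the
#'   VCF header.
#' @param autosomes_only Drop sex and mitochondrial chromosomes (default
#'   `TRUE`).
#' @return An `allele_counts` data frame; attributes record the number of
#'   non-biallelic records skipped and monomorphic sites dropped.
#' @export
allele_counts_from_vcf <- function(path, pop1, pop2, autosomes_only = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  miss <- setdiff(c(pop1, pop2), colnames(gt))
  if (length(miss)) {
    stop("samples absent from VCF header: ", paste(miss, collapse = ", "))
  }
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!biallelic_snp)
  if (n_skipped > 0) {
    warning(n_skipped, " non-biallelic or non-SNP record(s) skipped")
  }
  chrom <- fix[, "CHROM"]
  keep <- biallelic_snp
  if (autosomes_only) {
    keep <- keep & !(chrom %in% c("chrX", "X", "chrY", "Y", "chrM", "MT", "chrMT"))
  }
  gt <- gt[keep, , drop = FALSE]
  dosage <- matrix(unname(.GT_DOSAGE[gt]), nrow = nrow(gt),
                   dimnames = list(NULL, colnames(gt)))
  counts <- allele_counts_from_dosage(
    list(chrom = chrom[keep], pos = as.integer(fix[keep, "POS"]),
         dosage = dosage),
    pop1 = pop1, pop2 = pop2
  )
  attr(counts, "n_nonbiallelic_skipped") <- n_skipped
  counts
}

.fst_finish <- function(df, num, den, estimator) {
  keep <- is.finite(den) & den > 0
  n_zero_den <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  raw <- num[keep] / den[keep]
  df$numerator <- num[keep]
  df$denominator <- den[keep]
  df$fst_raw <- raw
  df$fst <- pmin(1, pmax(0, raw))
  df$estimator <- estimator
  rownames(df) <- NULL
  structure(df, class = c("fst_records", "data.frame"),
            n_zero_denominator = n_zero_den)
}

.fst_prepare <- function(counts) {
  keep <- counts$called1 >= 2 & counts$called2 >= 2
  structure(counts[keep, , drop = FALSE], n_low_call = sum(!keep))
}

#' Per-site Weir-Cockerham F_ST
#'
#' The Weir-Cockerham (1984) variance-components estimator applied at the
#' allele level: treating the called chromosomes of each population as the
#' sampling units, theta = (MSB - MSW) / (MSB + (n_c - 1) MSW), where MSB
#' and MSW are the between- and within-population mean squares of the
#' allele indicators and n_c is the variance-effective sample size. Sites
#' where either population has fewer than two called chromosomes are
#' dropped (`n_low_call` attribute), as are sites with a non-positive
#' denominator (`n_zero_denominator`). Negative estimates are clamped to 0
#' (`fst` column); the raw ratio is retained in `fst_raw`.
#'
#' @param counts An `allele_counts` data frame.
#' @return An `fst_records` data frame with columns `chrom`, `pos`, `p1`,
#'   `p2`, `numerator`, `denominator`, `fst_raw`, `fst`, `estimator`.
#' @export
fst_weir_cockerham <- function(counts) {
  cc <- .fst_prepare(counts)
  n1 <- cc$called1; n2 <- cc$called2
  p1 <- cc$alt1 / n1; p2 <- cc$alt2 / n2
  nt <- n1 + n2
  pbar <- (cc$alt1 + cc$alt2) / nt
  msb <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt
  num <- (msb - msw) / nc
  den <- (msb + (nc - 1) * msw) / nc
  out <- .fst_finish(
    data.frame(chrom = cc$chrom, pos = cc$pos, p1 = p1, p2 = p2,
               stringsAsFactors = FALSE),
    num, den, "weir_cockerham")
  attr(out, "n_low_call") <- attr(cc, "n_low_call")
  out
}

#' Per-site Hudson F_ST
#'
#' The Hudson estimator in the Bhatia et al. form:
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`, with n in called chromosomes. Dropping and
#' clamping as in [fst_weir_cockerham()].
#'
#' @param counts An `allele_counts` data frame.
#' @return An `fst_records` data frame.
#' @export
fst_hudson <- function(counts) {
  cc <- .fst_prepare(counts)
  n1 <- cc$called1; n2 <- cc$called2
  p1 <- cc$alt1 / n1; p2 <- cc$alt2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- .fst_finish(
    data.frame(chrom = cc$chrom, pos = cc$pos, p1 = p1, p2 = p2,
               stringsAsFactors = FALSE),
    num, den, "hudson")
  attr(out, "n_low_call") <- attr(cc, "n_low_call")
  out
}

#' Compute per-site F_ST
#'
#' @param counts An `allele_counts` data frame.
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @return An `fst_records` data frame.
#' @export
compute_fst <- function(counts, estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         weir_cockerham = fst_weir_cockerham(counts),
         hudson = fst_hudson(counts))
}

#' Ratio-of-averages F_ST
#'
#' Pools the per-site estimator components: `sum(numerator) /
#' sum(denominator)`. For the Hudson estimator under the Balding-Nichols
#' model this is an approximately unbiased estimate of the divergence
#' parameter F.
#'
#' @param fst An `fst_records` data frame.
#' @return A single number.
#' @export
fst_ratio_of_averages <- function(fst) {
  sum(fst$numerator) / sum(fst$denominator)
}

#' Select the top-quantile highly differentiated variants
#'
#' Selects the `ceiling(quantile * N)` records with the highest F_ST and
#' reports the realized threshold. All records tied with the threshold
#' value are included, so the selection can exceed the nominal count (a
#' warning reports ties).
#'
#' @param fst An `fst_records` data frame.
#' @param quantile Selection fraction (default 0.01 = top 1%).
#' @return An object of class `hd_selection`: `quantile`, `threshold`,
#'   `n_nominal`, `n_selected`, `ties`, and `variants` (the selected
#'   `fst_records` rows).
#' @export
select_hd <- function(fst, quantile = 0.01) {
  n <- nrow(fst)
  if (n == 0) stop("no F_ST records to select from")
  if (n < 1 / quantile) {
    warning("fewer than 1/quantile records; selection is degenerate")
  }
  n_nominal <- ceiling(quantile * n)
  threshold <- sort(fst$fst, decreasing = TRUE)[n_nominal]
  sel <- fst$fst >= threshold
  if (sum(sel) > n_nominal) {
    warning(sum(sel) - n_nominal, " record(s) tied at the threshold included")
  }
  variants <- fst[sel, , drop = FALSE]
  variants <- variants[order(-variants$fst, variants$chrom, variants$pos), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  structure(list(quantile = quantile, threshold = threshold,
                 n_total = n, n_nominal = n_nominal, n_selected = sum(sel),
                 ties = sum(sel) > n_nominal, variants = variants),
            class = "hd_selection")
}

#' @export
print.hd_selection <- function(x, ...) {
  cat(sprintf(
    "<hd_selection>: top %.3g%% of %d records -> %d selected (threshold %.4f%s)\n",
    100 * x$quantile, x$n_total, x$n_selected, x$threshold,
    if (x$ties) ", ties included" else ""))
  invisible(x)
}

#' Assign F_ST bins
#'
#' Labels each value with a left-closed right-open bin; values exactly 1
#' form their own stratum `"=1"` so complete fixation is kept separate from
#' `[0.9, 1)`.
#'
#' @param fst Numeric vector of clamped F_ST values in `[0, 1]`, or an
#'   `fst_records` data frame.
#' @param edges Strictly increasing interior bin edges within (0, 1)
#'   (default `c(0.5, 0.6, 0.7, 0.8, 0.9)`).
#' @return Factor of bin labels, one per record, levels ordered by F_ST.
#' @export
bin_fst <- function(fst, edges = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  x <- if (is.data.frame(fst)) fst$fst else fst
  if (any(x < 0 | x > 1)) stop("F_ST values must be in [0, 1] (post-clamp)")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0 | edges >= 1)) {
    stop("edges must be strictly increasing within (0, 1)")
  }
  full <- c(0, edges, 1)
  labs <- sprintf("[%g,%g)", full[-length(full)], full[-1])
  idx <- findInterval(x, full)            # x == 1 maps past the last interval
  lab <- c(labs, "=1")[idx]
  factor(lab, levels = c(labs, "=1"))
}
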