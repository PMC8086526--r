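# Fold enrichment of HD variants in region classes, per F_ST stratum.

#' Classify variants by region membership
#'
#' A variant at 1-based position `pos` is a member of a half-open region
#' `[start, end)` iff `start <= pos - 1 < end`. Membership is
#' non-exclusive: a variant inside both a promoter and an exon is counted
#' in both classes (enhancers exclude promoters by construction). Variants
#' on chromosomes absent from every region set are members of nothing but
#' remain in the totals.
#'
#' @param variants Data frame with columns `chrom` and `pos` (1-based).
#' @param region_sets Named list of [region_set]s (or interval data
#'   frames).
#' @return Logical matrix, one row per variant, one column per region
#'   class.
#' @export
classify_variants <- function(variants, region_sets) {
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  mem <- vapply(region_sets, function(rs) {
    iv <- .as_intervals(rs)
    if (nrow(iv) == 0) return(rep(FALSE, nrow(variants)))
    rgr <- .iv_to_gr(iv)
    lv <- union(GenomeInfoDb::seqlevels(vgr), GenomeInfoDb::seqlevels(rgr))
    GenomeInfoDb::seqlevels(rgr) <- lv
    v <- vgr
    GenomeInfoDb::seqlevels(v) <- lv
    IRanges::overlapsAny(v, rgr)
  }, logical(nrow(variants)))
  if (nrow(variants) == 1) mem <- matrix(mem, nrow = 1,
                                         dimnames = list(NULL, names(region_sets)))
  mem
}

#' Fold enrichment of HD variants in a region class
#'
#' The ratio of the HD-variant fraction inside the class to the
#' background fraction of all tested variants inside the class:
#' `(n_hd_in / n_hd_total) / (n_all_in / n_all_total)`. The baseline is
#' the variant-count fraction, not the genomic base fraction, so
#' differences in variant density between classes do not masquerade as
#' enrichment.
#'
#' @param n_hd_in,n_hd_total HD variants inside the class / overall.
#' @param n_all_in,n_all_total All tested variants inside the class /
#'   overall.
#' @return Fold enrichment; `NA` when the baseline is zero.
#' @export
fold_enrichment <- function(n_hd_in, n_hd_total, n_all_in, n_all_total) {
  if (n_hd_total <= 0) stop("n_hd_total must be positive")
  if (n_all_in <= 0) return(NA_real_)
  (n_hd_in / n_hd_total) / (n_all_in / n_all_total)
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least `n_hd_in` class members among
#' `n_hd_total` draws without replacement from a universe of `n_all_total`
#' variants of which `n_all_in` are in the class. Computed in log space so
#' extreme tails (p below the double-precision underflow limit) remain
#' representable via `log10_p`.
#'
#' @inheritParams fold_enrichment
#' @return List with `p` (may underflow to 0 for extreme tails) and
#'   `log10_p`.
#' @export
enrichment_pvalue <- function(n_hd_in, n_hd_total, n_all_in, n_all_total) {
  if (n_hd_in > n_hd_total || n_all_in > n_all_total ||
      n_hd_in > n_all_in || n_hd_total > n_all_total ||
      min(n_hd_in, n_hd_total, n_all_in, n_all_total) < 0) {
    stop("inconsistent contingency counts")
  }
  log_p <- stats::phyper(n_hd_in - 1, n_all_in, n_all_total - n_all_in,
                         n_hd_total, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(log_p), log10_p = log_p / log(10))
}

#' Report-style percentage formatting
#'
#' Whole percent at or above 10%, one decimal below; trailing `.0` is
#' dropped (so 20.26% prints as `20%`, 9.83% as `9.8%`, 2.04% as `2%`).
#'
#' @param x Fractions in `[0, 1]`.
#' @return Character vector like `"20%"`.
#' @export
format_percent <- function(x) {
  pct <- 100 * x
  out <- ifelse(pct >= 10, sprintf("%.0f", pct), sprintf("%.1f", pct))
  paste0(sub("\\.0$", "", out), "%")
}

#' Enrichment of HD variants per region class and F_ST stratum
#'
#' Builds the full enrichment table: one row per (stratum x region class),
#' where the strata are the overall top-quantile selection plus the
#' configured F_ST bins of the selected variants (complete fixation `=1`
#' kept separate from `[0.9, 1)` by default). Each row carries the
#' contingency counts, the occupancy percentage, the variant-count-baseline
#' fold enrichment and the one-sided hypergeometric p-value; the
#' genomic-base-fraction baseline fold is reported alongside when
#' `chrom_sizes` is supplied.
#'
#' @param fst An `fst_records` data frame of all tested variants.
#' @param hd An `hd_selection` from [select_hd()].
#' @param region_sets Named list of [region_set]s.
#' @param edges Interior bin edges passed to [bin_fst()].
#' @param chrom_sizes Optional named vector of chromosome lengths, enables
#'   the `fold_genomic` column.
#' @return An `hd_enrichment` data frame.
#' @export
binned_enrichment <- function(fst, hd, region_sets,
                              edges = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              chrom_sizes = NULL) {
  all_mem <- classify_variants(fst, region_sets)
  key <- paste(fst$chrom, fst$pos)
  hd_idx <- match(paste(hd$variants$chrom, hd$variants$pos), key)
  hd_mem <- all_mem[hd_idx, , drop = FALSE]
  bins <- bin_fst(hd$variants$fst, edges)
  strata <- c(sprintf("top%g%%", 100 * hd$quantile), rev(levels(bins)))
  n_all_total <- nrow(fst)
  n_hd_all <- nrow(hd$variants)
  rows <- list()
  for (st in strata) {
    in_stratum <- if (grepl("^top", st)) rep(TRUE, n_hd_all)
                  else as.character(bins) == st
    n_hd_total <- sum(in_stratum)
    for (cl in colnames(all_mem)) {
      n_all_in <- sum(all_mem[, cl])
      n_hd_in <- sum(hd_mem[in_stratum, cl])
      if (n_hd_total > 0 && n_all_in > 0) {
        fold <- fold_enrichment(n_hd_in, n_hd_total, n_all_in, n_all_total)
        pv <- enrichment_pvalue(n_hd_in, n_hd_total, n_all_in, n_all_total)
      } else {
        fold <- NA_real_
        pv <- list(p = NA_real_, log10_p = NA_real_)
      }
      fold_gen <- NA_real_
      if (!is.null(chrom_sizes)) {
        gf <- genome_fraction(region_sets[[cl]], chrom_sizes)
        if (gf > 0 && n_hd_total > 0) fold_gen <- (n_hd_in / n_hd_total) / gf
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, class = cl,
        n_hd_in = n_hd_in, n_hd_total = n_hd_total,
        n_all_in = n_all_in, n_all_total = n_all_total,
        pct_hd = if (n_hd_total > 0) format_percent(n_hd_in / n_hd_total)
                 else NA_character_,
        fold = fold, fold_genomic = fold_gen,
        p = pv$p, log10_p = pv$log10_p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hd_enrichment", "data.frame")
  out
}
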