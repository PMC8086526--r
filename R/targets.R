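# HD-dense enhancer selection and target-gene assignment.

#' Filter enhancers by HD-variant density
#'
#' Keeps an enhancer iff it carries at least one HD variant per
#' `1/min_density` bases, i.e. `hd_count / length >= min_density`
#' (boundary equality kept). Enhancers with no HD variant are always
#' dropped. The default rate, one variant per 500 bases, is applied as a
#' global per-enhancer rate; `sliding_window = TRUE` instead requires every
#' window of `1/min_density` bases (stepped per base, clipped at the
#' enhancer ends) to contain a variant, the strict reading.
#'
#' @param enhancers A [region_set] or interval data frame.
#' @param hd_variants Data frame with `chrom` and `pos` (1-based) of HD
#'   variants.
#' @param min_density Minimum variants per base (default `1/500`).
#' @param sliding_window Use the strict every-window criterion (default
#'   `FALSE`).
#' @return Data frame of kept enhancers with `hd_count` and `density`
#'   columns; the number dropped is in attribute `n_dropped`.
#' @export
density_filter <- function(enhancers, hd_variants, min_density = 1 / 500,
                           sliding_window = FALSE) {
  iv <- .as_intervals(enhancers)
  if (nrow(iv) == 0) {
    out <- cbind(iv, hd_count = integer(0), density = numeric(0))
    return(structure(out, n_dropped = 0L))
  }
  egr <- .iv_to_gr(iv)
  vgr <- GenomicRanges::GRanges(hd_variants$chrom,
                                IRanges::IRanges(hd_variants$pos,
                                                 hd_variants$pos))
  lv <- union(GenomeInfoDb::seqlevels(egr), GenomeInfoDb::seqlevels(vgr))
  GenomeInfoDb::seqlevels(egr) <- lv
  GenomeInfoDb::seqlevels(vgr) <- lv
  iv$hd_count <- GenomicRanges::countOverlaps(egr, vgr)
  iv$density <- iv$hd_count / (iv$end - iv$start)
  if (sliding_window) {
    w <- round(1 / min_density)
    hits <- GenomicRanges::findOverlaps(egr, vgr)
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      pos0 <- sort(hd_variants$pos[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]] - 1)
      if (length(pos0) == 0) return(FALSE)
      # every length-w window inside the enhancer must contain a variant:
      # equivalent to no gap of >= w bases between consecutive variants or
      # between an enhancer edge and its nearest variant
      gaps <- diff(c(iv$start[i] - 1, pos0, iv$end[i]))
      all(gaps <= w)
    }, logical(1))
  } else {
    keep <- iv$hd_count > 0 & iv$density >= min_density
  }
  out <- iv[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = sum(!keep))
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain around its TSS (default 5 kb
#' upstream, 1 kb downstream, the TSS base counted downstream) which is
#' then extended in both directions up to `max_extension` bases, truncating
#' at the nearest neighboring gene's basal domain and at the chromosome
#' ends. Extension never shrinks a domain below its own basal window. For
#' genes with several transcripts the most upstream coding TSS is used.
#'
#' @param models A [gene_models] object.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param basal_up,basal_down Basal window extent in bases (defaults
#'   5000 / 1000).
#' @param max_extension Maximum extension from the basal window in bases
#'   (default 1e6).
#' @param coding_only Use coding transcripts only (default `TRUE`).
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `ext_start`, `ext_end` (0-based
#'   half-open).
#' @export
build_regulatory_domains <- function(models, chrom_sizes, basal_up = 5000,
                                     basal_down = 1000,
                                     max_extension = 1e6,
                                     coding_only = TRUE) {
  tx <- models$transcripts
  if (coding_only) tx <- tx[tx$coding, , drop = FALSE]
  tx <- tx[tx$strand %in% c("+", "-"), , drop = FALSE]
  # one TSS per gene: the most upstream in transcription direction
  tx <- tx[order(tx$gene_id, ifelse(tx$strand == "+", tx$tss, -tx$tss)), ,
           drop = FALSE]
  tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  len <- chrom_sizes[tx$chrom]
  if (any(is.na(len))) stop("gene on chromosome absent from chrom_sizes")
  bs <- ifelse(tx$strand == "+", tx$tss - basal_up, tx$tss - basal_down + 1)
  be <- ifelse(tx$strand == "+", tx$tss + basal_down, tx$tss + basal_up + 1)
  bs <- pmax(0, bs)
  be <- pmin(as.numeric(len), be)
  d <- data.frame(gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
                  tss = tx$tss, basal_start = bs, basal_end = be,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$basal_start, d$gene_id), , drop = FALSE]
  d$ext_start <- NA_real_
  d$ext_end <- NA_real_
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    bstart <- d$basal_start[i]
    bend <- d$basal_end[i]
    k <- length(i)
    left_limit <- numeric(k)
    right_limit <- numeric(k)
    for (j in seq_len(k)) {
      # a neighbor lying at least partly to this side truncates extension;
      # when basal windows overlap the limit collapses to the basal edge
      other_ends <- bend[-j][bstart[-j] < bstart[j]]
      other_starts <- bstart[-j][bend[-j] > bend[j]]
      left_limit[j] <- if (length(other_ends)) max(other_ends) else 0
      right_limit[j] <- if (length(other_starts)) min(other_starts)
                        else chrom_sizes[ch]
    }
    d$ext_start[i] <- pmin(bstart,
                           pmax(bstart - max_extension, left_limit, 0))
    d$ext_end[i] <- pmax(bend,
                         pmin(bend + max_extension, right_limit,
                              chrom_sizes[ch]))
  }
  rownames(d) <- NULL
  d
}

#' Assign filtered enhancers to target genes
#'
#' An enhancer is assigned to every gene whose extended regulatory domain
#' it overlaps by at least one base. Enhancers overlapping no domain are
#' recorded as unassigned.
#'
#' @param enhancers Data frame of (density-filtered) enhancers with
#'   `chrom`, `start`, `end`.
#' @param domains Output of [build_regulatory_domains()].
#' @return List with `edges` (enhancer-to-gene data frame), `genes`
#'   (sorted unique gene ids) and `unassigned` (enhancers with no target).
#' @export
assign_enhancer_targets <- function(enhancers, domains) {
  if (nrow(enhancers) == 0) {
    return(list(edges = data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), gene_id = character(0),
                                   stringsAsFactors = FALSE),
                genes = character(0), unassigned = enhancers))
  }
  egr <- .iv_to_gr(enhancers)
  dgr <- .iv_to_gr(data.frame(chrom = domains$chrom,
                              start = domains$ext_start,
                              end = domains$ext_end))
  lv <- union(GenomeInfoDb::seqlevels(egr), GenomeInfoDb::seqlevels(dgr))
  GenomeInfoDb::seqlevels(egr) <- lv
  GenomeInfoDb::seqlevels(dgr) <- lv
  hits <- GenomicRanges::findOverlaps(egr, dgr)
  qi <- S4Vectors::queryHits(hits)
  edges <- data.frame(
    chrom = enhancers$chrom[qi],
    start = enhancers$start[qi],
    end = enhancers$end[qi],
    gene_id = domains$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$chrom, edges$start, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  unassigned <- enhancers[setdiff(seq_len(nrow(enhancers)), unique(qi)), ,
                          drop = FALSE]
  rownames(unassigned) <- NULL
  list(edges = edges, genes = sort(unique(edges$gene_id)),
       unassigned = unassigned)
}

#' Genes whose promoters contain HD variants
#'
#' @param promoter_windows Per-TSS promoter windows (the `windows` element
#'   of [build_promoters()]), with `chrom`, `start`, `end`, `gene_id`.
#' @param hd_variants Data frame with `chrom` and `pos` (1-based).
#' @return List with `genes` (sorted unique gene ids with at least one HD
#'   variant in at least one of their promoter windows), `n_promoters`
#'   (number of qualifying per-TSS windows) and `windows` (the windows with
#'   an `hd_count` column).
#' @export
promoter_hd_genes <- function(promoter_windows, hd_variants) {
  w <- promoter_windows
  if (nrow(w) == 0 || nrow(hd_variants) == 0) {
    w$hd_count <- integer(nrow(w))
    return(list(genes = character(0), n_promoters = 0L, windows = w))
  }
  wgr <- .iv_to_gr(w)
  vgr <- GenomicRanges::GRanges(hd_variants$chrom,
                                IRanges::IRanges(hd_variants$pos,
                                                 hd_variants$pos))
  lv <- union(GenomeInfoDb::seqlevels(wgr), GenomeInfoDb::seqlevels(vgr))
  GenomeInfoDb::seqlevels(wgr) <- lv
  GenomeInfoDb::seqlevels(vgr) <- lv
  w$hd_count <- GenomicRanges::countOverlaps(wgr, vgr)
  hit <- w$hd_count > 0
  list(genes = sort(unique(w$gene_id[hit])), n_promoters = sum(hit),
       windows = w)
}
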