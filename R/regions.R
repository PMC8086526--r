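# Region classes: promoters, enhancers, coding exons.

#' Construct a region set
#'
#' A region set is a named class of genomic territory (promoter, enhancer,
#' exon, or a custom class) stored as merged, sorted, non-overlapping
#' 0-based half-open intervals together with provenance.
#'
#' @param name Class name, e.g. `"promoter"`.
#' @param intervals Data frame with columns `chrom`, `start`, `end`;
#'   merged on construction.
#' @param provenance Named list recording source files / parameters.
#' @return An object of class `region_set`.
#' @export
region_set <- function(name, intervals, provenance = list()) {
  structure(
    list(name = name, intervals = merge_intervals(intervals),
         provenance = provenance),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s'>: %d merged intervals, %s bases\n",
              x$name, nrow(x$intervals),
              format(interval_width(x$intervals), big.mark = ",")))
  invisible(x)
}

.as_intervals <- function(x) {
  if (inherits(x, "region_set")) x$intervals else x
}

#' Gene models container
#'
#' Normalized transcript-level annotation used by the region and
#' target-assignment builders: one row per transcript with its strand-aware
#' TSS, plus the coding (CDS) intervals.
#'
#' @param transcripts Data frame with columns `tx_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tss` (0-based position of the first
#'   transcribed base) and `coding` (logical).
#' @param cds Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `tx_id`, `gene_id`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(transcripts, cds) {
  need <- c("tx_id", "gene_id", "chrom", "strand", "tss", "coding")
  if (!all(need %in% names(transcripts))) {
    stop("transcripts must have columns ", paste(need, collapse = ", "))
  }
  if (!all(transcripts$strand %in% c("+", "-", "."))) {
    stop("transcript strand must be one of +, -, .")
  }
  structure(list(transcripts = transcripts, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models>: %d transcripts (%d coding), %d genes, %d CDS intervals\n",
              nrow(x$transcripts), sum(x$transcripts$coding),
              length(unique(x$transcripts$gene_id)), nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3/GTF file
#'
#' Parses transcript (`mRNA`/`transcript`) and `CDS` records; the dialect is
#' auto-detected by rtracklayer. A transcript is coding when it has at least
#' one CDS record. Strandless transcripts are skipped with a warning.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A [gene_models] object (0-based half-open coordinates).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  cds <- gr[type == "CDS"]
  tx_id <- as.character(tx$ID)
  if (length(tx_id) == 0 || all(is.na(tx_id))) {
    tx_id <- as.character(tx$transcript_id)
  }
  gene_id <- .gff_gene_id(tx)
  strand <- as.character(GenomicRanges::strand(tx))
  strandless <- strand == "*"
  if (any(strandless)) {
    warning(sum(strandless), " strandless transcript(s) skipped")
  }
  cds_parent <- .gff_cds_parent(cds)
  tss <- ifelse(strand == "+",
                GenomicRanges::start(tx) - 1L,
                GenomicRanges::end(tx) - 1L)
  transcripts <- data.frame(
    tx_id = tx_id, gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = strand, tss = tss,
    coding = tx_id %in% cds_parent,
    stringsAsFactors = FALSE
  )[!strandless, , drop = FALSE]
  cds_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    tx_id = cds_parent,
    stringsAsFactors = FALSE
  )
  cds_df$gene_id <- transcripts$gene_id[match(cds_df$tx_id, transcripts$tx_id)]
  gene_models(transcripts, cds_df)
}

.gff_gene_id <- function(tx) {
  if (!is.null(tx$Parent) && length(tx$Parent) > 0) {
    p <- vapply(as.list(tx$Parent), function(v) {
      if (length(v)) as.character(v[1]) else NA_character_
    }, character(1))
    if (!all(is.na(p))) return(p)
  }
  if (!is.null(tx$gene_id)) return(as.character(tx$gene_id))
  as.character(tx$ID)
}

.gff_cds_parent <- function(cds) {
  if (length(cds) == 0) return(character(0))
  if (!is.null(cds$Parent) && length(cds$Parent) > 0) {
    return(vapply(as.list(cds$Parent), function(v) {
      if (length(v)) as.character(v[1]) else NA_character_
    }, character(1)))
  }
  as.character(cds$transcript_id)
}

#' Build promoter regions
#'
#' A promoter is the window from `upstream` bases upstream to `downstream`
#' bases downstream of a transcription start site, strand-aware and of fixed
#' total length `upstream + downstream` on both strands (the TSS base counts
#' as the first downstream base). On the plus strand the window for a TSS at
#' 0-based position t is `[t - upstream, t + downstream)`; on the minus
#' strand it mirrors to `[t - downstream + 1, t + upstream + 1)`. Windows
#' are clipped to chromosome bounds.
#'
#' Two views are produced: the per-TSS windows (duplicate TSSs of the same
#' gene deduplicated; used for counting promoters and for mapping variants
#' to genes) and the merged [region_set] used in overlap arithmetic.
#'
#' @param models A [gene_models] object.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param upstream,downstream Window extent in bases (defaults 1000 / 500).
#' @param coding_only Use only coding transcripts (default `TRUE`).
#' @return A `region_set` named `"promoter"` with an extra element
#'   `windows`: a data frame of per-TSS windows with `gene_id` and `tx_id`.
#' @export
build_promoters <- function(models, chrom_sizes, upstream = 1000,
                            downstream = 500, coding_only = TRUE) {
  tx <- models$transcripts
  if (coding_only) tx <- tx[tx$coding, , drop = FALSE]
  tx <- tx[tx$strand %in% c("+", "-"), , drop = FALSE]
  start <- ifelse(tx$strand == "+", tx$tss - upstream, tx$tss - downstream + 1)
  end <- ifelse(tx$strand == "+", tx$tss + downstream, tx$tss + upstream + 1)
  len <- chrom_sizes[tx$chrom]
  if (any(is.na(len))) stop("transcript on chromosome absent from chrom_sizes")
  w <- data.frame(
    chrom = tx$chrom,
    start = pmax(0, start),
    end = pmin(as.numeric(len), end),
    gene_id = tx$gene_id, tx_id = tx$tx_id, strand = tx$strand,
    tss = tx$tss,
    stringsAsFactors = FALSE
  )
  w <- w[w$start < w$end, , drop = FALSE]
  # distinct TSSs only: two transcripts of one gene sharing a TSS are one
  # promoter; the same applies across strand-identical duplicates
  w <- w[!duplicated(w[, c("chrom", "tss", "strand", "gene_id")]), , drop = FALSE]
  w <- w[order(w$chrom, w$start, w$tx_id), , drop = FALSE]
  rownames(w) <- NULL
  rs <- region_set("promoter", w[, c("chrom", "start", "end")],
                   provenance = list(upstream = upstream,
                                     downstream = downstream,
                                     coding_only = coding_only,
                                     n_windows = nrow(w)))
  rs$windows <- w
  rs
}

#' Build coding-exon regions
#'
#' Merged union of CDS intervals (or all exons when `coding_only = FALSE`,
#' in which case CDS intervals are still the source here since the container
#' stores coding intervals).
#'
#' @param models A [gene_models] object.
#' @param coding_only Restrict to coding transcripts (default `TRUE`).
#' @return A `region_set` named `"exon"`.
#' @export
build_exons <- function(models, coding_only = TRUE) {
  cds <- models$cds
  if (coding_only && nrow(cds) > 0) {
    coding_tx <- models$transcripts$tx_id[models$transcripts$coding]
    cds <- cds[cds$tx_id %in% coding_tx, , drop = FALSE]
  }
  region_set("exon",
             if (nrow(cds)) cds[, c("chrom", "start", "end")] else .iv_empty(),
             provenance = list(coding_only = coding_only))
}

#' Build enhancer regions from peak sets
#'
#' Enhancers are the non-promoter parts of the genome covered by open
#' chromatin (ATAC-seq) and/or an H3K27Ac mark: the union of all supplied
#' peak sets minus the promoter territory. Fragments of any length are
#' retained by default.
#'
#' @param peak_sets List of peak interval sets (data frames or
#'   `region_set`s, 0-based half-open).
#' @param promoters Promoter `region_set` (or interval data frame) to
#'   subtract.
#' @param min_length Minimum fragment length kept (default 1, i.e. no
#'   filter).
#' @return A `region_set` named `"enhancer"`, disjoint from the promoters.
#' @export
build_enhancers <- function(peak_sets, promoters, min_length = 1) {
  if (length(peak_sets) == 0) stop("at least one peak set is required")
  pooled <- do.call(rbind, lapply(peak_sets, function(p) {
    .as_intervals(p)[, c("chrom", "start", "end")]
  }))
  enh <- subtract_intervals(merge_intervals(pooled), .as_intervals(promoters))
  enh <- enh[(enh$end - enh$start) >= min_length, , drop = FALSE]
  region_set("enhancer", enh,
             provenance = list(n_peak_sets = length(peak_sets),
                               min_length = min_length))
}

#' Fraction of the genome covered by a region set
#'
#' @param rs A `region_set` or interval data frame.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return Covered bases divided by total genome bases.
#' @export
genome_fraction <- function(rs, chrom_sizes) {
  iv <- .as_intervals(rs)
  if (nrow(iv) > 0) {
    len <- chrom_sizes[iv$chrom]
    if (any(is.na(len))) stop("interval on chromosome absent from chrom_sizes")
    if (any(iv$end > len)) stop("interval extends beyond declared chromosome length")
  }
  interval_width(iv) / sum(chrom_sizes)
}

#' Read a BED file as an interval data frame
#'
#' @param path Path to a BED3+ file.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), plus `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- .gr_to_iv(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Read a chromosome-sizes TSV
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}
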