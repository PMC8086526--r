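# Plain-text writers for the formats the pipeline exchanges.
# Reading goes through vcfR / rtracklayer; writing is done directly so that
# the generator's byte-identical determinism contract holds.

#' Write genotypes as VCF v4.2
#'
#' Emits biallelic SNPs (REF `A`, ALT `G`) with diploid `GT` fields;
#' missing genotypes are `./.`.
#'
#' @param geno A `synth_genotypes` object.
#' @param chrom_sizes Named vector of chromosome lengths (for `##contig`
#'   header lines).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(geno, chrom_sizes, path) {
  stopifnot(inherits(geno, "synth_genotypes"))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[geno$dosage + 1L], nrow = nrow(geno$dosage))
  gt[is.na(geno$dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hdscan_synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
            as.integer(chrom_sizes)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$dosage)), collapse = "\t")
  )
  body <- paste(geno$chrom, geno$pos, ".", "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a synthetic annotation as GFF3
#'
#' One `gene`, one `mRNA` and one `CDS` record per exon for each gene,
#' 1-based inclusive coordinates per the GFF3 standard.
#'
#' @param annotation A `synth_annotation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "synth_annotation"))
  g <- annotation$genes
  gene_lines <- sprintf(
    "%s\thdscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=protein_coding",
    g$chrom, g$start + 1, g$end, g$strand, g$gene_id)
  mrna_lines <- sprintf(
    "%s\thdscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
    g$chrom, g$start + 1, g$end, g$strand, g$tx_id, g$gene_id)
  cds <- annotation$cds
  strand <- g$strand[match(cds$tx_id, g$tx_id)]
  cds_lines <- sprintf(
    "%s\thdscan\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s-%d;Parent=%s",
    cds$chrom, cds$start + 1, cds$end, strand, cds$tx_id,
    stats::ave(seq_len(nrow(cds)), cds$tx_id, FUN = seq_along), cds$tx_id)
  feature <- c(gene_lines, mrna_lines, cds_lines)
  key_start <- c(g$start, g$start, cds$start)
  key_chrom <- c(g$chrom, g$chrom, cds$chrom)
  key_rank <- c(rep(1, nrow(g)), rep(2, nrow(g)), rep(3, nrow(cds)))
  ord <- order(key_chrom, key_start, key_rank)
  writeLines(c("##gff-version 3", feature[ord]), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name` / `score` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, as.integer(df$start), as.integer(df$end))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) cols <- c(cols, list(df$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write a chromosome-sizes TSV
#'
#' @param chrom_sizes Named vector of lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(paste(names(chrom_sizes), as.integer(chrom_sizes), sep = "\t"),
             path)
  invisible(path)
}

#' Read a sample-ID list
#'
#' @param path Plain-text file, one sample identifier per line.
#' @return Character vector.
#' @export
read_sample_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): fewer than 3 fields")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to the set names).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
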