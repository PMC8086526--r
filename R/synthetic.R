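# Synthetic two-population dataset with planted per-region differentiation.
#
# The generator emulates the inputs of a two-population differentiation scan:
# a compact genome with non-overlapping protein-coding genes, ATAC and
# H3K27Ac peak tracks, and diploid genotypes for two population samples
# whose allele frequencies diverge under the Balding-Nichols model. A
# per-region-class divergence parameter can be planted so that recovery of
# the enrichment signal is testable against known truth.

.wrap_seed <- function(seed, offset = 0) {
  as.integer((as.numeric(seed) + offset) %% 2147483629)
}

#' Peak density needed for a target merged coverage
#'
#' Peaks are placed uniformly, so merged coverage of independently placed
#' peaks follows the Poisson-coverage approximation
#' `1 - exp(-density * mean_length)`. This inverts it.
#'
#' @param target Desired merged genome fraction (e.g. 0.054).
#' @param peak_length_range Two-element vector of peak lengths in bases.
#' @param n_sets Number of peak tracks sharing the target (default 2).
#' @return Peaks per megabase per track.
#' @export
peak_density_for_coverage <- function(target, peak_length_range = c(500, 2000),
                                      n_sets = 2) {
  -log(1 - target) * 1e6 / (mean(peak_length_range) * n_sets)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the package is verified under: a
#' 2 x 5 Mb genome with 120 genes (merged promoter coverage about 1.8%,
#' coding-exon coverage about 1.4%), two peak tracks calibrated to about
#' 5.4% merged coverage, samples of 38 and 41 diploids, and a background
#' divergence parameter of 0.2.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total number of protein-coding genes.
#' @param promoter_up,promoter_down Promoter window extent in bases
#'   (defaults 1000 / 500).
#' @param peak_density Peaks per megabase per peak track.
#' @param peak_length_range Range of peak lengths in bases.
#' @param n_sites Number of biallelic SNP sites.
#' @param n_samples_pop1,n_samples_pop2 Diploid sample sizes (defaults
#'   38 / 41).
#' @param f_background Balding-Nichols divergence parameter for sites
#'   outside every planted class, in (0, 1).
#' @param f_by_class Named list mapping region class
#'   (`promoter`/`enhancer`/`exon`) to a planted divergence parameter.
#' @param ancestral_freq_range Interval within (0, 1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param missing_rate Per-genotype missingness probability in `[0, 1)`.
#' @param site_density_by_class Named list of per-class site-density
#'   multipliers (default 1 for every class); controls the variant-count
#'   baseline of the enrichment test.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_chromosomes = 2, chrom_length = 5e6, n_genes = 120,
                         promoter_up = 1000, promoter_down = 500,
                         peak_density = peak_density_for_coverage(0.054),
                         peak_length_range = c(500, 2000),
                         n_sites = 1e5,
                         n_samples_pop1 = 38, n_samples_pop2 = 41,
                         f_background = 0.2, f_by_class = list(),
                         ancestral_freq_range = c(0.05, 0.95),
                         missing_rate = 0,
                         site_density_by_class = list(),
                         seed = 1) {
  counts <- c(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, n_sites = n_sites,
              n_samples_pop1 = n_samples_pop1, n_samples_pop2 = n_samples_pop2)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (!(f_background > 0 && f_background < 1)) {
    stop("f_background must be in (0, 1)")
  }
  if (length(f_by_class)) {
    if (is.null(names(f_by_class)) || any(names(f_by_class) == "")) {
      stop("f_by_class must be a named list")
    }
    if (!all(unlist(f_by_class) > 0 & unlist(f_by_class) < 1)) {
      stop("every f_by_class value must be in (0, 1)")
    }
    if (!all(names(f_by_class) %in% c("promoter", "enhancer", "exon"))) {
      stop("f_by_class names must be promoter, enhancer or exon")
    }
  }
  if (!(length(ancestral_freq_range) == 2 &&
        ancestral_freq_range[1] > 0 && ancestral_freq_range[2] < 1 &&
        ancestral_freq_range[1] < ancestral_freq_range[2])) {
    stop("ancestral_freq_range must be an increasing interval within (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (peak_length_range[1] < 1 || peak_length_range[1] > peak_length_range[2]) {
    stop("invalid peak_length_range")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, n_genes = as.integer(n_genes),
    promoter_up = promoter_up, promoter_down = promoter_down,
    peak_density = peak_density, peak_length_range = peak_length_range,
    n_sites = as.integer(n_sites),
    n_samples_pop1 = as.integer(n_samples_pop1),
    n_samples_pop2 = as.integer(n_samples_pop2),
    f_background = f_background, f_by_class = f_by_class,
    ancestral_freq_range = ancestral_freq_range,
    missing_rate = missing_rate,
    site_density_by_class = site_density_by_class,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Simulate genome annotation and peak tracks
#'
#' Places non-overlapping gene bodies (each with 1-4 coding exons, the first
#' starting at the gene 5' end so the TSS is well defined), assigns strands,
#' and scatters two peak tracks (`atac`, `h3k27ac`) uniformly along the
#' genome.
#'
#' @param config A [synth_config].
#' @return An object of class `synth_annotation`: `genes` and `cds` data
#'   frames (0-based half-open), `peaks` (list of BED-like data frames),
#'   `chrom_sizes`, and the `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.wrap_seed(config$seed, 0))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                           paste0("chr", seq_len(config$n_chromosomes)))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  genes <- list()
  cds <- list()
  gi <- 0L
  for (ci in seq_along(sizes)) {
    k <- per_chrom[ci]
    if (k == 0) next
    L <- sizes[ci]
    lens <- round(stats::runif(k, 3000, 12000))
    if (sum(lens) + (k + 1) > L) {
      stop("infeasible configuration: genes cannot fit on chromosome ",
           names(sizes)[ci], " without overlap")
    }
    free <- L - sum(lens) - (k + 1)
    props <- diff(c(0, sort(stats::runif(k)), 1))
    gaps <- 1 + floor(free * props)
    starts <- cumsum(gaps)[seq_len(k)] + c(0, cumsum(lens))[seq_len(k)]
    strand <- sample(c("+", "-"), k, replace = TRUE)
    for (j in seq_len(k)) {
      gi <- gi + 1L
      gid <- sprintf("gene%04d", gi)
      gstart <- starts[j]
      ex <- .simulate_exons(gstart, lens[j])
      gend <- ex$gene_end
      genes[[gi]] <- data.frame(
        gene_id = gid, tx_id = paste0(gid, ".t1"),
        chrom = names(sizes)[ci], strand = strand[j],
        start = gstart, end = gend,
        tss = if (strand[j] == "+") gstart else gend - 1,
        stringsAsFactors = FALSE
      )
      cds[[gi]] <- data.frame(
        chrom = names(sizes)[ci], start = ex$start, end = ex$end,
        tx_id = paste0(gid, ".t1"), gene_id = gid,
        stringsAsFactors = FALSE
      )
    }
  }
  peaks <- lapply(stats::setNames(nm = c("atac", "h3k27ac")), function(nm) {
    .simulate_peaks(config, sizes, nm)
  })
  structure(list(
    genes = do.call(rbind, genes), cds = do.call(rbind, cds),
    peaks = peaks, chrom_sizes = sizes, config = config
  ), class = "synth_annotation")
}

# 1-4 coding exons starting at gstart, fitted inside a reserved slot of
# slot_len bases; exon lengths are drawn directly (coding bases stay a
# small share of the gene body), introns absorb the rest
.simulate_exons <- function(gstart, slot_len) {
  k <- sample.int(4, 1)
  e <- round(stats::runif(k, 150, 780))
  intr <- if (k > 1) round(stats::runif(k - 1, 200, 2000)) else numeric(0)
  excess <- sum(e) + sum(intr) - slot_len
  if (excess > 0) {
    if (k > 1 && sum(intr) - excess >= 50 * (k - 1)) {
      intr <- intr - excess * intr / sum(intr)
      intr <- pmax(50, round(intr))
    }
    if (sum(e) + sum(intr) > slot_len) {
      k <- 1L
      e <- min(slot_len, 300)
      intr <- numeric(0)
    }
  }
  m <- 2L * k - 1L
  seg <- numeric(m)
  seg[seq(1, m, by = 2)] <- e
  if (k > 1) seg[seq(2, m, by = 2)] <- intr
  ends <- gstart + cumsum(seg)
  starts <- c(gstart, ends[-m])
  is_exon <- seq_len(m) %% 2 == 1
  list(start = starts[is_exon], end = ends[is_exon],
       gene_end = gstart + sum(seg))
}

.simulate_peaks <- function(config, sizes, name) {
  total_mb <- sum(sizes) / 1e6
  n_peaks <- max(1, round(config$peak_density * total_mb))
  chrom <- sample(names(sizes), n_peaks, replace = TRUE,
                  prob = sizes / sum(sizes))
  len <- round(stats::runif(n_peaks, config$peak_length_range[1],
                            config$peak_length_range[2]))
  start <- floor(stats::runif(n_peaks) * (sizes[chrom] - len))
  df <- data.frame(chrom = chrom, start = start, end = start + len,
                   name = sprintf("%s_peak%05d", name, seq_len(n_peaks)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert a synthetic annotation to gene models
#'
#' @param annotation A `synth_annotation`.
#' @return A [gene_models] object (one transcript per gene, all coding).
#' @export
as_gene_models <- function(annotation) {
  stopifnot(inherits(annotation, "synth_annotation"))
  g <- annotation$genes
  gene_models(
    transcripts = data.frame(
      tx_id = g$tx_id, gene_id = g$gene_id, chrom = g$chrom,
      strand = g$strand, tss = g$tss, coding = TRUE,
      stringsAsFactors = FALSE
    ),
    cds = annotation$cds
  )
}

#' Region classes of a synthetic annotation
#'
#' Builds the promoter, enhancer and coding-exon region sets from a
#' synthetic annotation with the configured promoter window.
#'
#' @param annotation A `synth_annotation`.
#' @return Named list of three [region_set]s.
#' @export
synth_region_sets <- function(annotation) {
  cfg <- annotation$config
  models <- as_gene_models(annotation)
  promoters <- build_promoters(models, annotation$chrom_sizes,
                               upstream = cfg$promoter_up,
                               downstream = cfg$promoter_down)
  list(
    promoter = promoters,
    enhancer = build_enhancers(annotation$peaks, promoters),
    exon = build_exons(models)
  )
}

#' Simulate per-site population allele frequencies
#'
#' Sites are placed along the genome (uniformly by default; per-class
#' density multipliers shift the variant-count baseline), each gets an
#' ancestral frequency drawn uniformly from `ancestral_freq_range`, and the
#' two population frequencies are drawn from the Balding-Nichols model:
#' `p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with mean `p` and variance
#' `p(1-p)F`. `F` is `f_by_class[[class]]` for sites inside a planted class
#' and `f_background` otherwise. Class labels follow the priority
#' promoter > enhancer > exon > background, so each site has exactly one
#' planted divergence parameter. Draws where both populations land on the
#' same fixed allele are re-drawn (F_ST is undefined for monomorphic sites);
#' the count is recorded in the `n_freq_redraws` attribute.
#'
#' @param config A [synth_config].
#' @param annotation Output of [simulate_annotation()].
#' @return A `planted_truth` data frame with columns `chrom`, `pos`
#'   (1-based), `class`, `p_anc`, `f`, `p1`, `p2`; the region sets used for
#'   labelling are attached as attribute `regions`.
#' @export
simulate_site_frequencies <- function(config, annotation) {
  stopifnot(inherits(config, "synth_config"),
            inherits(annotation, "synth_annotation"))
  set.seed(.wrap_seed(config$seed, 1000003))
  sizes <- annotation$chrom_sizes
  regions <- synth_region_sets(annotation)
  genome <- data.frame(chrom = names(sizes), start = 0,
                       end = as.numeric(sizes), stringsAsFactors = FALSE)
  prom <- regions$promoter$intervals
  enh <- regions$enhancer$intervals
  exon_only <- subtract_intervals(regions$exon$intervals,
                                  union_intervals(prom, enh))
  covered <- union_intervals(union_intervals(prom, enh), exon_only)
  background <- subtract_intervals(genome, covered)
  class_iv <- list(promoter = prom, enhancer = enh, exon = exon_only,
                   background = background)
  bases <- vapply(class_iv, interval_width, numeric(1))
  mult <- vapply(names(class_iv), function(cl) {
    m <- config$site_density_by_class[[cl]]
    if (is.null(m)) 1 else m
  }, numeric(1))
  w <- bases * mult
  n_per <- as.vector(stats::rmultinom(1, config$n_sites, prob = w))
  names(n_per) <- names(class_iv)
  if (any(n_per > bases)) {
    stop("infeasible configuration: more sites requested than bases in class")
  }
  out <- list()
  for (cl in names(class_iv)) {
    n_c <- n_per[[cl]]
    if (n_c == 0) next
    iv <- class_iv[[cl]]
    widths <- iv$end - iv$start
    cum <- c(0, cumsum(widths))
    off <- sort(sample(sum(widths), n_c))
    idx <- findInterval(off - 1, cum, rightmost.closed = FALSE) # off-1 in [cum[i], cum[i+1])
    out[[cl]] <- data.frame(
      chrom = iv$chrom[idx],
      pos = iv$start[idx] + (off - cum[idx]), # 1-based
      class = cl, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, out)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  n <- nrow(truth)
  truth$p_anc <- stats::runif(n, config$ancestral_freq_range[1],
                              config$ancestral_freq_range[2])
  truth$f <- config$f_background
  for (cl in names(config$f_by_class)) {
    truth$f[truth$class == cl] <- config$f_by_class[[cl]]
  }
  draw_bn <- function(p, f) {
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  truth$p1 <- draw_bn(truth$p_anc, truth$f)
  truth$p2 <- draw_bn(truth$p_anc, truth$f)
  redraws <- 0L
  for (it in seq_len(100)) {
    bad <- (truth$p1 <= 0 & truth$p2 <= 0) | (truth$p1 >= 1 & truth$p2 >= 1)
    if (!any(bad)) break
    redraws <- redraws + sum(bad)
    truth$p1[bad] <- draw_bn(truth$p_anc[bad], truth$f[bad])
    truth$p2[bad] <- draw_bn(truth$p_anc[bad], truth$f[bad])
  }
  attr(truth, "n_freq_redraws") <- redraws
  attr(truth, "regions") <- regions
  class(truth) <- c("planted_truth", "data.frame")
  truth
}

#' Simulate diploid genotypes from planted frequencies
#'
#' Each sample's genotype at a site is a Binomial(2, p_pop) dosage of the
#' alternate allele; genotypes are masked missing independently at
#' `missing_rate`. Sites whose realized genotypes are monomorphic across
#' both populations combined (F_ST would be undefined) are re-drawn, up to
#' 100 rounds; the number of re-drawn site rounds is recorded in the
#' `n_geno_redraws` attribute.
#'
#' @param truth Output of [simulate_site_frequencies()].
#' @param config The same [synth_config].
#' @return An object of class `synth_genotypes`: `chrom`, `pos`, integer
#'   dosage matrix (`NA` = missing) with one column per sample, and the two
#'   sample-name vectors.
#' @export
simulate_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "synth_config"))
  set.seed(.wrap_seed(config$seed, 2000003))
  n <- nrow(truth)
  n1 <- config$n_samples_pop1
  n2 <- config$n_samples_pop2
  draw_pop <- function(p, k) {
    m <- matrix(stats::rbinom(n * k, 2, p), nrow = n, ncol = k)
    if (config$missing_rate > 0) {
      m[stats::runif(n * k) < config$missing_rate] <- NA_integer_
    }
    m
  }
  d1 <- draw_pop(truth$p1, n1)
  d2 <- draw_pop(truth$p2, n2)
  mono_rows <- function(idx) {
    a <- rowSums(d1[idx, , drop = FALSE], na.rm = TRUE) +
      rowSums(d2[idx, , drop = FALSE], na.rm = TRUE)
    cl <- 2 * (rowSums(!is.na(d1[idx, , drop = FALSE])) +
                 rowSums(!is.na(d2[idx, , drop = FALSE])))
    idx[cl == 0 | a == 0 | a == cl]
  }
  redraws <- 0L
  bad <- mono_rows(seq_len(n))
  it <- 0L
  while (length(bad) && it < 100L) {
    it <- it + 1L
    redraws <- redraws + length(bad)
    nb <- length(bad)
    redraw_rows <- function(p, k) {
      m <- matrix(stats::rbinom(nb * k, 2, p), nrow = nb, ncol = k)
      if (config$missing_rate > 0) {
        m[stats::runif(nb * k) < config$missing_rate] <- NA_integer_
      }
      m
    }
    d1[bad, ] <- redraw_rows(truth$p1[bad], n1)
    d2[bad, ] <- redraw_rows(truth$p2[bad], n2)
    bad <- mono_rows(bad)
  }
  dosage <- cbind(d1, d2)
  s1 <- sprintf("pop1_s%02d", seq_len(n1))
  s2 <- sprintf("pop2_s%02d", seq_len(n2))
  colnames(dosage) <- c(s1, s2)
  structure(list(chrom = truth$chrom, pos = truth$pos, dosage = dosage,
                 samples_pop1 = s1, samples_pop2 = s2),
            class = "synth_genotypes", n_geno_redraws = redraws)
}

#' Simulate gene-set collections
#'
#' Draws random gene sets from a gene universe, optionally with planted
#' sets supplied verbatim, for exercising the gene-set enrichment stage.
#'
#' @param universe Character vector of gene identifiers.
#' @param n_sets Number of random sets.
#' @param size_range Range of set sizes.
#' @param planted Named list of gene vectors included as-is.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors (a GMT-style collection).
#' @export
simulate_gene_sets <- function(universe, n_sets = 50, size_range = c(10, 40),
                               planted = list(), seed = 1) {
  set.seed(.wrap_seed(seed, 3000003))
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sample(seq(size_range[1], size_range[2]), 1)
    sort(sample(universe, min(k, length(universe))))
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  c(planted, sets)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the full generator ([simulate_annotation()],
#' [simulate_site_frequencies()], [simulate_genotypes()],
#' [simulate_gene_sets()]) and writes the standard files a real analysis
#' would consume: VCF, two sample lists, GFF3, one BED per peak track, a
#' chromosome-sizes TSV, a GMT collection and the planted-truth TSV.
#'
#' @param config A [synth_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the in-memory
#'   simulation objects (`annotation`, `truth`, `genotypes`).
#' @export
simulate_hd_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  annotation <- simulate_annotation(config)
  truth <- simulate_site_frequencies(config, annotation)
  geno <- simulate_genotypes(truth, config)
  sets <- simulate_gene_sets(annotation$genes$gene_id, seed = config$seed)
  paths <- list(
    vcf = file.path(dir, "variants.vcf"),
    samples_pop1 = file.path(dir, "samples_pop1.txt"),
    samples_pop2 = file.path(dir, "samples_pop2.txt"),
    gff = file.path(dir, "annotation.gff3"),
    peaks = stats::setNames(file.path(dir, paste0(names(annotation$peaks), ".bed")),
                            names(annotation$peaks)),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "planted_truth.tsv")
  )
  write_vcf(geno, annotation$chrom_sizes, paths$vcf)
  writeLines(geno$samples_pop1, paths$samples_pop1)
  writeLines(geno$samples_pop2, paths$samples_pop2)
  write_gff3(annotation, paths$gff)
  for (nm in names(annotation$peaks)) {
    write_bed(annotation$peaks[[nm]], paths$peaks[[nm]])
  }
  write_chrom_sizes(annotation$chrom_sizes, paths$chrom_sizes)
  write_gmt(sets, paths$gmt)
  utils::write.table(as.data.frame(truth), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(annotation = annotation, truth = truth,
                          genotypes = geno, gene_sets = sets)))
}
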