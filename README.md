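# hdscan

Scans for **highly differentiated (HD) variants** — biallelic SNPs in the
top quantile of per-site F_ST between two populations — and quantifies
their enrichment in **promoters, enhancers and coding exons**, with
target-gene assignment and gene-set enrichment downstream. The package is
aimed at population and regulatory genomicists comparing a derived
population against its source (domesticates vs wild relatives, selected
lines vs founders) who want to ask whether differentiation concentrates in
cis-regulatory territory rather than the exome.

A built-in synthetic-data generator plants a known per-region divergence
structure (Balding–Nichols model), so every stage of the pipeline can be
verified against ground truth without any external download.

## The statistics

**Per-site F_ST.** For each site, with alternate-allele counts
`a_i` among `n_i` called chromosomes in population *i* (`p_i = a_i/n_i`):

- *Weir–Cockerham (default)*: the variance-components estimator applied to
  the allele indicators, `theta = (MSB − MSW) / (MSB + (n_c − 1) MSW)`,
  where MSB/MSW are the between/within-population mean squares and
  `n_c = n_T − (n_1² + n_2²)/n_T` is the variance-effective sample size.
- *Hudson (Bhatia form)*:
  `N = (p_1 − p_2)² − p_1(1−p_1)/(n_1−1) − p_2(1−p_2)/(n_2−1)`,
  `D = p_1(1−p_2) + p_2(1−p_1)`, `theta = N/D`.

Negative estimates clamp to 0 (raw values are retained); sites monomorphic
across both populations, or with fewer than two called chromosomes in
either population, are dropped with logged counts.

**HD selection and strata.** The top 1% (configurable) of F_ST values,
ties at the threshold included; strata keep complete fixation (`=1`)
separate from `[0.9, 1)`.

**Region classes.** Promoters are 1,000 bases upstream to 500 bases
downstream of each coding TSS (strand-aware, per-TSS windows kept for gene
mapping, merged set used for overlap arithmetic). Enhancers are the union
of the supplied peak tracks (open chromatin and/or H3K27Ac) minus
promoter territory. Exons are the merged CDS intervals. All arithmetic is
0-based half-open.

**Enrichment.** For each (stratum × class) cell the fold enrichment is
`(HD fraction in class) / (fraction of all tested variants in class)` —
a variant-count baseline, so depressed SNP density in constrained regions
does not masquerade as enrichment (a genomic-base-fraction fold is
reported alongside). The p-value is the one-sided hypergeometric upper
tail, computed in log space so extreme tails stay representable.

**Targets and gene sets.** Enhancers carrying at least one HD variant per
500 bases are assigned to genes by basal-plus-extension regulatory
domains (5 kb up / 1 kb down, extended up to 1 Mb, truncated at
neighboring basal domains); genes with HD promoter variants are added.
Gene lists are tested against GMT collections with the hypergeometric
test, BH-FDR adjusted, and enriched terms are clustered by the Jaccard
distance of their query-overlap gene sets into a newick tree.

## Worked example

```r
library(hdscan)
res <- hdscan_demo("demo_out", seed = 7)
enr <- res$results$enrichment
enr[enr$stratum == "top1%", c("class", "n_hd_in", "n_hd_total",
                              "pct_hd", "fold", "log10_p")]
```

The demo simulates a 2 × 2.5 Mb genome (60 genes, two peak tracks, region
coverages 1.79% promoter / 5.28% enhancer / 1.30% exon), 40,000 SNPs and
38 + 41 diploid samples, with divergence F = 0.6 planted in promoters and
0.5 in enhancers over a 0.2 background, then runs the full pipeline.
It prints:

```
     class n_hd_in n_hd_total pct_hd   fold   log10_p
1 promoter      97        398    24% 13.854  -80.5168
2 enhancer     182        398    46%  8.820 -124.0843
3     exon      23        398   5.8%  4.380   -8.3197
```

Of the 398 top-1% variants (realized threshold F_ST ≥ 0.797), 24% fall in
promoters — a 13.9-fold excess over the 1.8% of all tested variants that
promoters contain, at a hypergeometric tail of 10^-80.5 — and 46% in
enhancers (8.8-fold). The exon fold (4.4) reflects the planted promoter
signal leaking into first exons that overlap promoter windows, not an
exonic effect. Downstream, 19 of 206 enhancers pass the 1-per-500-bases
HD density filter and map to 26 target genes; 48 genes carry an HD
variant in a promoter; the union list of 55 genes feeds the gene-set
stage. Per-stage outputs (TSV/BED/JSON and a checksummed manifest) land
in `demo_out/results/`. The same pipeline runs on real data from a YAML
config via `run_hdscan("config.yaml")` or the CLI wrapper
`inst/cli/hdscan.R` (subcommands `demo`, `all`, and one per stage).

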