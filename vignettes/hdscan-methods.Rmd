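---
title: "Methods: differentiation scans and regulatory enrichment in hdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation scans and regulatory enrichment in hdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdscan)
```

# Overview

`hdscan` implements a two-population differentiation scan with a
regulatory-genomics readout: per-site F_ST from a multi-sample VCF, a
top-quantile selection of highly differentiated (HD) variants, overlap of
those variants with promoter / enhancer / exon region classes built from
annotation and peak files, fold-enrichment statistics per F_ST stratum,
target-gene assignment for HD-dense enhancers, and gene-set enrichment of
the resulting gene lists. A synthetic generator with planted per-region
divergence provides ground truth for every stage; this vignette explains
the models, the defaults, and the choices made where the design was
genuinely open.

# Per-site F_ST

Both estimators consume the same substrate: per site, the alternate-allele
count and the number of successfully genotyped chromosomes in each
population. Missing and half-called genotypes contribute nothing; sites
monomorphic across both populations combined are dropped (F_ST is
undefined there), as are sites with fewer than two called chromosomes in
either population — dropped, never imputed.

**Weir–Cockerham (default).** The 1984 variance-components estimator is
applied at the allele level, i.e. the called chromosomes are the sampling
units of a one-way ANOVA on allele indicators:

$$\hat\theta=\frac{MSB-MSW}{MSB+(n_c-1)\,MSW},\qquad
n_c=n_T-\frac{n_1^2+n_2^2}{n_T},$$

with $MSB=\sum_i n_i(p_i-\bar p)^2$ (two populations, one degree of
freedom) and $MSW=\sum_i n_i p_i(1-p_i)/(n_T-2)$. The allele-level form is
the one determined by the substrate: the genotype-level variant needs
per-individual heterozygosity, which the allele-count table deliberately
does not carry. Under Hardy–Weinberg sampling — which is how the synthetic
generator draws genotypes — the two forms estimate the same quantity; for
equal sample sizes the allele-level estimator coincides exactly with the
Hudson form below (a property the tests exploit as a cross-check, using
unequal sizes to tell the estimators apart).

**Hudson (Bhatia form).** With $p_i$ the sample frequency among $n_i$
chromosomes:

$$N=(p_1-p_2)^2-\frac{p_1(1-p_1)}{n_1-1}-\frac{p_2(1-p_2)}{n_2-1},\qquad
D=p_1(1-p_2)+p_2(1-p_1).$$

The correction terms make $E[N]$ unbiased for the squared frequency
difference, so the *ratio of averages* $\sum N/\sum D$ estimates the
Balding–Nichols divergence parameter F directly — this is what the
parameter-recovery checks use.

**Numerical choices.** Negative per-site estimates are clamped to 0 so
values can be binned into $[0,1]$; the raw ratio is retained in the
output (`fst_raw`) for transparency. Which estimator produced a table is
recorded in an `estimator` column. Per-site (not windowed) values are
used throughout because individual variants, not regions, are selected.
Non-autosomal chromosomes are excluded by default at VCF reading
(`autosomes_only = TRUE`).

# HD selection and F_ST strata

`select_hd()` takes the `ceiling(q·N)` highest values (default
`q = 0.01`) and reports the realized threshold. Ties at the threshold are
all included — the conservative choice that avoids order-dependence — and
flagged. `bin_fst()` assigns left-closed right-open bins with interior
edges `0.5, 0.6, 0.7, 0.8, 0.9` by default, and keeps F_ST exactly 1 as
its own stratum `=1`: complete fixation is qualitatively different from
`[0.9, 1)` and is reported separately.

# Region classes

All interval arithmetic is 0-based half-open (the BED convention); GFF3's
1-based inclusive coordinates are converted at the file boundary. The set
operations are delegated to GenomicRanges and verified against a per-base
bitmap oracle in the tests.

- **Promoters** — one window per distinct coding-transcript TSS, 1,000
  bases upstream to 500 bases downstream. The window has a fixed length of
  1,500 bases on both strands, with the TSS base counted as the first
  downstream base; on the minus strand the window for a TSS at 0-based
  position $t$ is $[t-499,\,t+1001)$. Windows are clipped at chromosome
  ends. Two views are emitted: per-TSS windows (for counting promoters and
  mapping variants to genes) and the merged set (for overlap arithmetic).
- **Enhancers** — the union of all supplied peak tracks ("and/or" of open
  chromatin and H3K27Ac is read inclusively, i.e. set union) minus
  promoter territory. No minimum fragment length by default.
- **Exons** — the merged union of CDS intervals of coding transcripts.

Exons are *not* subtracted from promoters or enhancers: classes other
than enhancer-vs-promoter may overlap, and variant membership is
correspondingly non-exclusive. The overlap matters in practice — the
downstream 500 bases of a promoter window usually cover the first exon —
and its consequences for enrichment are discussed below.

# Enrichment statistics

For each stratum (the overall top-quantile selection plus each F_ST bin)
and region class, the fold enrichment is

$$\text{fold}=\frac{n^{HD}_{in}/n^{HD}}{n^{all}_{in}/n^{all}},$$

the HD occupancy of the class relative to the occupancy by *all tested
variants*. The variant-count baseline is primary because SNP density
differs systematically between region classes (constrained sequence holds
fewer variants), which a genomic-base-fraction baseline would misread as
enrichment; the base-fraction fold is computed alongside when chromosome
sizes are provided. The p-value is the one-sided upper-tail
hypergeometric probability of drawing at least $n^{HD}_{in}$ class
members in $n^{HD}$ draws from the tested-variant universe, computed via
`phyper(..., log.p = TRUE)` so tails far below the double-precision
underflow limit remain representable as `log10_p`. Report percentages
follow the convention: whole percent at or above 10%, one decimal below.

# Target assignment

Enhancers are kept when they carry at least one HD variant per 500 bases,
read as a global per-enhancer rate (`count/length >= 1/500`, boundary
equality kept; zero-HD enhancers always dropped). The phrase "one variant
in every 500 bases" also admits a strict sliding-window reading — every
500-base window must contain a variant — which is available behind
`sliding_window = TRUE`; the rate reading is the default because it is
the weaker, more inclusive interpretation. The filter counts HD variants
(matching the surrounding analysis), not all variants.

Regulatory domains follow the basal-plus-extension rule: a strand-aware
basal window (5 kb upstream / 1 kb downstream of the TSS) extended in
both directions up to 1 Mb, truncating at the nearest neighboring gene's
basal domain and at chromosome ends; extension never shrinks a domain
below its own basal window, so when basal windows of adjacent genes
overlap, both keep their basal territory. This geometric rule is a
re-implementation of the published default of regulatory-domain
assignment tools; expression-aware or curated-enhancer-aware assignment
is out of scope. An enhancer is assigned to every gene whose extended
domain it overlaps by at least one base; enhancers in domain deserts are
recorded as unassigned. Genes whose per-TSS promoter windows contain at
least one HD variant are collected separately, with the qualifying
promoter count reported alongside (a gene may have several).

# Gene-set enrichment and the term tree

Gene lists are tested against GMT collections with the same upper-tail
hypergeometric test, adjusted across terms by Benjamini–Hochberg
(`stats::p.adjust`). Query and term members outside the universe are
dropped with logged counts. The recommended universe — and the one the
pipeline builds — is the set of annotated genes with at least one tested
variant in their promoter windows, coding exons or extended regulatory
domain: that is the frame within which the query lists were selected.
The universe choice materially affects enrichment results and is
surfaced as an explicit argument for that reason.

Enriched terms are clustered by the Jaccard distance
$1-|A\cap B|/|A\cup B|$ of their query-overlap gene sets, with average
linkage by default (configurable); terms are name-sorted before
clustering so the newick tree is reproducible regardless of input order.
Report thresholds default to FDR 0.05, with a configurable cap (default
30) on the number of enriched terms carried into the tree.

# The synthetic generator

`simulate_hd_dataset()` emulates the full input bundle: a genome with
non-overlapping protein-coding genes (1–4 coding exons each, the first
starting at the gene's 5' end so the TSS is well defined), two peak
tracks, diploid genotypes for two populations, sample lists, a GMT
collection and a planted-truth table, written as VCF / GFF3 / BED / TSV.
Identical configurations (including the seed) produce byte-identical
files.

**Divergence model.** Each site gets an ancestral frequency
$p\sim U(0.05, 0.95)$ and each population's frequency is drawn from the
Balding–Nichols distribution
$\mathrm{Beta}\big(p(1-F)/F,\,(1-p)(1-F)/F\big)$, which has mean $p$ and
variance $p(1-p)F$ — so the planted $F$ is also the expected F_ST,
giving closed-form recovery targets. $F$ is `f_by_class[[class]]` inside
a planted region class and `f_background` elsewhere. Because a site can
sit in overlapping classes, planting uses the disjoint priority
promoter > enhancer > exon > background, so each site has exactly one
planted parameter. Genotypes are Binomial(2, p_pop) dosages, masked
missing at `missing_rate`. Draws where both populations land on the same
fixed allele, and genotype draws that come out monomorphic across both
populations, are re-drawn with bounded retries (counts recorded as
attributes); the downstream pipeline drops any residually monomorphic
site, and the recovery oracles mirror that conditioning.

**Default conditions.** 2 chromosomes × 5 Mb; 120 genes, giving merged
promoter coverage ≈ 1.8% and coding-exon coverage ≈ 1.3–1.4% of the
genome; two peak tracks whose density is calibrated by the
Poisson-coverage relation (`peak_density_for_coverage()`) to ≈ 5.4%
merged coverage — proportions chosen to match the published annotation
shares of a mammalian genome analysed this way (promoters ≈ 1.7%,
enhancers ≈ 5.4%, exons ≈ 1.4%). Samples of 38 and 41 diploids mirror
the two-population comparison that motivates the package. The background
divergence default `f_background = 0.2` is a realistic genome-wide level
for a domesticate-vs-wild comparison; recovery analyses plant
`f_promoter = 0.6` against it. Sites are placed uniformly; an optional
per-class site-density multiplier shifts the variant-count baseline to
emulate constrained-sequence SNP depletion (default 1, i.e. off).

**What the generator does not emulate.** No linkage disequilibrium (sites
are independent, so there is no clumping of HD variants), no coalescent
history, no sequencing error, no indels or multiallelic sites, no QC
artifacts beyond uniform missingness, and one transcript per gene.
Passing tests therefore demonstrate the correctness and calibration of
the *statistics* under the stated sampling model, not robustness to the
correlation structure of real resequencing data — on real data,
LD-induced clustering inflates the effective weight of selected regions
and the hypergeometric p-values should be read as descriptive, not
literal.

**Problem sizes used in verification.** The test suite calibrates the
null at 200 replicates of 4,000 sites (38+41 diploids) and recovers the
planted promoter signal over 20 replicates of 100,000 sites, comparing
each class fold against a 10^6-site Monte-Carlo of the generator's
site-level distribution within three standard errors (replicate
variation and Monte-Carlo error combined in quadrature). Two effects are
worth noting when reading those checks: a planted promoter excess raises
the realized top-1% threshold, so classes with background divergence
settle at folds slightly below 1; and the intrinsic promoter–first-exon
overlap lets the non-exclusive exon class inherit part of a planted
promoter signal, while the promoter-exclusive exome stays at baseline.
Both are properties of the geometry, reproduced by the oracle, not
artifacts of the estimator.

# Pipeline and reproducibility

`run_hdscan()` executes fst → regions → enrichment → targets → gene sets
with a TSV/BED/JSON file contract between stages, so each stage can be
re-run alone (`stage_fst()` … `stage_genesets()`, or the CLI wrapper's
subcommands). A JSON manifest records the configuration, package
version, row counts and an md5 checksum of every output; identical
configurations reproduce identical checksums. Configuration is a single
YAML file mirroring `pipeline_config()`'s arguments; all input paths are
validated before any computation starts.

# Known limitations

- The enrichment null is the hypergeometric draw of exchangeable
  variants; no LD-aware or MAF-matched permutation null is provided
  (a documented extension point).
- Regulatory-domain assignment is purely geometric; no expression
  weighting or chromatin-loop data.
- Gene-set testing treats collections as flat GMT files; no
  ontology-graph propagation.
- The promoter count uses distinct (gene, TSS) windows; annotations with
  many identical-TSS transcript isoforms collapse to one window each.
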