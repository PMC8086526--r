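# Independent oracles used to verify the implementation by a second route.
# These are deliberately written from the defining formulas, not by calling
# package code.

# Weir-Cockerham variance-components F_ST, general r-population allele-level
# ANOVA transcription (scalar, one site)
oracle_fst_wc <- function(alt, called) {
  r <- length(called)
  p <- alt / called
  pbar <- sum(called * p) / sum(called)
  msp <- sum(called * (p - pbar)^2) / (r - 1)
  msg <- sum(called * p * (1 - p)) / sum(called - 1)
  nc <- (sum(called) - sum(called^2) / sum(called)) / (r - 1)
  num <- (msp - msg) / nc
  den <- (msp + (nc - 1) * msg) / nc
  c(num = num, den = den, fst = num / den)
}

# Hudson/Bhatia closed form (scalar, one site)
oracle_fst_hudson <- function(alt1, called1, alt2, called2) {
  p1 <- alt1 / called1
  p2 <- alt2 / called2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (called1 - 1) -
    p2 * (1 - p2) / (called2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den, fst = num / den)
}

# Upper-tail hypergeometric by direct enumeration of the mass function
oracle_hyper_ge <- function(k, K, n, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Per-base bitmap interval algebra on a single toy chromosome of length L.
# Intervals are 0-based half-open; the bitmap marks covered bases.
bm_from_iv <- function(iv, L, chrom = "chr1") {
  bm <- logical(L)
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) bm[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  bm
}

iv_from_bm <- function(bm, chrom = "chr1") {
  r <- rle(bm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

random_iv <- function(n, L, chrom = "chr1") {
  start <- sample.int(L, n, replace = TRUE) - 1L
  len <- sample.int(max(2, L %/% 10), n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(L, start + len), stringsAsFactors = FALSE)
}
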