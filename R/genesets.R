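# Gene-set enrichment and term clustering.

#' Hypergeometric gene-set test
#'
#' Upper-tail hypergeometric probability of an overlap of at least `k`
#' between the query and the term, drawn from the universe. Query and term
#' members outside the universe are dropped (counts recorded in the
#' result).
#'
#' @param query Character vector of query gene ids.
#' @param term Character vector of term (gene-set) member ids.
#' @param universe Character vector of all eligible gene ids.
#' @return List with `k` (overlap), `K` (term size in universe), `n`
#'   (query size in universe), `N` (universe size), `p`, `log10_p`,
#'   `genes` (the overlapping ids, sorted) and `n_dropped` (query/term
#'   members outside the universe).
#' @export
term_test <- function(query, term, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  q0 <- unique(query)
  t0 <- unique(term)
  q <- intersect(q0, universe)
  t <- intersect(t0, universe)
  ov <- sort(intersect(q, t))
  k <- length(ov)
  log_p <- stats::phyper(k - 1, length(t), N - length(t), length(q),
                         lower.tail = FALSE, log.p = TRUE)
  list(k = k, K = length(t), n = length(q), N = N,
       p = exp(log_p), log10_p = log_p / log(10), genes = ov,
       n_dropped = (length(q0) - length(q)) + (length(t0) - length(t)))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment of a query gene list
#'
#' Tests the query against every set of a collection with the
#' hypergeometric test and adjusts across terms with Benjamini-Hochberg.
#' Rows are ordered by p-value, ties broken by term name so results are
#' deterministic.
#'
#' @param query Character vector of gene ids.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all eligible genes. The recommended
#'   universe is the set of annotated genes with at least one tested
#'   variant in any analyzed region, matching the selection frame;
#'   enrichment results are sensitive to this choice.
#' @param fdr Report threshold on the q-value (default 0.05); all terms
#'   are returned, the `enriched` column flags `q <= fdr`.
#' @param min_set_size Skip sets with fewer in-universe members (default
#'   1).
#' @param max_terms Optional cap on the number of enriched terms kept for
#'   downstream reporting/clustering (`NULL` = no cap).
#' @return A `term_enrichment` data frame with columns `term`, `k`, `K`,
#'   `n`, `N`, `p`, `log10_p`, `q`, `enriched`, `genes`
#'   (comma-separated overlap).
#' @export
geneset_enrichment <- function(query, collection, universe, fdr = 0.05,
                               min_set_size = 1, max_terms = NULL) {
  if (length(collection) == 0) stop("empty gene-set collection")
  tests <- lapply(collection, term_test, query = query, universe = universe)
  keep <- vapply(tests, function(x) x$K >= min_set_size, logical(1))
  tests <- tests[keep]
  out <- data.frame(
    term = names(tests),
    k = vapply(tests, `[[`, numeric(1), "k"),
    K = vapply(tests, `[[`, numeric(1), "K"),
    n = vapply(tests, `[[`, numeric(1), "n"),
    N = vapply(tests, `[[`, numeric(1), "N"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    log10_p = vapply(tests, `[[`, numeric(1), "log10_p"),
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q <= fdr
  out$genes <- vapply(tests, function(x) paste(x$genes, collapse = ","),
                      character(1))
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (!is.null(max_terms) && sum(out$enriched) > max_terms) {
    drop_idx <- which(out$enriched)[-seq_len(max_terms)]
    out$enriched[drop_idx] <- FALSE
  }
  rownames(out) <- NULL
  class(out) <- c("term_enrichment", "data.frame")
  out
}

#' Jaccard distance between gene sets
#'
#' `1 - |A intersect B| / |A union B|`; 0 for identical sets, 1 for
#' disjoint sets.
#'
#' @param a,b Character vectors.
#' @return A single number in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Hierarchical clustering tree of enriched terms
#'
#' The distance between two enriched terms is the Jaccard distance of
#' their query-restricted member-gene sets (the genes shared with the
#' query), and the distance matrix is clustered agglomeratively
#' (average linkage by default). Terms are ordered by name before
#' clustering so the tree is reproducible regardless of input order.
#'
#' @param members Named list of character vectors: the query-overlap genes
#'   of each enriched term (at least 2 terms), or a `term_enrichment` data
#'   frame from which the enriched rows' `genes` columns are taken.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `phylo` (ape), writable with
#'   [ape::write.tree()]; `NULL` with a message when fewer than 2 terms
#'   are available.
#' @export
jaccard_tree <- function(members, linkage = "average") {
  if (inherits(members, "term_enrichment")) {
    en <- members[members$enriched, , drop = FALSE]
    members <- stats::setNames(strsplit(en$genes, ",", fixed = TRUE), en$term)
  }
  if (length(members) < 2) {
    message("fewer than 2 enriched terms; no tree built")
    return(NULL)
  }
  members <- members[order(names(members))]
  k <- length(members)
  d <- matrix(0, k, k, dimnames = list(names(members), names(members)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d[i, j] <- d[j, i] <- jaccard_distance(members[[i]], members[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ape::as.phylo(hc)
}
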