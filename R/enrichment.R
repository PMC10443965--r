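#' Upper hypergeometric tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least `k` members of a size-`K` set when drawing `n` features from a
#' universe of `N`.  Exact (log-space stable via [stats::phyper]).
#'
#' @param k observed overlap.
#' @param K set members in the universe.
#' @param n draw (cluster) size.
#' @param N universe size.
#' @return the over-representation p-value in (0, 1].
#' @examples
#' hypergeomTail(3, 4, 5, 10)  # 66/252
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(n, K)))
    stop("inconsistent hypergeometric counts (need k <= min(n, K) <= N)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Enrichment factor
#'
#' EF = (k/n) / (K/N): the overlap fraction within the cluster relative to
#' the set's background fraction in the universe.  EF = 1 means no
#' enrichment; EF > 1 over-representation.
#'
#' @inheritParams hypergeomTail
#' @return the enrichment factor (>= 0).
#' @export
enrichmentFactor <- function(k, K, n, N) {
  if (any(n == 0) || any(K == 0))
    stop("enrichment factor undefined for empty cluster or empty set")
  (k / n) / (K / N)
}

#' Hypergeometric over-representation of gene sets in clusters
#'
#' One exact hypergeometric test per (cluster, set) pair, after intersecting
#' both with the universe (by default: all features passing the detection
#' filter of the matching kind).  Sets disjoint from the universe are
#' skipped with a warning.  BH adjustment across the whole batch; rows
#' sorted by p-value.
#'
#' @param clusters a [ClusterResult-class] object, a named list of feature
#'   id vectors, or a named character vector of assignments (UNASSIGNED
#'   entries ignored).
#' @param sets a named list of gene-id vectors (gene sets), or a target-map
#'   data.frame (`mirna_id`, `gene_id`) whose per-miRNA target sets are
#'   tested.
#' @param universe character vector of background feature ids.
#' @return data.frame: `cluster`, `set`, `k`, `n`, `K`, `N`, `EF`,
#'   `pvalue`, `pval_adj`, sorted by `pvalue`.
#' @export
enrichClusters <- function(clusters, sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (is(clusters, "ClusterResult")) clusters <- clusterAssignments(clusters)
  if (is.character(clusters) && !is.null(names(clusters))) {
    clusters <- clusters[clusters != UNASSIGNED]
    clusters <- split(names(clusters), clusters)
  }
  if (is.data.frame(sets))
    sets <- split(as.character(sets$gene_id), as.character(sets$mirna_id))
  N <- length(universe)
  rows <- list()
  for (setName in names(sets)) {
    members <- intersect(unique(sets[[setName]]), universe)
    K <- length(members)
    if (K == 0) {
      warning("set '", setName, "' is disjoint from the universe; skipped")
      next
    }
    for (cid in names(clusters)) {
      cl <- intersect(unique(clusters[[cid]]), universe)
      n <- length(cl)
      if (n == 0) next
      k <- length(intersect(cl, members))
      rows[[paste(cid, setName)]] <- data.frame(
        cluster = cid, set = setName, k = k, n = n, K = K, N = N,
        EF = enrichmentFactor(k, K, n, N),
        pvalue = hypergeomTail(k, K, n, N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(0), set = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), EF = numeric(0), pvalue = numeric(0),
                      pval_adj = numeric(0)))
  out <- do.call(rbind, rows)
  out$pval_adj <- bhAdjust(out$pvalue)
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
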