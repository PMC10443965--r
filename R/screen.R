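#' Mean standardized profile of a miRNA's targets inside a cluster
#'
#' Averages the standardized 6-condition profiles of the miRNA's predicted
#' targets that fall inside the given cluster.  Requires at least
#' `minTargets` such targets; otherwise returns `NULL` (the candidate is
#' skipped by the screen).
#'
#' @param clusterFeatures feature ids of one cluster.
#' @param mirna miRNA id.
#' @param targetMap data.frame (`mirna_id`, `gene_id`).
#' @param profiles mRNA [ConditionProfiles-class].
#' @param minTargets minimal targets inside the cluster (default 5).
#' @return numeric length-6 profile, or `NULL` if too few targets.
#' @export
targetMeanProfile <- function(clusterFeatures, mirna, targetMap, profiles,
                              minTargets = 5L) {
  targets <- targetMap$gene_id[targetMap$mirna_id == mirna]
  z <- standardizedProfiles(profiles)
  inCluster <- intersect(intersect(targets, clusterFeatures), rownames(z))
  inCluster <- inCluster[!zeroVariance(profiles)[inCluster]]
  if (length(inCluster) < minTargets) return(NULL)
  colMeans(z[inCluster, , drop = FALSE])
}

#' Pearson anti-correlation between miRNA and target profiles
#'
#' Pearson correlation over the six (organ, timepoint) condition means.
#' Either vector being constant makes r undefined (`NA`); such candidates
#' are skipped by the screen.
#'
#' @param mirProfile length-6 miRNA profile.
#' @param targetProfile length-6 mean target profile.
#' @return Pearson r in \[-1, 1\], or `NA` for a constant input.
#' @export
antiCorrelation <- function(mirProfile, targetProfile) {
  if (length(mirProfile) != length(targetProfile))
    stop("profiles must have equal length")
  if (stats::sd(mirProfile) == 0 || stats::sd(targetProfile) == 0)
    return(NA_real_)
  stats::cor(mirProfile, targetProfile)
}

#' Screen differentially expressed miRNAs for candidate regulators
#'
#' The integration step: a miRNA is nominated when (i) its predicted
#' targets are significantly over-represented in a DEG cluster
#' (hypergeometric p < `pThresh`, raw) and (ii) its standardized
#' 6-condition expression profile is negatively correlated with the mean
#' standardized profile of those in-cluster targets (r < `rThresh`).  The
#' full (miRNA, cluster) table is returned, including failing pairs, for
#' transparency; `passes` marks the nominated candidates.
#'
#' @param deMirnas ids of differentially expressed miRNAs (only these are
#'   screened).
#' @param clusters a [ClusterResult-class], a list of them, or a named list
#'   of feature-id vectors (the DEG clusters).
#' @param targetMap data.frame (`mirna_id`, `gene_id`).
#' @param mrnaProfiles mRNA [ConditionProfiles-class].
#' @param mirnaProfiles miRNA [ConditionProfiles-class].
#' @param universe background gene ids for the enrichment test (typically
#'   the detection-filtered mRNA features).
#' @param pThresh raw enrichment p-value threshold (strict; default 0.01).
#' @param rThresh correlation threshold (strict; default -0.4).
#' @param minTargets minimal predicted targets inside the cluster for r to
#'   be computed (default 5).
#' @return data.frame sorted by (pvalue, r): `mirna`, `cluster`, `k`, `n`,
#'   `K`, `N`, `EF`, `pvalue`, `pval_adj`, `r`, `n_targets_in_cluster`,
#'   `passes`.
#' @export
screenRegulators <- function(deMirnas, clusters, targetMap, mrnaProfiles,
                             mirnaProfiles, universe,
                             pThresh = 0.01, rThresh = -0.4,
                             minTargets = 5L) {
  clusterList <- asClusterList(clusters)
  tm <- targetMap[targetMap$mirna_id %in% deMirnas, , drop = FALSE]
  zMir <- standardizedProfiles(mirnaProfiles)
  screenable <- intersect(deMirnas, unique(tm$mirna_id))
  screenable <- intersect(screenable, rownames(zMir))
  screenable <- screenable[!zeroVariance(mirnaProfiles)[screenable]]
  enr <- enrichClusters(clusterList,
                        tm[tm$mirna_id %in% screenable, , drop = FALSE],
                        universe)
  if (!nrow(enr))
    return(data.frame(mirna = character(0), cluster = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), EF = numeric(0), pvalue = numeric(0),
                      pval_adj = numeric(0), r = numeric(0),
                      n_targets_in_cluster = integer(0),
                      passes = logical(0)))
  out <- enr
  names(out)[names(out) == "set"] <- "mirna"
  out$r <- NA_real_
  out$n_targets_in_cluster <- out$k
  for (i in seq_len(nrow(out))) {
    tp <- targetMeanProfile(clusterList[[out$cluster[i]]], out$mirna[i],
                            tm, mrnaProfiles, minTargets)
    if (is.null(tp)) next
    out$r[i] <- antiCorrelation(zMir[out$mirna[i], ], tp)
  }
  out$passes <- !is.na(out$r) & out$pvalue < pThresh & out$r < rThresh
  out <- out[order(out$pvalue, out$r), , drop = FALSE]
  out <- out[, c("mirna", "cluster", "k", "n", "K", "N", "EF", "pvalue",
                 "pval_adj", "r", "n_targets_in_cluster", "passes")]
  rownames(out) <- NULL
  out
}

asClusterList <- function(clusters) {
  if (is(clusters, "ClusterResult")) clusters <- list(clusters)
  if (is.list(clusters) && length(clusters) &&
      all(vapply(clusters, is, TRUE, "ClusterResult"))) {
    out <- list()
    for (cr in clusters) {
      a <- clusterAssignments(cr)
      a <- a[a != UNASSIGNED]
      out <- c(out, split(names(a), a))
    }
    return(out)
  }
  clusters
}
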