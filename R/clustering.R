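#' Cluster standardized DEG profiles
#'
#' Partitions the standardized 6-condition profiles of one DEG direction
#' into homogeneous clusters: k-means (Euclidean on standardized rows,
#' multi-restart) for each k in `kRange`, k chosen by maximal mean
#' silhouette width; then a homogeneity post-pass moves features whose
#' Pearson correlation with their cluster mean falls below `homogeneity` to
#' `UNASSIGNED`, and clusters smaller than `minClusterSize` are dissolved to
#' `UNASSIGNED`.  Deterministic for a fixed `seed`.
#'
#' @param profiles a [ConditionProfiles-class] object.
#' @param features the DEG feature ids (of one direction) to cluster;
#'   zero-variance features are dropped with a message.
#' @param direction "up" or "down" tag carried into the result.
#' @param kRange candidate cluster counts (default 2:12, capped at n-1).
#' @param homogeneity minimal Pearson r of a member to its cluster mean
#'   (default 0.7).
#' @param minClusterSize smallest cluster kept (default 20).
#' @param nstart k-means restarts (default 10).
#' @param seed RNG seed for k-means.
#' @return a [ClusterResult-class] object; cluster ids are
#'   `"<direction>_<i>"` in decreasing size order.
#' @export
clusterProfiles <- function(profiles, features, direction = c("down", "up"),
                            kRange = 2:12, homogeneity = 0.7,
                            minClusterSize = 20L, nstart = 10L, seed = 1L) {
  direction <- match.arg(direction)
  features <- intersect(features, rownames(standardizedProfiles(profiles)))
  zv <- zeroVariance(profiles)[features]
  if (any(zv)) {
    message(sum(zv), " zero-variance feature(s) dropped before clustering")
    features <- features[!zv]
  }
  z <- standardizedProfiles(profiles)[features, , drop = FALSE]
  empty <- new("ClusterResult",
               assignments = stats::setNames(
                 rep(UNASSIGNED, length(features)), features),
               centers = matrix(numeric(0), 0, ncol(z),
                                dimnames = list(NULL,
                                                profiles@conditions)),
               labels = character(0), direction = direction,
               params = list(kRange = kRange, homogeneity = homogeneity,
                             minClusterSize = minClusterSize, seed = seed))
  if (length(features) < minClusterSize) {
    warning("fewer features than minClusterSize; all UNASSIGNED")
    return(empty)
  }
  uniq <- unique(as.data.frame(z))
  kMax <- min(max(kRange), nrow(uniq) )
  ks <- kRange[kRange <= min(kMax, nrow(z) - 1L)]
  if (nrow(uniq) == 1L || !length(ks)) {
    ## all profiles identical (or too few distinct): one cluster
    cl <- rep(1L, nrow(z))
    best <- list(cluster = cl, centers = matrix(colMeans(z), 1))
  } else {
    best <- NULL
    bestSil <- -Inf
    d <- stats::dist(z)
    for (k in ks) {
      set.seed(seed + k)
      km <- suppressWarnings(
        stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100))
      sil <- cluster::silhouette(km$cluster, d)
      msil <- mean(sil[, "sil_width"])
      if (msil > bestSil + 1e-12) {
        bestSil <- msil
        best <- km
      }
    }
  }
  assign <- best$cluster
  centers <- vapply(sort(unique(assign)), function(k) {
    colMeans(z[assign == k, , drop = FALSE])
  }, numeric(ncol(z)))
  centers <- t(centers)
  ## homogeneity post-pass
  r <- vapply(seq_len(nrow(z)), function(i) {
    suppressWarnings(stats::cor(z[i, ], centers[assign[i], ]))
  }, numeric(1))
  lab <- as.character(assign)
  lab[is.na(r) | r < homogeneity] <- UNASSIGNED
  ## dissolve small clusters
  sz <- table(lab[lab != UNASSIGNED])
  lab[lab %in% names(sz)[sz < minClusterSize]] <- UNASSIGNED
  kept <- names(sort(table(lab[lab != UNASSIGNED]), decreasing = TRUE))
  if (!length(kept)) {
    warning("no cluster survived the homogeneity/size post-pass")
    return(empty)
  }
  newId <- stats::setNames(sprintf("%s_%d", direction, seq_along(kept)), kept)
  assignments <- ifelse(lab == UNASSIGNED, UNASSIGNED, newId[lab])
  names(assignments) <- features
  ## recompute centers on surviving members
  centers <- t(vapply(unname(newId), function(cid) {
    colMeans(z[assignments == cid, , drop = FALSE])
  }, numeric(ncol(z))))
  rownames(centers) <- unname(newId)
  colnames(centers) <- profiles@conditions
  new("ClusterResult", assignments = assignments, centers = centers,
      labels = character(0), direction = direction,
      params = list(kRange = kRange, homogeneity = homogeneity,
                    minClusterSize = minClusterSize, seed = seed,
                    meanSilhouette = if (exists("bestSil")) bestSil else NA))
}

## organ-wise trend of a standardized 3-point trajectory:
## "transient" if the middle point is the strict extreme and departs from
## both ends by more than transientTol; "up"/"down" if the ends differ by
## more than flatTol; else "flat".
organTrend <- function(zOrg, flatTol = 0.5, transientTol = 1.0) {
  mid <- zOrg[2]
  if ((mid > max(zOrg[c(1, 3)]) + transientTol) ||
      (mid < min(zOrg[c(1, 3)]) - transientTol))
    return("transient")
  span <- zOrg[3] - zOrg[1]
  if (abs(span) <= flatTol) return("flat")
  rho <- suppressWarnings(stats::cor(zOrg, 1:3, method = "spearman"))
  if (!is.na(rho) && rho < 0 && span > 0) return("flat")  # non-monotone guard
  if (span > 0) "up" else "down"
}

#' Label clusters as shared / organ-specific / transient programs
#'
#' Rule-based tags from each cluster's mean standardized profile and mean
#' CPM level.  Per organ, the 3-point trajectory is classed as up, down,
#' flat or transient; the combination gives `shared-up/down` (same monotone
#' trend in both organs), `<organ>-specific-up/down` (trend in one organ,
#' flat in the other), `transient-<organ>`, `divergent` (opposite trends) or
#' `unlabeled`.  Shared programs whose absolute CPM level differs more than
#' twofold between organs gain a `-high-<organ>` qualifier.
#'
#' @param result a [ClusterResult-class] object.
#' @param profiles the [ConditionProfiles-class] the clusters were built on.
#' @param flatTol standardized end-to-end span below which an organ is flat.
#' @param transientTol standardized margin by which the middle timepoint
#'   must exceed both ends to call a transient.
#' @return `result` with the `labels` slot filled.
#' @export
labelClusters <- function(result, profiles, flatTol = 0.5,
                          transientTol = 1.0) {
  centers <- clusterCenters(result)
  if (!nrow(centers)) return(result)
  conds <- colnames(centers)
  organs <- unique(sub("_.*$", "", conds))
  assign <- clusterAssignments(result)
  labels <- character(nrow(centers))
  names(labels) <- rownames(centers)
  for (cid in rownames(centers)) {
    zc <- centers[cid, ]
    tr <- vapply(organs, function(og) {
      organTrend(zc[grep(paste0("^", og, "_"), conds)], flatTol,
                 transientTol)
    }, character(1))
    members <- names(assign)[assign == cid]
    mcpm <- meanCPM(profiles)[members, , drop = FALSE]
    lvl <- vapply(organs, function(og) {
      mean(log2(mcpm[, grep(paste0("^", og, "_"), conds), drop = FALSE] + 1))
    }, numeric(1))
    qual <- ""
    if (lvl[1] - lvl[2] > 1) qual <- paste0("-high-", organs[1])
    if (lvl[2] - lvl[1] > 1) qual <- paste0("-high-", organs[2])
    lab <- if (any(tr == "transient")) {
      tOrg <- organs[tr == "transient"]
      if (length(tOrg) == 2) "transient" else paste0("transient-", tOrg)
    } else if (all(tr %in% c("up", "down")) && tr[1] == tr[2]) {
      paste0("shared-", tr[1], qual)
    } else if (sum(tr == "flat") == 1 && any(tr %in% c("up", "down"))) {
      og <- organs[tr != "flat"]
      paste0(og, "-specific-", tr[tr != "flat"])
    } else if (all(tr %in% c("up", "down"))) {
      "divergent"
    } else {
      "unlabeled"
    }
    labels[cid] <- lab
  }
  result@labels <- labels
  result
}
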