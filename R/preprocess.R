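#' CPM transformation
#'
#' Adds a `"cpm"` assay: each count divided by its sample's total counts,
#' times 1e6.  A zero-sum sample is an error (it has no library to
#' normalize by).
#'
#' @param x a [DevCounts-class] object.
#' @return `x` with an added `"cpm"` assay.
#' @export
cpmTransform <- function(x) {
  cts <- SummarizedExperiment::assay(x, "counts")
  libs <- colSums(cts)
  if (any(libs == 0))
    stop("zero-sum sample(s): ",
         paste(colnames(cts)[libs == 0], collapse = ", "))
  cpm <- sweep(cts, 2, libs, "/") * 1e6
  SummarizedExperiment::assays(x)$cpm <- cpm
  x
}

cpmAssay <- function(x) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(x))
    x <- cpmTransform(x)
  SummarizedExperiment::assay(x, "cpm")
}

#' Detection filter
#'
#' A feature is retained iff in at least one (organ, timepoint) condition it
#' exceeds `minCPM` (strictly) in at least `minReplicates` replicates.
#' Defaults follow the mRNA convention (over 0.5 CPM in 3 replicates of any
#' time point); for miRNA use `minCPM = 1, minReplicates = 2`.
#'
#' @param x a [DevCounts-class] object (CPM computed on the fly if absent).
#' @param minCPM strict CPM threshold.
#' @param minReplicates replicates required above threshold within one
#'   condition.
#' @return character vector of retained feature ids.
#' @export
detectionFilter <- function(x, minCPM = 0.5, minReplicates = 3L) {
  cpm <- cpmAssay(x)
  cond <- conditionOf(x)
  if (max(table(cond)) < minReplicates)
    stop("minReplicates exceeds the replicates available in every condition")
  hit <- matrix(FALSE, nrow(cpm), nlevels(cond),
                dimnames = list(rownames(cpm), levels(cond)))
  for (cl in levels(cond)) {
    sub <- cpm[, cond == cl, drop = FALSE]
    hit[, cl] <- rowSums(sub > minCPM) >= minReplicates
  }
  kept <- rownames(cpm)[rowSums(hit) > 0]
  if (!length(kept)) warning("detection filter retained no features")
  kept
}

#' Condition mean and standardized profiles
#'
#' Averages CPM over replicates within each of the six (organ, timepoint)
#' conditions, then standardizes each feature's profile of
#' `log2(mean CPM + 1)` values to mean 0 and population SD 1 (the
#' conventional scale for expression-profile clustering; on the raw scale
#' the high-expression conditions would dominate every distance).  Features
#' whose condition means are all equal cannot be standardized; they are
#' flagged `zeroVariance` and their standardized rows set to `NA`.
#'
#' @param x a [DevCounts-class] object.
#' @param features feature ids to profile (default all).
#' @return a [ConditionProfiles-class] object.
#' @export
conditionProfiles <- function(x, features = rownames(x)) {
  cpm <- cpmAssay(x)
  bad <- setdiff(features, rownames(cpm))
  if (length(bad))
    stop("unknown feature(s): ", paste(utils::head(bad, 5), collapse = ", "))
  cpm <- cpm[features, , drop = FALSE]
  cond <- conditionOf(x)
  mu <- vapply(levels(cond), function(cl) {
    rowMeans(cpm[, cond == cl, drop = FALSE])
  }, numeric(length(features)))
  if (length(features) == 1L)
    mu <- matrix(mu, nrow = 1, dimnames = list(features, levels(cond)))
  lg <- log2(mu + 1)
  m <- rowMeans(lg)
  s2 <- rowMeans(lg^2) - m^2
  s <- sqrt(pmax(s2, 0))
  zv <- s <= 1e-12 * pmax(1, abs(m))
  z <- (lg - m) / ifelse(zv, NA_real_, s)
  z[zv, ] <- NA_real_
  new("ConditionProfiles", conditions = levels(cond), meanCPM = mu,
      standardized = z, zeroVariance = stats::setNames(zv, features))
}

#' PCA quality control
#'
#' PCA on centred, unscaled log2(CPM + 1) of the `nTop` most variable
#' features; used to check that samples separate by organ (expected PC1)
#' and developmental stage (expected PC2).
#'
#' @param x a [DevCounts-class] object.
#' @param nTop number of most-variable features used (default 500).
#' @return list with `varianceExplained` (fractions summing to 1), `scores`
#'   (samples x PCs, centred), and the sample `design` data.frame.
#' @export
pcaQC <- function(x, nTop = 500L) {
  if (ncol(x) < 2) stop("PCA needs at least 2 samples")
  expr <- log2(cpmAssay(x) + 1)
  v <- apply(expr, 1, stats::var)
  if (all(v == 0)) stop("all features have zero variance across samples")
  keep <- order(v, decreasing = TRUE)[seq_len(min(nTop, sum(v > 0)))]
  p <- stats::prcomp(t(expr[keep, , drop = FALSE]), center = TRUE,
                     scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(varianceExplained = ve, scores = p$x, design = designFrame(x))
}
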