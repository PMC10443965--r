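#' Median-of-ratios size factors
#'
#' Library-size normalization factors computed over the features with
#' all-positive counts: the per-sample median ratio to the feature-wise
#' geometric mean.
#'
#' @param counts integer matrix, features x samples.
#' @return numeric vector of size factors (one per sample).
#' @export
sizeFactors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has all-positive counts; size factors undefined")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(counts))
}

## Method-of-moments NB dispersion per feature, from normalized counts.
## Within each group: E[var] ~= m * mean(1/sf) + alpha * m^2; numerators and
## denominators pooled across groups with (n_g - 1) implicit weights.
momDispersion <- function(norm, group, sf, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in levels(group)) {
    sel <- group == g
    n <- sum(sel)
    if (n < 2) next
    sub <- norm[, sel, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (n - 1)
    cinv <- mean(1 / sf[sel])
    num <- num + (n - 1) * (v - m * cinv)
    den <- den + (n - 1) * m^2
  }
  alpha <- ifelse(den > 0, num / den, floor)
  pmax(alpha, floor)
}

## Vectorized NB GLM group-mean MLE (log link, fixed dispersion, size-factor
## offsets) by Newton iterations on b = log(mu).
nbGroupFit <- function(counts, sf, alpha) {
  n <- nrow(counts)
  m0 <- pmax(rowMeans(sweep(counts, 2, sf, "/")), 1e-8)
  b <- log(m0)
  for (it in 1:50) {
    mu <- outer(exp(b), sf)                    # features x samples
    denom <- 1 + alpha * mu
    U <- rowSums((counts - mu) / denom)
    I <- rowSums(mu / denom)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    b <- b + step
    b <- pmax(b, log(1e-3))                    # floor for all-zero groups
    if (max(abs(step)) < 1e-10) break
  }
  mu <- outer(exp(b), sf)
  I <- rowSums(mu / (1 + alpha * mu))
  list(b = b, varB = 1 / pmax(I, 1e-12))
}

#' Negative-binomial Wald test for one contrast
#'
#' Tests each feature for differential expression between one organ's later
#' timepoint and its T0/E16 baseline under an NB model with variance
#' `mu + alpha * mu^2`: size factors by median-of-ratios over the full
#' matrix, per-feature dispersion by method of moments on normalized counts
#' pooled over the replicate residuals of all six (organ, timepoint)
#' conditions (floored at 1e-8), group means by maximum likelihood with
#' size-factor offsets, and a two-sided Wald test of log2 fold change = 0.
#' The Wald statistic is referred to a t distribution whose degrees of
#' freedom are the residual degrees of freedom of the dispersion estimate
#' (samples minus conditions), acknowledging that the per-feature
#' dispersion comes from few replicates.
#'
#' Features with all-zero counts across both groups get `NA` statistics and
#' are excluded from downstream multiple-testing correction.
#'
#' @param x a [DevCounts-class] object.
#' @param organGroup organ level to test within.
#' @param tp later timepoint level (baseline is the first timepoint level).
#' @param features features to test (default all).
#' @return data.frame: `feature_id`, `organ`, `timepoint`, `baseMean`,
#'   `log2fc`, `se`, `stat`, `pvalue`.
#' @export
fitNBTest <- function(x, organGroup, tp, features = rownames(x)) {
  cts <- SummarizedExperiment::assay(x, "counts")[features, , drop = FALSE]
  baseTp <- levels(timepoint(x))[1]
  selA <- organ(x) == organGroup & timepoint(x) == baseTp
  selB <- organ(x) == organGroup & timepoint(x) == tp
  if (sum(selA) < 2 || sum(selB) < 2)
    stop("each group of the contrast needs >= 2 samples")
  sf <- sizeFactors(SummarizedExperiment::assay(x, "counts"))
  ## dispersion from the residuals of the full six-condition design
  cond <- droplevels(factor(conditionOf(x)))
  alpha <- momDispersion(sweep(cts, 2, sf, "/"), cond, sf)
  dfResid <- ncol(cts) - nlevels(cond)
  sel <- selA | selB
  sub <- cts[, sel, drop = FALSE]
  sfSub <- sf[sel]
  grp <- factor(ifelse(selB[sel], "later", "base"),
                levels = c("base", "later"))
  norm <- sweep(sub, 2, sfSub, "/")
  allZero <- rowSums(sub) == 0
  fitA <- nbGroupFit(sub[, grp == "base", drop = FALSE],
                     sfSub[grp == "base"], alpha)
  fitB <- nbGroupFit(sub[, grp == "later", drop = FALSE],
                     sfSub[grp == "later"], alpha)
  delta <- fitB$b - fitA$b
  se <- sqrt(fitA$varB + fitB$varB)
  stat <- delta / se
  p <- 2 * stats::pt(-abs(stat), df = max(dfResid, 2))
  out <- data.frame(
    feature_id = rownames(sub),
    organ = organGroup, timepoint = tp,
    baseMean = rowMeans(norm),
    log2fc = delta / log(2),
    se = se / log(2),
    stat = stat,
    pvalue = p,
    stringsAsFactors = FALSE
  )
  out$log2fc[allZero] <- NA_real_
  out$se[allZero] <- NA_real_
  out$stat[allZero] <- NA_real_
  out$pvalue[allZero] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement.  `NA` values pass
#' through and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Replicate direction-consistency filter
#'
#' A feature passes for a given (organ, later-timepoint) contrast iff every
#' replicate of the later timepoint deviates from the baseline-condition mean
#' CPM in the same direction, with no exact ties (a replicate equal to the
#' baseline mean has no direction and fails the feature).
#'
#' @param x a [DevCounts-class] object.
#' @param organGroup organ level.
#' @param tp later timepoint level.
#' @param features features to evaluate (default all).
#' @return named logical vector.
#' @export
consistencyFilter <- function(x, organGroup, tp, features = rownames(x)) {
  cpm <- cpmAssay(x)[features, , drop = FALSE]
  baseTp <- levels(timepoint(x))[1]
  selBase <- organ(x) == organGroup & timepoint(x) == baseTp
  selLater <- organ(x) == organGroup & timepoint(x) == tp
  baseMean <- rowMeans(cpm[, selBase, drop = FALSE])
  dev <- sign(cpm[, selLater, drop = FALSE] - baseMean)
  ok <- rowSums(dev == 1) == ncol(dev) | rowSums(dev == -1) == ncol(dev)
  stats::setNames(ok, features)
}

#' Differential-expression configuration
#'
#' @param alphaFdr FDR threshold (mRNA convention 0.01; miRNA 0.05).
#' @param fcMin fold-change threshold on the linear scale, must be > 1
#'   (mRNA 2.5; miRNA 1.5); the test requires `|log2fc| > log2(fcMin)`.
#' @return list of class `DEConfig`.
#' @export
deConfig <- function(alphaFdr = 0.01, fcMin = 2.5) {
  stopifnot(alphaFdr > 0, alphaFdr < 1, fcMin > 1)
  structure(list(alphaFdr = alphaFdr, fcMin = fcMin), class = "DEConfig")
}

#' mRNA-flavour and miRNA-flavour default DE thresholds
#' @rdname deConfig
#' @export
deConfigMirna <- function() deConfig(alphaFdr = 0.05, fcMin = 1.5)

#' Three-criterion DE call
#'
#' `TRUE` iff `fdr < alphaFdr`, `|log2fc| > log2(fcMin)` and the replicate
#' directions are consistent.  `NA` statistics (untestable features) give
#' `FALSE`.
#'
#' @param log2fc,fdr,consistent per-feature statistics.
#' @param config a [deConfig()] object.
#' @return logical vector.
#' @export
deCall <- function(log2fc, fdr, consistent, config = deConfig()) {
  !is.na(fdr) & !is.na(log2fc) & fdr < config$alphaFdr &
    abs(log2fc) > log2(config$fcMin) & consistent
}

#' Run all per-organ later-vs-baseline contrasts
#'
#' For each organ and each later timepoint (T1, T2) vs the T0 baseline:
#' NB Wald test, BH adjustment across the tested features within the
#' contrast, consistency filter, and the three-criterion DE call
#' `is_de = (fdr < alphaFdr) & (|log2fc| > log2(fcMin)) & consistent`.
#'
#' @param x a [DevCounts-class] object.
#' @param features features to test (typically the detection-filtered set).
#' @param config a [deConfig()] object.
#' @return data.frame of per-feature, per-contrast results with columns
#'   `feature_id, organ, timepoint, baseMean, log2fc, se, stat, pvalue, fdr,
#'   consistent, is_de, direction`.
#' @export
deAnalysis <- function(x, features = rownames(x), config = deConfig()) {
  organs <- levels(organ(x))
  tps <- levels(timepoint(x))[-1]
  res <- list()
  for (og in organs) {
    for (tp in tps) {
      r <- fitNBTest(x, og, tp, features)
      r$fdr <- bhAdjust(r$pvalue)
      r$consistent <- unname(consistencyFilter(x, og, tp, features))
      r$is_de <- deCall(r$log2fc, r$fdr, r$consistent, config)
      r$direction <- ifelse(r$is_de, ifelse(r$log2fc > 0, "up", "down"),
                            "none")
      res[[paste(og, tp)]] <- r
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize contrast-level results into per-feature DEG calls
#'
#' A feature is differentially expressed if it meets the three criteria in
#' any contrast of either organ (for miRNAs this is exactly the "either T1
#' or T2 vs baseline" rule).  Its direction for clustering is the direction
#' of its passing contrasts; if passing contrasts disagree, the direction of
#' the largest `|log2fc|` wins and the feature is flagged `conflicted`.
#'
#' @param results output of [deAnalysis()].
#' @return data.frame: `feature_id`, `is_de`, `direction`
#'   ("up"/"down"/"none"), `conflicted`, `max_abs_log2fc`, `min_fdr`.
#' @export
callDEGs <- function(results) {
  sp <- split(results, results$feature_id)
  rows <- lapply(sp, function(r) {
    de <- r[r$is_de, , drop = FALSE]
    if (!nrow(de)) {
      return(data.frame(feature_id = r$feature_id[1], is_de = FALSE,
                        direction = "none", conflicted = FALSE,
                        max_abs_log2fc = suppressWarnings(
                          max(abs(r$log2fc), na.rm = TRUE)),
                        min_fdr = suppressWarnings(min(r$fdr, na.rm = TRUE)),
                        stringsAsFactors = FALSE))
    }
    dirs <- unique(de$direction)
    conflicted <- length(dirs) > 1
    dir <- de$direction[which.max(abs(de$log2fc))]
    data.frame(feature_id = r$feature_id[1], is_de = TRUE, direction = dir,
               conflicted = conflicted,
               max_abs_log2fc = max(abs(de$log2fc)),
               min_fdr = min(de$fdr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$max_abs_log2fc[!is.finite(out$max_abs_log2fc)] <- NA_real_
  out$min_fdr[!is.finite(out$min_fdr)] <- NA_real_
  rownames(out) <- NULL
  out[order(out$feature_id), , drop = FALSE]
}
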