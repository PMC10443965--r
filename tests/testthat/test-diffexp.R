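test_that("BH adjustment matches the hand-computed step-up on small cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)            # single p unchanged
  p <- c(0.001, 0.5, 0.04, NA, 0.9)
  adj <- bhAdjust(p)
  expect_true(is.na(adj[4]))                  # NA passes through
  expect_equal(adj[-4], bhAdjust(p[-4]))      # and is excluded from m
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p[perm]), adj[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("consistency filter demands one nonzero direction for all reps", {
  mk <- function(laterCPM) {
    # library 1e8 so 1 CPM = 100 counts; baseline mean CPM = 10
    cts <- matrix(1000L, nrow = 1, ncol = 18, dimnames = list("g", NULL))
    cts[1, 4:6] <- as.integer(laterCPM * 100)  # A_T1 replicates
    toyCounts(cts, libSize = 1e8)
  }
  expect_false(consistencyFilter(mk(c(25, 30, 2)), "A", "T1")["g"])
  expect_true(consistencyFilter(mk(c(26, 31, 24)), "A", "T1")["g"])
  # a replicate exactly at the baseline mean has no direction
  expect_false(consistencyFilter(mk(c(26, 31, 10)), "A", "T1")["g"])
  # consistent DOWN also passes
  expect_true(consistencyFilter(mk(c(2, 3, 4)), "A", "T1")["g"])
})

test_that("identical groups give zero fold change and p of 1", {
  cts <- matrix(0L, nrow = 2, ncol = 18,
                dimnames = list(c("same", "bg"), NULL))
  cts["same", ] <- rep(c(500L, 510L, 490L), 6)
  cts["bg", ] <- 1000L
  x <- toyCounts(cts, libSize = 1e6)
  r <- fitNBTest(x, "A", "T1", c("same", "bg"))
  i <- r$feature_id == "same"
  expect_equal(r$log2fc[i], 0, tolerance = 1e-6)
  expect_equal(r$pvalue[i], 1, tolerance = 1e-6)
})

test_that("equal-size-factor fold change equals the group-mean log-ratio", {
  # with identical library sizes the NB group-mean MLE is the arithmetic
  # mean, so log2fc has a closed form independent of the dispersion
  d <- simulateDataset(smallSim(seed = 12, libsizeLogSd = 0))
  x <- d$mrna
  cts <- SummarizedExperiment::assay(x, "counts")
  keep <- rownames(cts)[rowSums(cts == 0) == 0]
  keep <- head(keep, 50)
  r <- fitNBTest(x, "A", "T2", keep)
  sf <- sizeFactors(cts)
  norm <- sweep(cts[keep, ], 2, sf, "/")
  selA <- organ(x) == "A" & timepoint(x) == "T0"
  selB <- organ(x) == "A" & timepoint(x) == "T2"
  expected <- log2(rowMeans(norm[, selB]) / rowMeans(norm[, selA]))
  # size factors estimated by median-of-ratios are near but not exactly
  # equal, so the MLE deviates from the plain mean ratio at the 4th decimal
  expect_equal(r$log2fc, unname(expected), tolerance = 5e-3)
})

test_that("Wald fit agrees with an independent NB GLM on the same model", {
  skip_if_not_installed("MASS")
  d <- simulateDataset(smallSim(seed = 13))
  x <- d$mrna
  cts <- SummarizedExperiment::assay(x, "counts")
  sf <- sizeFactors(cts)
  feats <- head(rownames(cts)[rowSums(cts == 0) == 0 &
                                rowMeans(cts) > 100], 25)
  r <- fitNBTest(x, "B", "T2", feats)
  sel <- organ(x) == "B" & timepoint(x) %in% c("T0", "T2")
  grp <- factor(as.character(timepoint(x))[sel], levels = c("T0", "T2"))
  lfcGlm <- vapply(feats, function(g) {
    y <- cts[g, sel]
    fit <- suppressWarnings(
      MASS::glm.nb(y ~ grp + offset(log(sf[sel]))))
    unname(stats::coef(fit)["grpT2"]) / log(2)
  }, numeric(1))
  expect_equal(r$log2fc, unname(lfcGlm), tolerance = 0.02)
})

test_that("swapping group labels negates log2fc and preserves p", {
  d <- simulateDataset(smallSim(seed = 14))
  x <- d$mrna
  r1 <- fitNBTest(x, "A", "T1")
  des <- designFrame2(x)
  swap <- des$organ == "A" & des$timepoint %in% c("T0", "T1")
  des$timepoint[swap] <- ifelse(des$timepoint[swap] == "T0", "T1", "T0")
  x2 <- DevCounts(SummarizedExperiment::assay(x, "counts"), des, "mRNA",
                  organs = c("A", "B"), timepoints = c("T0", "T1", "T2"))
  r2 <- fitNBTest(x2, "A", "T1")
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-6)
})

test_that("p-values are stable under a global doubling of counts", {
  d <- simulateDataset(smallSim(seed = 15))
  x <- d$mrna
  x2 <- DevCounts(SummarizedExperiment::assay(x, "counts") * 2L,
                  designFrame2(x), "mRNA",
                  organs = c("A", "B"), timepoints = c("T0", "T1", "T2"))
  r1 <- fitNBTest(x, "A", "T2")
  r2 <- fitNBTest(x2, "A", "T2")
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 0.05)
  ok <- !is.na(r1$pvalue) & r1$baseMean > 50
  expect_gt(stats::cor(log10(r1$pvalue[ok] + 1e-300),
                       log10(r2$pvalue[ok] + 1e-300)), 0.99)
})

test_that("the three DE criteria combine as specified", {
  cfg <- deConfig(alphaFdr = 0.01, fcMin = 2.5)
  # |log2fc| must exceed log2(2.5) ~ 1.3219
  expect_false(deCall(1.0, 0.001, TRUE, cfg))
  expect_true(deCall(2.0, 0.009, TRUE, cfg))
  expect_false(deCall(2.0, 0.011, TRUE, cfg))
  expect_false(deCall(2.0, 0.009, FALSE, cfg))
  expect_false(deCall(NA, 0.001, TRUE, cfg))
  expect_true(deCall(-2.0, 0.009, TRUE, cfg))  # direction-symmetric
})

test_that("DEG calls shrink as thresholds tighten", {
  d <- simulateDataset(smallSim(seed = 16))
  loose <- callDEGs(deAnalysis(d$mrna, config = deConfig(0.05, 1.5)))
  tight <- callDEGs(deAnalysis(d$mrna, config = deConfig(0.01, 2.5)))
  expect_true(all(tight$feature_id[tight$is_de] %in%
                    loose$feature_id[loose$is_de]))
})

test_that("conflicting directions resolve to the larger effect and flag", {
  res <- data.frame(
    feature_id = "g", organ = c("A", "B"), timepoint = "T2",
    baseMean = 10, log2fc = c(2, -3), se = 0.1, stat = 1,
    pvalue = 1e-5, fdr = 1e-4, consistent = TRUE, is_de = TRUE,
    direction = c("up", "down"))
  call <- callDEGs(res)
  expect_true(call$conflicted)
  expect_equal(call$direction, "down")
})
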