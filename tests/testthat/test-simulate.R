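test_that("simulation is byte-identical under a fixed seed", {
  d1 <- simulateDataset(smallSim(seed = 11))
  d2 <- simulateDataset(smallSim(seed = 11))
  expect_identical(SummarizedExperiment::assay(d1$mrna, "counts"),
                   SummarizedExperiment::assay(d2$mrna, "counts"))
  expect_identical(SummarizedExperiment::assay(d1$mirna, "counts"),
                   SummarizedExperiment::assay(d2$mirna, "counts"))
  expect_identical(d1$targetMap, d2$targetMap)
  expect_identical(d1$truth, d2$truth)
})

test_that("mRNA draws do not depend on the miRNA side of the config", {
  d1 <- simulateDataset(smallSim(seed = 3))
  d2 <- simulateDataset(smallSim(seed = 3, nMirnas = 90))
  expect_identical(SummarizedExperiment::assay(d1$mrna, "counts"),
                   SummarizedExperiment::assay(d2$mrna, "counts"))
})

test_that("noise-free limit collapses counts to rounded expected means", {
  d <- simulateDataset(smallSim(seed = 5, nbDispersion = 0,
                                libsizeLogSd = 0))
  cts <- SummarizedExperiment::assay(d$mrna, "counts")
  cond <- conditionOf(d$mrna)
  # replicates within a condition are exact copies of the expected mean
  for (cl in levels(cond)) {
    sub <- cts[, cond == cl, drop = FALSE]
    expect_true(all(sub == sub[, 1]))
  }
  # and rerunning gives the identical deterministic matrix
  d2 <- simulateDataset(smallSim(seed = 5, nbDispersion = 0,
                                 libsizeLogSd = 0))
  expect_identical(cts, SummarizedExperiment::assay(d2$mrna, "counts"))
})

test_that("column sums track the drawn library sizes within 5%", {
  # stated at the generator's default problem size
  for (s in 1:3) {
    d <- simulateDataset(simConfig(seed = 20 + s))
    libs <- d$truth$librarySizes$mrna
    cs <- colSums(SummarizedExperiment::assay(d$mrna, "counts"))
    expect_lt(max(abs(cs - libs) / libs), 0.05)
  }
})

test_that("planted archetype profiles are recovered from member means", {
  d <- simulateDataset(simConfig(seed = 7))
  prof <- conditionProfiles(cpmTransform(d$mrna))
  z <- standardizedProfiles(prof)
  arch <- d$truth$geneArchetype
  for (a in names(defaultArchetypes())) {
    members <- names(arch)[arch == a]
    rec <- colMeans(z[members, , drop = FALSE])
    ref <- defaultArchetypes()[[a]]
    ref <- (ref - mean(ref)) / sqrt(mean((ref - mean(ref))^2))
    cosine <- sum(rec * ref) / sqrt(sum(rec^2) * sum(ref^2))
    expect_gt(cosine, 0.95)
  }
})

test_that("planted regulators anti-correlate strongly with their targets", {
  for (s in 1:4) {
    d <- simulateDataset(simConfig(seed = 30 + s))
    gp <- conditionProfiles(cpmTransform(d$mrna))
    mp <- conditionProfiles(cpmTransform(d$mirna))
    zG <- standardizedProfiles(gp)
    zM <- standardizedProfiles(mp)
    r <- vapply(d$truth$regulatorIds, function(m) {
      tgt <- colMeans(zG[d$truth$trueTargets[[m]], , drop = FALSE])
      stats::cor(zM[m, ], tgt)
    }, numeric(1))
    expect_true(all(r < -0.8))
  }
})

test_that("decoupled (coupling 0) regulators behave like decoy miRNAs", {
  rReg <- c(); rDecoy <- c()
  for (s in 1:6) {
    d <- simulateDataset(smallSim(seed = 40 + s, couplingStrength = 0))
    gp <- conditionProfiles(cpmTransform(d$mrna))
    mp <- conditionProfiles(cpmTransform(d$mirna))
    zG <- standardizedProfiles(gp)
    zM <- standardizedProfiles(mp)
    tm <- d$targetMap
    corTo <- function(m) {
      tg <- intersect(tm$gene_id[tm$mirna_id == m], rownames(zG))
      tg <- tg[!zeroVariance(gp)[tg]]
      if (length(tg) < 3 || zeroVariance(mp)[m]) return(NA_real_)
      stats::cor(zM[m, ], colMeans(zG[tg, , drop = FALSE]))
    }
    regs <- d$truth$regulatorIds
    decoys <- setdiff(unique(tm$mirna_id), regs)
    rReg <- c(rReg, vapply(regs, corTo, numeric(1)))
    rDecoy <- c(rDecoy, vapply(decoys, corTo, numeric(1)))
  }
  ks <- suppressWarnings(
    stats::ks.test(abs(rReg[!is.na(rReg)]), abs(rDecoy[!is.na(rDecoy)])))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nRegulators = 10, nMirnas = 5), "nRegulators")
  expect_error(simConfig(targetsPerRegulator = 200, genesPerArchetype = 100),
               "exceeds the genes assigned")
  expect_error(simConfig(nbDispersion = -1), "nbDispersion")
  expect_error(simConfig(nRegulators = 2, archetypes = list()),
               "archetype")
})

test_that("fixture writing emits six files that round-trip", {
  d <- simulateDataset(smallSim(seed = 2))
  dir <- withr::local_tempdir()
  paths <- writeFixture(d, dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  back <- readFixture(dir)
  expect_identical(SummarizedExperiment::assay(back$mrna, "counts"),
                   SummarizedExperiment::assay(d$mrna, "counts"))
  expect_identical(SummarizedExperiment::assay(back$mirna, "counts"),
                   SummarizedExperiment::assay(d$mirna, "counts"))
  expect_setequal(
    paste(back$targetMap$mirna_id, back$targetMap$gene_id),
    paste(d$targetMap$mirna_id, d$targetMap$gene_id))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$regulatorIds, smallSim()$nRegulators)
  # row counts match the config
  cts <- utils::read.table(paths["mrna_counts"], sep = "\t", header = TRUE)
  expect_equal(nrow(cts), smallSim()$nGenes)
})
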