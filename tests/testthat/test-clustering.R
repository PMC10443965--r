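test_that("two noise-free archetypes are recovered exactly", {
  arch <- defaultArchetypes()[c("shared-down", "shared-up")]
  d <- simulateDataset(smallSim(seed = 1, archetypes = arch,
                                nRegulators = 2, nbDispersion = 0,
                                libsizeLogSd = 0))
  pr <- conditionProfiles(cpmTransform(d$mrna))
  truth <- d$truth$geneArchetype
  planted <- names(truth)[truth != "flat"]
  cr <- clusterProfiles(pr, planted, "down", minClusterSize = 10, seed = 1)
  a <- clusterAssignments(cr)
  expect_equal(nrow(clusterCenters(cr)), 2)
  expect_false(any(a == "UNASSIGNED"))
  expect_equal(mclust::adjustedRandIndex(unname(a), unname(truth[planted])),
               1)
})

test_that("all-identical profiles collapse to a single cluster", {
  z <- matrix(rep(c(1, 0.5, 0, 1, 0.5, 0), 30), ncol = 6, byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  pr <- profilesFromMeans(z)
  cr <- clusterProfiles(pr, rownames(z), "down", minClusterSize = 5,
                        seed = 1)
  expect_equal(nrow(clusterCenters(cr)), 1)
  expect_true(all(clusterAssignments(cr) != "UNASSIGNED"))
})

test_that("too few features yields a warned all-UNASSIGNED result", {
  set.seed(1)
  z <- matrix(stats::runif(5 * 6, 10, 1000), ncol = 6,
              dimnames = list(paste0("g", 1:5), NULL))
  pr <- profilesFromMeans(z)
  expect_warning(cr <- clusterProfiles(pr, rownames(z), "up",
                                       minClusterSize = 20, seed = 1),
                 "UNASSIGNED")
  expect_true(all(clusterAssignments(cr) == "UNASSIGNED"))
})

test_that("assigned plus unassigned features account for every input", {
  d <- simulateDataset(smallSim(seed = 3))
  pr <- conditionProfiles(cpmTransform(d$mrna))
  truth <- d$truth$geneArchetype
  feats <- names(truth)[truth %in% c("shared-down", "shared-down-high-A")]
  cr <- clusterProfiles(pr, feats, "down", minClusterSize = 10, seed = 1)
  a <- clusterAssignments(cr)
  expect_setequal(names(a), feats)
  sz <- table(a)
  expect_equal(sum(sz), length(feats))
})

test_that("clustering is invariant to feature order", {
  d <- simulateDataset(smallSim(seed = 5))
  pr <- conditionProfiles(cpmTransform(d$mrna))
  truth <- d$truth$geneArchetype
  feats <- names(truth)[truth %in% c("shared-up", "A-specific-up",
                                     "B-specific-up", "transient-A")]
  cr1 <- clusterProfiles(pr, feats, "up", minClusterSize = 10, seed = 2)
  set.seed(99)
  cr2 <- clusterProfiles(pr, sample(feats), "up", minClusterSize = 10,
                         seed = 2)
  a1 <- clusterAssignments(cr1)
  a2 <- clusterAssignments(cr2)[names(a1)]
  keep <- a1 != "UNASSIGNED" & a2 != "UNASSIGNED"
  expect_equal(mclust::adjustedRandIndex(a1[keep], a2[keep]), 1)
})

test_that("every assigned member meets the homogeneity bound", {
  d <- simulateDataset(smallSim(seed = 6))
  pr <- conditionProfiles(cpmTransform(d$mrna))
  truth <- d$truth$geneArchetype
  feats <- names(truth)[truth != "flat"]
  cr <- clusterProfiles(pr, feats, "up", homogeneity = 0.7,
                        minClusterSize = 10, seed = 1)
  a <- clusterAssignments(cr)
  z <- standardizedProfiles(pr)
  for (cid in rownames(clusterCenters(cr))) {
    members <- names(a)[a == cid]
    r <- apply(z[members, , drop = FALSE], 1, stats::cor,
               clusterCenters(cr)[cid, ])
    expect_true(all(r >= 0.7))
  }
})

test_that("label rules tag constructed mean profiles correctly", {
  mkResult <- function(zc, mcpmA = 100, mcpmB = 100) {
    members <- sprintf("g%02d", 1:25)
    mu <- matrix(rep(c(rep(mcpmA, 3), rep(mcpmB, 3)), 25), ncol = 6,
                 byrow = TRUE, dimnames = list(members, NULL))
    mu <- mu * 2^matrix(rep(zc, 25), ncol = 6, byrow = TRUE)
    pr <- profilesFromMeans(mu)
    cr <- new("ClusterResult",
              assignments = stats::setNames(rep("c1", 25), members),
              centers = matrix(zc, 1, 6,
                               dimnames = list("c1", pr@conditions)),
              labels = character(0), direction = "down", params = list())
    clusterLabels(labelClusters(cr, pr))[["c1"]]
  }
  expect_equal(mkResult(c(1, 0, -1, 1, 0, -1)), "shared-down")
  expect_equal(mkResult(c(1, 0, -1, 1, 0, -1), mcpmA = 800, mcpmB = 100),
               "shared-down-high-A")
  expect_equal(mkResult(c(1, 0, -1, 0.1, 0, -0.1)), "A-specific-down")
  expect_equal(mkResult(c(-0.5, 2, -0.5, 0, 0.1, -0.1)), "transient-A")
  expect_equal(mkResult(c(1, 0, -1, -1, 0, 1)), "divergent")
})

test_that("the planted transient archetype is tagged transient on fixtures", {
  hits <- 0
  for (s in 1:5) {
    d <- simulateDataset(smallSim(seed = 60 + s))
    pr <- conditionProfiles(cpmTransform(d$mrna))
    truth <- d$truth$geneArchetype
    feats <- names(truth)[truth %in% c("shared-up", "A-specific-up",
                                       "B-specific-up", "transient-A")]
    cr <- labelClusters(clusterProfiles(pr, feats, "up",
                                        minClusterSize = 10, seed = 1), pr)
    hits <- hits + any(grepl("^transient", clusterLabels(cr)))
  }
  expect_gte(hits, 4)
})
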