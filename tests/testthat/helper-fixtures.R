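# Shared fixtures, all built in code.

# a reduced-size simulation config for fast module tests
smallSim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nGenes = 400, nMirnas = 60, genesPerArchetype = 40,
         nRegulators = 6, targetsPerRegulator = 25,
         decoyTargetsPerMirna = 10),
    list(...))
  args$seed <- seed
  do.call(simConfig, args)
}

# a DevCounts with hand-picked counts; equal column sums unless padded off,
# so CPM is proportional to counts (pad feature absorbs the remainder)
toyCounts <- function(counts, libSize = 1e6, nrep = 3,
                      featureKind = "mRNA") {
  counts <- as.matrix(counts)
  nS <- ncol(counts)
  stopifnot(nS == 6 * nrep)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  pad <- libSize - colSums(counts)
  stopifnot(all(pad >= 0))
  m <- rbind(counts, pad = pad)
  colnames(m) <- sprintf("s%02d", seq_len(nS))
  design <- data.frame(
    sample_id = colnames(m),
    organ = rep(c("A", "B"), each = 3 * nrep),
    timepoint = rep(rep(c("T0", "T1", "T2"), each = nrep), 2),
    replicate = rep(seq_len(nrep), 6))
  DevCounts(m, design, featureKind,
            organs = c("A", "B"), timepoints = c("T0", "T1", "T2"))
}

# ConditionProfiles built directly from a matrix of condition mean CPM;
# standardization mirrors the class contract (log2(CPM + 1), mean 0, SD 1)
profilesFromMeans <- function(mu) {
  conds <- c("A_T0", "A_T1", "A_T2", "B_T0", "B_T1", "B_T2")
  colnames(mu) <- conds
  lg <- log2(mu + 1)
  m <- rowMeans(lg)
  s <- sqrt(pmax(rowMeans(lg^2) - m^2, 0))
  zv <- s <= 1e-12 * pmax(1, abs(m))
  z <- (lg - m) / ifelse(zv, NA_real_, s)
  z[zv, ] <- NA_real_
  new("ConditionProfiles", conditions = conds, meanCPM = mu,
      standardized = z, zeroVariance = stats::setNames(zv, rownames(mu)))
}

# sample sheet data.frame of a DevCounts object
designFrame2 <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = cd$sample_id, organ = as.character(cd$organ),
             timepoint = as.character(cd$timepoint),
             replicate = cd$replicate, stringsAsFactors = FALSE)
}

# combined named assignment vector over a list of ClusterResults
combinedAssignments <- function(clusterResults) {
  a <- character(0)
  for (cr in clusterResults) {
    x <- clusterAssignments(cr)
    x <- x[x != "UNASSIGNED"]
    a[names(x)] <- unname(x)
  }
  a
}
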