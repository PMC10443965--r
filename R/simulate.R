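#' Default profile archetypes
#'
#' Six mean log2 profile shapes over the six (organ, timepoint) conditions in
#' fixed order (A_T0, A_T1, A_T2, B_T0, B_T1, B_T2).  They emulate the
#' canonical developmental programs seen in paired-organ time courses:
#' expression repressed in both organs (with equal or organ-biased absolute
#' levels), induced in both, induced in one organ only, or transiently
#' induced at the middle timepoint.
#'
#' @return named list of numeric length-6 log2 profiles.
#' @export
defaultArchetypes <- function() {
  list(
    "shared-down"        = c(3, 1.5, 0,    3, 1.5, 0),
    "shared-down-high-A" = c(3, 2.5, 2,    1, -0.5, -2),
    "shared-up"          = c(0, 1.5, 3,    0, 1.5, 3),
    "A-specific-up"      = c(0, 1.5, 3,    0, 0, 0),
    "B-specific-up"      = c(0, 0, 0,      0, 1.5, 3),
    "transient-A"        = c(0, 3, 0,      0, 0, 0)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic paired mRNA/miRNA dataset generator.
#' Defaults reflect a desk-scale version of a two-organ, three-timepoint
#' developmental design probed with 3 replicates per condition, negative
#' binomial count noise (variance mu + alpha mu^2) and log-normal library
#' sizes around 5e6 (mRNA) / 1e6 (miRNA) reads.
#'
#' @param nGenes number of mRNA features.
#' @param nMirnas number of miRNA features.
#' @param nReplicates replicates per (organ, timepoint) condition.
#' @param archetypes named list of length-6 log2 profiles; genes not assigned
#'   to an archetype are flat.  May be empty (all genes flat).
#' @param genesPerArchetype genes planted per archetype.
#' @param nRegulators planted repressor miRNAs (each coupled to one archetype,
#'   cycling through `archetypes`).
#' @param targetsPerRegulator true targets per regulator, drawn from the
#'   coupled archetype's genes.
#' @param decoyTargetsPerMirna predicted-target decoys per miRNA, drawn
#'   uniformly from non-target genes (emulates target-prediction false
#'   positives).
#' @param couplingStrength log2-scale amplitude of a regulator miRNA's
#'   sign-flipped (anti-correlated) profile; 0 decouples regulators entirely.
#' @param nbDispersion NB dispersion alpha (>= 0); 0 gives Poisson noise, and
#'   together with `libsizeLogSd = 0` a fully deterministic noise-free limit.
#' @param libsizeLogSd sdlog of the log-normal library-size draw.
#' @param mrnaLibSize,mirnaLibSize median library sizes.
#' @param seed master seed; independent substreams are derived at fixed
#'   offsets so e.g. adding miRNAs never perturbs the mRNA draws.
#' @return object of class `SimConfig` (a validated list).
#' @export
simConfig <- function(nGenes = 2000L, nMirnas = 300L, nReplicates = 3L,
                      archetypes = defaultArchetypes(),
                      genesPerArchetype = 150L,
                      nRegulators = 6L, targetsPerRegulator = 100L,
                      decoyTargetsPerMirna = 50L,
                      couplingStrength = 1.5, nbDispersion = 0.1,
                      libsizeLogSd = 0.3,
                      mrnaLibSize = 5e6, mirnaLibSize = 1e6,
                      seed = 1L) {
  cfg <- list(
    nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
    nReplicates = as.integer(nReplicates),
    organs = c("A", "B"), timepoints = c("T0", "T1", "T2"),
    archetypes = archetypes,
    genesPerArchetype = as.integer(genesPerArchetype),
    nRegulators = as.integer(nRegulators),
    targetsPerRegulator = as.integer(targetsPerRegulator),
    decoyTargetsPerMirna = as.integer(decoyTargetsPerMirna),
    couplingStrength = couplingStrength,
    nbDispersion = nbDispersion, libsizeLogSd = libsizeLogSd,
    mrnaLibSize = mrnaLibSize, mirnaLibSize = mirnaLibSize,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(cfg$nGenes > 0, cfg$nMirnas > 0, cfg$nReplicates > 0,
            cfg$genesPerArchetype > 0)
  if (cfg$nRegulators > cfg$nMirnas)
    stop("nRegulators must not exceed nMirnas")
  if (cfg$targetsPerRegulator > cfg$nGenes)
    stop("targetsPerRegulator must not exceed nGenes")
  if (cfg$nbDispersion < 0) stop("nbDispersion must be >= 0")
  if (cfg$libsizeLogSd < 0) stop("libsizeLogSd must be >= 0")
  if (cfg$nRegulators > 0 && length(cfg$archetypes) == 0)
    stop("regulators require at least one archetype to couple to")
  if (cfg$nRegulators > 0 && cfg$targetsPerRegulator > cfg$genesPerArchetype)
    stop("targetsPerRegulator exceeds the genes assigned to each archetype")
  if (length(cfg$archetypes)) {
    if (any(vapply(cfg$archetypes, length, 1L) != 6L))
      stop("every archetype profile must have length 6")
    if (length(cfg$archetypes) * cfg$genesPerArchetype > cfg$nGenes)
      stop("archetype genes exceed nGenes")
  }
  invisible(cfg)
}

# population-SD standardization of a length-6 profile
standardizeVec <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) return(rep(NA_real_, length(v)))
  (v - m) / s
}

## CPM is compositional: if the planted profiles shift the total abundance
## of a condition, every feature's relative profile is distorted by the
## per-condition total.  Rebalance by scaling the flat features so each
## condition carries the same total relative abundance; planted features
## then show their archetype shape exactly on the CPM scale, while flat
## features absorb a small common factor.
balanceComposition <- function(log2rel, flatIdx) {
  if (!any(flatIdx) || all(flatIdx)) return(log2rel)
  rel <- 2^log2rel
  S <- colSums(rel)
  target <- exp(mean(log(S)))
  planted <- colSums(rel[!flatIdx, , drop = FALSE])
  f <- (target - planted) / colSums(rel[flatIdx, , drop = FALSE])
  if (any(f <= 0)) return(log2rel)  # planted mass dominates; leave as is
  rel[flatIdx, ] <- sweep(rel[flatIdx, , drop = FALSE], 2, f, "*")
  log2(rel)
}

# draw one count matrix given per-feature log2 relative condition profiles
simCountMatrix <- function(log2rel, libMedian, cfg, prefix) {
  organs <- cfg$organs
  tps <- cfg$timepoints
  nrep <- cfg$nReplicates
  conds <- conditionLevels(organs, tps)
  design <- expand.grid(replicate = seq_len(nrep), timepoint = tps,
                        organ = organs, stringsAsFactors = FALSE)
  design <- design[, c("organ", "timepoint", "replicate")]
  design$sample_id <- sprintf("%s_%s_%s_r%d", prefix, design$organ,
                              design$timepoint, design$replicate)
  condOfSample <- paste(design$organ, design$timepoint, sep = "_")
  libs <- stats::rlnorm(nrow(design), meanlog = log(libMedian),
                        sdlog = cfg$libsizeLogSd)
  rel <- 2^log2rel                              # features x 6
  prop <- sweep(rel, 2, colSums(rel), "/")      # per-condition proportions
  mu <- prop[, match(condOfSample, conds), drop = FALSE]
  mu <- sweep(mu, 2, libs, "*")
  nf <- cfg$nbDispersion == 0 && cfg$libsizeLogSd == 0
  if (nf) {
    cts <- round(mu)
  } else if (cfg$nbDispersion == 0) {
    cts <- matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
  } else {
    cts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / cfg$nbDispersion),
                  nrow = nrow(mu))
  }
  storage.mode(cts) <- "integer"
  dimnames(cts) <- list(rownames(log2rel), design$sample_id)
  names(libs) <- design$sample_id
  list(counts = cts, design = design, libs = libs)
}

#' Simulate a paired mRNA/miRNA developmental dataset
#'
#' Generates mRNA and miRNA count matrices over a 2-organ x 3-timepoint
#' replicated design, a predicted-target map, a small "deafness-like" gene
#' set enriched in one shared archetype, and full ground-truth labels.
#'
#' Genes planted in an archetype follow its (mean-centred) log2 profile on
#' top of a gene-specific baseline abundance; the rest are flat.  Each
#' planted regulator miRNA carries the sign-flipped standardized profile of
#' its coupled archetype scaled by `couplingStrength` (plus mild profile
#' noise), so its expression anti-correlates with its targets' mean profile.
#' A fifth of the non-regulator miRNAs carry a random archetype profile
#' (same sign, unit amplitude) and act as realistic differentially expressed
#' distractors; the rest are flat.  Counts are NB(mu, alpha) with
#' library-size-scaled means.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `mrna` and `mirna` ([DevCounts-class]),
#'   `targetMap` (data.frame `mirna_id`, `gene_id`), `geneSets` (named list),
#'   and `truth` (list: `geneArchetype`, `regulatorIds`, `trueTargets`,
#'   `regulatorArchetype`, `librarySizes`).
#' @examples
#' d <- simulateDataset(simConfig(nGenes = 200, nMirnas = 30,
#'                                genesPerArchetype = 20,
#'                                targetsPerRegulator = 15, seed = 7))
#' d$mrna
#' @export
simulateDataset <- function(cfg = simConfig()) {
  validateSimConfig(cfg)
  archNames <- names(cfg$archetypes)
  nArch <- length(cfg$archetypes)
  geneIds <- sprintf("gene%04d", seq_len(cfg$nGenes))
  mirIds <- sprintf("mir%03d", seq_len(cfg$nMirnas))

  ## stream 1: structural assignments
  set.seed(cfg$seed + 1L)
  geneArch <- rep("flat", cfg$nGenes)
  if (nArch > 0) {
    planted <- sample(geneIds, nArch * cfg$genesPerArchetype)
    geneArch[match(planted, geneIds)] <-
      rep(archNames, each = cfg$genesPerArchetype)
  }
  names(geneArch) <- geneIds
  baseGene <- ifelse(geneArch == "flat",
                     stats::rnorm(cfg$nGenes, 4, 2),
                     stats::rnorm(cfg$nGenes, 4.5, 1))
  log2relGene <- matrix(rep(baseGene, 6), ncol = 6,
                        dimnames = list(geneIds, NULL))
  for (a in archNames) {
    idx <- which(geneArch == a)
    prof <- cfg$archetypes[[a]]
    log2relGene[idx, ] <- log2relGene[idx, ] +
      matrix(prof - mean(prof), nrow = length(idx), ncol = 6, byrow = TRUE)
  }

  regulatorIds <- character(0)
  regArch <- character(0)
  trueTargets <- list()
  if (cfg$nRegulators > 0) {
    regulatorIds <- sample(mirIds, cfg$nRegulators)
    regArch <- archNames[((seq_len(cfg$nRegulators) - 1L) %% nArch) + 1L]
    names(regArch) <- regulatorIds
    for (i in seq_along(regulatorIds)) {
      members <- geneIds[geneArch == regArch[i]]
      trueTargets[[regulatorIds[i]]] <-
        sample(members, cfg$targetsPerRegulator)
    }
  }
  nonReg <- setdiff(mirIds, regulatorIds)
  mirArch <- rep("flat", length(nonReg))
  if (nArch > 0 && length(nonReg)) {
    nDistract <- floor(length(nonReg) / 5)
    if (nDistract > 0)
      mirArch[sample(length(nonReg), nDistract)] <-
        sample(archNames, nDistract, replace = TRUE)
  }
  names(mirArch) <- nonReg
  baseMir <- stats::rnorm(cfg$nMirnas, 6, 1.5)
  names(baseMir) <- mirIds

  ## stream 2: mRNA matrix
  set.seed(cfg$seed + 2L)
  log2relGene <- balanceComposition(log2relGene, geneArch == "flat")
  simG <- simCountMatrix(log2relGene, cfg$mrnaLibSize, cfg, "rna")
  mrna <- DevCounts(simG$counts, simG$design, "mRNA",
                    organs = cfg$organs, timepoints = cfg$timepoints)

  ## stream 3: miRNA matrix
  set.seed(cfg$seed + 3L)
  log2relMir <- matrix(rep(baseMir, 6), ncol = 6,
                       dimnames = list(mirIds, NULL))
  for (m in regulatorIds) {
    z <- standardizeVec(cfg$archetypes[[regArch[m]]])
    log2relMir[m, ] <- log2relMir[m, ] - cfg$couplingStrength * z +
      stats::rnorm(6, 0, 0.15)
  }
  for (m in nonReg[mirArch[nonReg] != "flat"]) {
    z <- standardizeVec(cfg$archetypes[[mirArch[m]]])
    log2relMir[m, ] <- log2relMir[m, ] + z + stats::rnorm(6, 0, 0.15)
  }
  flatMir <- !(mirIds %in% regulatorIds) &
    mirArch[match(mirIds, names(mirArch))] %in% c("flat", NA)
  flatMir[is.na(flatMir)] <- FALSE
  log2relMir <- balanceComposition(log2relMir, flatMir)
  simM <- simCountMatrix(log2relMir, cfg$mirnaLibSize, cfg, "mir")
  mirna <- DevCounts(simM$counts, simM$design, "miRNA",
                     organs = cfg$organs, timepoints = cfg$timepoints)

  ## stream 4: target map (true targets + uniform decoys, per miRNA)
  set.seed(cfg$seed + 4L)
  pairs <- vector("list", cfg$nMirnas)
  for (i in seq_along(mirIds)) {
    m <- mirIds[i]
    truth <- if (m %in% regulatorIds) trueTargets[[m]] else character(0)
    pool <- setdiff(geneIds, truth)
    nDecoy <- min(cfg$decoyTargetsPerMirna, length(pool))
    decoys <- if (nDecoy > 0) sample(pool, nDecoy) else character(0)
    tg <- c(truth, decoys)
    pairs[[i]] <- data.frame(mirna_id = rep(m, length(tg)), gene_id = tg,
                             stringsAsFactors = FALSE)
  }
  targetMap <- do.call(rbind, pairs)
  rownames(targetMap) <- NULL

  ## stream 5: deafness-like gene set, enriched in one shared archetype
  set.seed(cfg$seed + 5L)
  geneSets <- list()
  if (nArch > 0) {
    enrichedArch <- if ("shared-down-high-A" %in% archNames)
      "shared-down-high-A" else archNames[1]
    members <- geneIds[geneArch == enrichedArch]
    inArch <- sample(members, min(25L, length(members)))
    outside <- sample(setdiff(geneIds, members), 15L)
    geneSets[["deafness_like"]] <- c(inArch, outside)
  }

  list(
    mrna = mrna, mirna = mirna, targetMap = targetMap, geneSets = geneSets,
    truth = list(
      geneArchetype = geneArch,
      regulatorIds = regulatorIds,
      regulatorArchetype = regArch,
      trueTargets = trueTargets,
      librarySizes = list(mrna = simG$libs, mirna = simM$libs)
    )
  )
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits `mrna_counts.tsv`, `mirna_counts.tsv`, `sample_sheet.csv` (both
#' matrices share one sheet), `target_map.tsv`, `gene_sets.gmt` and
#' `truth.json` in the pipeline's external formats.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the six file paths, invisibly.
#' @export
writeFixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    mrna_counts = file.path(dir, "mrna_counts.tsv"),
    mirna_counts = file.path(dir, "mirna_counts.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    target_map = file.path(dir, "target_map.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  writeCountsTSV(dataset$mrna, paths["mrna_counts"])
  writeCountsTSV(dataset$mirna, paths["mirna_counts"])
  sheet <- rbind(designFrame(dataset$mrna), designFrame(dataset$mirna))
  utils::write.csv(sheet, paths["sample_sheet"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(dataset$targetMap, paths["target_map"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeGMT(dataset$geneSets, paths["gene_sets"])
  truth <- dataset$truth
  jsonlite::write_json(
    list(geneArchetype = as.list(truth$geneArchetype),
         regulatorIds = truth$regulatorIds,
         regulatorArchetype = as.list(truth$regulatorArchetype),
         trueTargets = truth$trueTargets,
         librarySizes = lapply(truth$librarySizes, as.list)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

designFrame <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = cd$sample_id, organ = as.character(cd$organ),
             timepoint = as.character(cd$timepoint),
             replicate = cd$replicate, stringsAsFactors = FALSE)
}
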