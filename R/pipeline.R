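#' Pipeline run configuration
#'
#' Collects every stage threshold plus the seed and output directory.  When
#' `inputDir` is `NULL` the synthetic generator supplies the dataset
#' (`sim` holds its [simConfig()]); otherwise the directory must contain
#' fixture-format files (see [writeFixture()]).
#'
#' @param outDir artifact directory.
#' @param inputDir optional directory of input files; `NULL` simulates.
#' @param sim [simConfig()] used when simulating.
#' @param seed master seed (also used for the simulator unless `sim` sets
#'   its own).
#' @param mrnaDetect,mirnaDetect lists with `minCPM`, `minReplicates`.
#' @param mrnaDE,mirnaDE [deConfig()] objects.
#' @param cluster list: `kRange`, `homogeneity`, `minClusterSize`, `nstart`.
#' @param screen list: `pThresh`, `rThresh`, `minTargets`.
#' @param skip character vector of stage names to skip (only "screen" and
#'   "enrich" are skippable).
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(outDir, inputDir = NULL, seed = 1L,
                      sim = NULL,
                      mrnaDetect = list(minCPM = 0.5, minReplicates = 3L),
                      mirnaDetect = list(minCPM = 1, minReplicates = 2L),
                      mrnaDE = deConfig(),
                      mirnaDE = deConfigMirna(),
                      cluster = list(kRange = 2:12, homogeneity = 0.7,
                                     minClusterSize = 20L, nstart = 10L),
                      screen = list(pThresh = 0.01, rThresh = -0.4,
                                    minTargets = 5L),
                      skip = character(0)) {
  if (is.null(sim)) sim <- simConfig(seed = seed)
  cfg <- list(outDir = outDir, inputDir = inputDir, seed = as.integer(seed),
              sim = sim, mrnaDetect = mrnaDetect, mirnaDetect = mirnaDetect,
              mrnaDE = mrnaDE, mirnaDE = mirnaDE, cluster = cluster,
              screen = screen, skip = skip)
  class(cfg) <- "RunConfig"
  cfg
}

writeStage <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Chains simulate (or load) -> CPM + detection filter + profiles + PCA ->
#' differential expression (mRNA and miRNA) -> DEG clustering (down and up)
#' with labelling -> gene-set enrichment -> regulator screen, writing every
#' stage output as TSV into `config$outDir` together with `summary.json`
#' and a `run_metadata.json` sidecar echoing the configuration.  Idempotent
#' for a fixed seed.
#'
#' @param config a [runConfig()] object.
#' @return (invisibly) a list with all in-memory stage results plus the
#'   `summary` list.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$inputDir)) {
    data <- simulateDataset(config$sim)
  } else {
    need <- file.path(config$inputDir,
                      c("mrna_counts.tsv", "mirna_counts.tsv",
                        "sample_sheet.csv", "target_map.tsv"))
    absent <- need[!file.exists(need)]
    if (length(absent))
      stop("stage input: missing input file(s): ",
           paste(absent, collapse = ", "))
    data <- readFixture(config$inputDir)
  }

  ## preprocess
  mrna <- cpmTransform(data$mrna)
  mirna <- cpmTransform(data$mirna)
  detectedGenes <- detectionFilter(mrna, config$mrnaDetect$minCPM,
                                   config$mrnaDetect$minReplicates)
  detectedMirs <- detectionFilter(mirna, config$mirnaDetect$minCPM,
                                  config$mirnaDetect$minReplicates)
  geneProfiles <- conditionProfiles(mrna, detectedGenes)
  mirProfiles <- conditionProfiles(mirna, detectedMirs)
  pca <- pcaQC(mrna)
  writeStage(data.frame(feature_id = detectedGenes),
             file.path(config$outDir, "detected_genes.txt"))
  writeStage(data.frame(feature_id = detectedMirs),
             file.path(config$outDir, "detected_mirnas.txt"))
  writeStage(data.frame(feature_id = rownames(meanCPM(geneProfiles)),
                        meanCPM(geneProfiles), check.names = FALSE),
             file.path(config$outDir, "profiles_mean.tsv"))
  z <- standardizedProfiles(geneProfiles)
  writeStage(data.frame(feature_id = rownames(z), z, check.names = FALSE),
             file.path(config$outDir, "profiles_standardized.tsv"))
  writeStage(data.frame(sample_id = rownames(pca$scores),
                        pca$scores[, 1:2],
                        pca$design[, c("organ", "timepoint")],
                        check.names = FALSE),
             file.path(config$outDir, "pca_scores.tsv"))

  ## differential expression
  deGenes <- deAnalysis(mrna, detectedGenes, config$mrnaDE)
  degCalls <- callDEGs(deGenes)
  deMirs <- deAnalysis(mirna, detectedMirs, config$mirnaDE)
  mirCalls <- callDEGs(deMirs)
  writeStage(deGenes, file.path(config$outDir, "de_results_mrna.tsv"))
  writeStage(deMirs, file.path(config$outDir, "de_results_mirna.tsv"))
  writeStage(degCalls, file.path(config$outDir, "deg_calls_mrna.tsv"))
  writeStage(mirCalls, file.path(config$outDir, "deg_calls_mirna.tsv"))

  ## clustering of DEG profiles, per direction
  clusterResults <- list()
  for (dirn in c("down", "up")) {
    feats <- degCalls$feature_id[degCalls$is_de &
                                   degCalls$direction == dirn]
    if (length(feats) >= config$cluster$minClusterSize) {
      cr <- clusterProfiles(geneProfiles, feats, dirn,
                            kRange = config$cluster$kRange,
                            homogeneity = config$cluster$homogeneity,
                            minClusterSize = config$cluster$minClusterSize,
                            nstart = config$cluster$nstart,
                            seed = config$seed)
      clusterResults[[dirn]] <- labelClusters(cr, geneProfiles)
    }
  }
  clTab <- do.call(rbind, lapply(clusterResults, function(cr) {
    a <- clusterAssignments(cr)
    lab <- clusterLabels(cr)
    data.frame(feature_id = names(a), direction = cr@direction, cluster = a,
               label = ifelse(a == UNASSIGNED, "", lab[a]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(clTab)) {
    rownames(clTab) <- NULL
    writeStage(clTab, file.path(config$outDir, "clusters.tsv"))
    cm <- do.call(rbind, lapply(clusterResults, clusterCenters))
    writeStage(data.frame(cluster = rownames(cm), cm, check.names = FALSE),
               file.path(config$outDir, "cluster_means.tsv"))
  }

  ## enrichment of supplied gene sets in the clusters
  enrTab <- NULL
  if (!("enrich" %in% config$skip) && length(data$geneSets) &&
      length(clusterResults)) {
    enrTab <- enrichClusters(asClusterList(unname(clusterResults)),
                             data$geneSets, detectedGenes)
    writeStage(enrTab, file.path(config$outDir, "enrichment.tsv"))
  }

  ## regulator screen
  candidates <- NULL
  if (!("screen" %in% config$skip)) {
    if (is.null(data$targetMap) || !nrow(data$targetMap))
      stop("stage screen: no target map available")
    deMirIds <- mirCalls$feature_id[mirCalls$is_de]
    if (length(clusterResults)) {
      candidates <- screenRegulators(
        deMirIds, asClusterList(unname(clusterResults)), data$targetMap,
        geneProfiles, mirProfiles, detectedGenes,
        pThresh = config$screen$pThresh, rThresh = config$screen$rThresh,
        minTargets = config$screen$minTargets)
      writeStage(candidates, file.path(config$outDir, "candidates.tsv"))
    }
  }

  summary <- list(
    seed = config$seed,
    detected_genes = length(detectedGenes),
    detected_mirnas = length(detectedMirs),
    degs_down = sum(degCalls$is_de & degCalls$direction == "down"),
    degs_up = sum(degCalls$is_de & degCalls$direction == "up"),
    de_mirnas = sum(mirCalls$is_de),
    n_clusters = sum(vapply(clusterResults,
                            function(cr) nrow(clusterCenters(cr)), 1L)),
    pc1_variance_pct = round(100 * pca$varianceExplained[1], 2),
    passing_candidates = if (is.null(candidates)) NA_integer_ else
      length(unique(candidates$mirna[candidates$passes]))
  )
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(seed = config$seed,
               thresholds = list(
                 mrnaDetect = config$mrnaDetect,
                 mirnaDetect = config$mirnaDetect,
                 mrnaDE = unclass(config$mrnaDE),
                 mirnaDE = unclass(config$mirnaDE),
                 cluster = config$cluster, screen = config$screen),
               simulated = is.null(config$inputDir),
               packageVersion =
                 as.character(utils::packageVersion("mirDevScreen")))
  jsonlite::write_json(meta, file.path(config$outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, detectedGenes = detectedGenes,
                 detectedMirs = detectedMirs, geneProfiles = geneProfiles,
                 mirProfiles = mirProfiles, pca = pca,
                 deGenes = deGenes, degCalls = degCalls, deMirs = deMirs,
                 mirCalls = mirCalls, clusters = clusterResults,
                 enrichment = enrTab, candidates = candidates,
                 summary = summary))
}
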