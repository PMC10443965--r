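#' @include AllGenerics.R
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

UNASSIGNED <- "UNASSIGNED"

#' Feature-by-sample counts with a typed developmental design
#'
#' `DevCounts` extends [SummarizedExperiment::SummarizedExperiment] with a
#' two-organ, three-timepoint, replicated design in `colData` (columns
#' `organ`, `timepoint`, `replicate`) and a `featureKind` tag ("mRNA" or
#' "miRNA").  The `"counts"` assay holds non-negative integers.  After
#' [cpmTransform()] a `"cpm"` assay is present as well.
#'
#' Validity requires unique feature ids, non-negative finite integer counts,
#' exactly two organ levels and three ordered timepoint levels, and a unique
#' (organ, timepoint, replicate) triple per sample.
#'
#' @slot featureKind character, "mRNA" or "miRNA".
#' @export
setClass("DevCounts",
  contains = "SummarizedExperiment",
  slots = c(featureKind = "character")
)

setValidity("DevCounts", function(object) {
  msg <- character()
  if (!length(object@featureKind) == 1L ||
      !object@featureKind %in% c("mRNA", "miRNA"))
    msg <- c(msg, "featureKind must be 'mRNA' or 'miRNA'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts) || any(!is.finite(cts)))
      msg <- c(msg, "counts must be finite and non-missing")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(abs(cts - round(cts)) > 1e-8))
        msg <- c(msg, "counts must be integers")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("organ", "timepoint", "replicate")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, "colData must have columns organ, timepoint, replicate")
  } else {
    if (nlevels(cd$organ) != 2L)
      msg <- c(msg, "organ must be a factor with exactly 2 levels")
    if (!is.ordered(cd$timepoint) || nlevels(cd$timepoint) != 3L)
      msg <- c(msg, "timepoint must be an ordered factor with 3 levels")
    key <- paste(cd$organ, cd$timepoint, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "(organ, timepoint, replicate) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DevCounts object
#'
#' @param counts integer matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param design data.frame with one row per sample and columns `sample_id`,
#'   `organ`, `timepoint`, `replicate`.  Organ/timepoint are coerced to
#'   factors; timepoint level order follows `timepoints` if given, else the
#'   sorted unique values.
#' @param featureKind "mRNA" or "miRNA".
#' @param organs optional explicit organ level order.
#' @param timepoints optional explicit timepoint level order (baseline first).
#' @return A [DevCounts-class] object with samples in design order.
#' @examples
#' cts <- matrix(0:5, nrow = 1, dimnames = list("g1", paste0("s", 1:6)))
#' des <- data.frame(sample_id = paste0("s", 1:6),
#'                   organ = rep(c("A", "B"), each = 3),
#'                   timepoint = rep(c("T0", "T1", "T2"), 2), replicate = 1)
#' DevCounts(cts, des, "mRNA")
#' @export
DevCounts <- function(counts, design, featureKind = c("mRNA", "miRNA"),
                      organs = NULL, timepoints = NULL) {
  featureKind <- match.arg(featureKind)
  counts <- as.matrix(counts)
  design <- as.data.frame(design)
  if (is.null(design$sample_id)) design$sample_id <- colnames(counts)
  if (is.null(colnames(counts)))
    stop("counts must have sample ids as column names")
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing))
    stop("sample(s) missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(design$sample_id, colnames(counts))
  if (length(extra))
    stop("sample sheet row(s) with no counts column: ",
         paste(extra, collapse = ", "))
  counts <- counts[, as.character(design$sample_id), drop = FALSE]
  if (is.null(organs)) organs <- sort(unique(as.character(design$organ)))
  if (is.null(timepoints))
    timepoints <- sort(unique(as.character(design$timepoint)))
  cd <- S4Vectors::DataFrame(
    sample_id = as.character(design$sample_id),
    organ = factor(as.character(design$organ), levels = organs),
    timepoint = factor(as.character(design$timepoint),
                       levels = timepoints, ordered = TRUE),
    replicate = as.integer(design$replicate),
    row.names = as.character(design$sample_id)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("DevCounts", se, featureKind = featureKind)
}

#' @describeIn DevCounts feature kind ("mRNA" or "miRNA")
#' @param x a `DevCounts` object
#' @export
setMethod("featureKind", "DevCounts", function(x) x@featureKind)

#' @describeIn DevCounts organ factor over samples
#' @export
setMethod("organ", "DevCounts",
          function(x) SummarizedExperiment::colData(x)$organ)

#' @describeIn DevCounts ordered timepoint factor over samples
#' @export
setMethod("timepoint", "DevCounts",
          function(x) SummarizedExperiment::colData(x)$timepoint)

#' @describeIn DevCounts per-sample condition label "organ_timepoint"
#' @export
setMethod("conditionOf", "DevCounts", function(x) {
  factor(paste(organ(x), timepoint(x), sep = "_"),
         levels = conditionLevels(levels(organ(x)), levels(timepoint(x))))
})

setMethod("show", "DevCounts", function(object) {
  cat("DevCounts (", object@featureKind, "): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  tb <- table(organ(object), timepoint(object))
  cat("samples per condition:\n")
  print(tb)
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
})

# fixed condition order: organ-major, timepoint-minor
conditionLevels <- function(organs, timepoints) {
  as.vector(t(outer(organs, timepoints, paste, sep = "_")))
}

#' Per-condition mean and standardized expression profiles
#'
#' Holds, for each feature, the mean CPM over replicates in each of the six
#' (organ, timepoint) conditions, and the per-feature standardized profile
#' (log2(mean CPM + 1), scaled to mean 0 and population SD 1).  Features
#' whose six condition means are all equal cannot be standardized; they are
#' flagged in `zeroVariance` and their standardized rows are `NA`.
#'
#' @slot conditions character(6), condition labels in fixed organ-major order.
#' @slot meanCPM features x 6 matrix of condition mean CPM.
#' @slot standardized features x 6 matrix, rows mean 0 / SD 1 (NA if flagged).
#' @slot zeroVariance named logical, TRUE for flat features.
#' @export
setClass("ConditionProfiles", slots = c(
  conditions = "character",
  meanCPM = "matrix",
  standardized = "matrix",
  zeroVariance = "logical"
))

setValidity("ConditionProfiles", function(object) {
  msg <- character()
  if (length(object@conditions) != ncol(object@meanCPM))
    msg <- c(msg, "conditions length must match meanCPM columns")
  if (!identical(dim(object@meanCPM), dim(object@standardized)))
    msg <- c(msg, "meanCPM and standardized must have identical shape")
  if (length(object@zeroVariance) != nrow(object@meanCPM))
    msg <- c(msg, "zeroVariance must flag every feature")
  ok <- !object@zeroVariance
  if (any(ok)) {
    z <- object@standardized[ok, , drop = FALSE]
    m <- rowMeans(z)
    s <- sqrt(rowMeans(z^2) - m^2)
    if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-8)
      msg <- c(msg, "standardized rows must have mean 0 and SD 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ConditionProfiles condition mean CPM matrix
#' @param x a `ConditionProfiles` object
#' @export
setMethod("meanCPM", "ConditionProfiles", function(x) x@meanCPM)

#' @describeIn ConditionProfiles standardized profile matrix
#' @export
setMethod("standardizedProfiles", "ConditionProfiles",
          function(x) x@standardized)

#' @describeIn ConditionProfiles logical flags for flat features
#' @export
setMethod("zeroVariance", "ConditionProfiles", function(x) x@zeroVariance)

setMethod("show", "ConditionProfiles", function(object) {
  cat("ConditionProfiles: ", nrow(object@meanCPM), " features x ",
      ncol(object@meanCPM), " conditions (",
      paste(object@conditions, collapse = ", "), ")\n", sep = "")
  cat(sum(object@zeroVariance), "zero-variance feature(s) flagged\n")
})

#' Result of profile clustering
#'
#' @slot assignments named character, feature -> cluster id or "UNASSIGNED".
#' @slot centers cluster x condition matrix of mean standardized profiles.
#' @slot labels named character, cluster id -> category tag (filled by
#'   [labelClusters()]).
#' @slot direction "up" or "down": which DEG set was clustered.
#' @slot params list of clustering parameters actually used.
#' @export
setClass("ClusterResult", slots = c(
  assignments = "character",
  centers = "matrix",
  labels = "character",
  direction = "character",
  params = "list"
))

setValidity("ClusterResult", function(object) {
  msg <- character()
  ids <- setdiff(unique(object@assignments), UNASSIGNED)
  if (length(ids) && !all(ids %in% rownames(object@centers)))
    msg <- c(msg, "every cluster id must have a center")
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by feature id")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterResult named feature -> cluster assignment vector
#' @param x a `ClusterResult` object
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' @describeIn ClusterResult cluster center (mean standardized profile) matrix
#' @export
setMethod("clusterCenters", "ClusterResult", function(x) x@centers)

#' @describeIn ClusterResult cluster -> category tag labels
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

setMethod("show", "ClusterResult", function(object) {
  sz <- table(object@assignments)
  cat("ClusterResult (direction=", object@direction, "): ",
      nrow(object@centers), " cluster(s), ",
      sum(object@assignments != UNASSIGNED), " assigned / ",
      length(object@assignments), " features\n", sep = "")
  print(sz)
  if (length(object@labels)) {
    cat("labels:\n")
    print(object@labels)
  }
})
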