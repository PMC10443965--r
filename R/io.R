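## Readers/writers for the pipeline's external plain-text formats.
## Dialect: tab-separated, UTF-8, header row required, '#' comment lines
## skipped.  Readers are total: a file either parses to a validated object
## or raises an error naming the offending sample/line.

readTSV <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", fileEncoding = "UTF-8")
}

#' Read a count matrix and its sample sheet
#'
#' The counts file is a TSV whose first column holds feature ids and whose
#' remaining columns are samples; cells must be non-negative integers.  The
#' sample sheet is a CSV with columns `sample_id`, `organ`, `timepoint`,
#' `replicate`; it may describe more samples than the counts file (e.g. a
#' shared sheet for mRNA and miRNA), but every counts column must appear in
#' it.  Samples are reordered to sample-sheet order.
#'
#' @param path counts TSV path.
#' @param sampleSheetPath sample sheet CSV path.
#' @param featureKind "mRNA" or "miRNA".
#' @param organs,timepoints optional explicit factor level orders
#'   (baseline timepoint first).
#' @return a [DevCounts-class] object.
#' @export
readCounts <- function(path, sampleSheetPath, featureKind = c("mRNA", "miRNA"),
                       organs = NULL, timepoints = NULL) {
  featureKind <- match.arg(featureKind)
  tab <- readTSV(path)
  if (ncol(tab) < 2) stop("counts file needs a feature column and >=1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(abs(m - round(m)) > 1e-8))
    stop("non-integer count cell(s) in ", path)
  if (any(m < 0)) stop("negative count cell(s) in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  sheet <- utils::read.csv(sampleSheetPath, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("sample_id", "organ", "timepoint", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    stop("counts column(s) absent from sample sheet: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  DevCounts(m, sheet, featureKind, organs = organs, timepoints = timepoints)
}

#' Write a DevCounts count matrix as TSV
#'
#' @param x a [DevCounts-class] object.
#' @param path output path; first column `feature_id`, then sample columns.
#' @export
writeCountsTSV <- function(x, path) {
  cts <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(feature_id = rownames(cts), cts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a miRNA -> predicted-target pair list
#'
#' TSV with columns `mirna_id` and `gene_id`, one pair per row (TargetScan
#' style pair dump).  Duplicate pairs are dropped with a warning stating how
#' many were removed.
#'
#' @param path TSV path.
#' @return data.frame with columns `mirna_id`, `gene_id`, deduplicated.
#' @export
readTargetMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    warning("empty target map file: ", path)
    return(data.frame(mirna_id = character(0), gene_id = character(0)))
  }
  tab <- readTSV(path)
  if (!all(c("mirna_id", "gene_id") %in% colnames(tab)))
    stop("target map must have columns mirna_id, gene_id")
  tab <- data.frame(mirna_id = as.character(tab$mirna_id),
                    gene_id = as.character(tab$gene_id),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(tab$mirna_id, tab$gene_id, sep = "\r"))
  if (any(dup))
    warning(sum(dup), " duplicate target pair(s) dropped")
  tab[!dup, , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields tab-separated, `name`,
#' `description`, then members.  Lines with fewer than three fields raise an
#' error naming the line; duplicate members within a set are dropped with a
#' warning.
#'
#' @param path GMT path.
#' @return named list of character vectors (set name -> gene ids).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character(0)))
  }
  sets <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " (< 3 fields) in ", path)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", f[1], "': ", sum(duplicated(members)),
              " duplicate member(s) dropped")
      members <- unique(members)
    }
    if (!length(members))
      stop("malformed GMT line ", i, " (no members) in ", path)
    sets[[f[1]]] <- members
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param dir fixture directory.
#' @return list with `mrna`, `mirna`, `targetMap`, `geneSets`, `truth`.
#' @export
readFixture <- function(dir) {
  sheet <- file.path(dir, "sample_sheet.csv")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    mrna = readCounts(file.path(dir, "mrna_counts.tsv"), sheet, "mRNA",
                      organs = c("A", "B"),
                      timepoints = c("T0", "T1", "T2")),
    mirna = readCounts(file.path(dir, "mirna_counts.tsv"), sheet, "miRNA",
                       organs = c("A", "B"),
                       timepoints = c("T0", "T1", "T2")),
    targetMap = readTargetMap(file.path(dir, "target_map.tsv")),
    geneSets = readGMT(file.path(dir, "gene_sets.gmt")),
    truth = truth
  )
}
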