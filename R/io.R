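# Reading and writing 10x-style Matrix Market triplet directories and the
# run configuration.

.find10xFile <- function(dir, stem) {
  for (f in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz"))))
    if (file.exists(f)) return(f)
  stopCfg("missing file in ", dir, ": ", stem, "(.gz)")
}

.readLinesMaybeGz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style count matrix directory
#'
#' Expects `matrix.mtx(.gz)`, `barcodes.tsv(.gz)` and `features.tsv(.gz)`.
#' The on-disk matrix may be stored either genes x cells (the 10x convention)
#' or cells x genes; orientation is resolved against the barcode and feature
#' lists and the returned object is always genes x cells.
#'
#' @param dir directory containing the three files.
#' @param species optional species tag stored in `metadata()$species`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay.
#' @export
readCounts10x <- function(dir, species = NULL) {
  if (!dir.exists(dir)) stopCfg("no such directory: ", dir)
  mtx <- .find10xFile(dir, "matrix.mtx")
  bcf <- .find10xFile(dir, "barcodes.tsv")
  ftf <- .find10xFile(dir, "features.tsv")

  barcodes <- .readLinesMaybeGz(bcf)
  features <- .readLinesMaybeGz(ftf)
  geneIds <- vapply(strsplit(features, "\t"), `[`, "", 1L)
  if (anyDuplicated(geneIds))
    stopCfg("format error: duplicate gene ids in ", ftf)
  if (anyDuplicated(barcodes))
    stopCfg("format error: duplicate barcodes in ", bcf)

  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx
  m <- Matrix::readMM(con)
  ng <- length(geneIds); nc <- length(barcodes)
  if (nrow(m) == ng && ncol(m) == nc) {
    # genes x cells as stored
  } else if (nrow(m) == nc && ncol(m) == ng) {
    m <- Matrix::t(m)
  } else {
    stopCfg("format error: matrix is ", nrow(m), " x ", ncol(m),
            " but features/barcodes have ", ng, "/", nc, " entries")
  }
  if (any(m@x < 0)) stopCfg("format error: negative counts in ", mtx)
  m <- as(m, "CsparseMatrix")
  dimnames(m) <- list(geneIds, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    metadata = list(species = species))
}

#' Write a count matrix as a 10x-style directory
#'
#' Writes `matrix.mtx` (genes x cells), `barcodes.tsv` and `features.tsv`
#' (gene id, gene symbol, "Gene Expression").
#'
#' @param x a `SingleCellExperiment` or genes x cells matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts10x <- function(x, dir) {
  cnt <- .counts(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(cnt, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(cnt), file.path(dir, "barcodes.tsv"))
  writeLines(paste(rownames(cnt), rownames(cnt), "Gene Expression",
                   sep = "\t"),
             file.path(dir, "features.tsv"))
  invisible(dir)
}

# Known configuration keys with defaults; unknown keys are rejected rather
# than silently ignored.
.configDefaults <- function() {
  list(
    countsDir = NULL,
    outDir = "leprmap_out",
    seed = 1,
    species = "mouse",
    stages = list(qc = TRUE, doublets = TRUE, cluster = TRUE,
                  annotate = FALSE),
    qc = list(minCellsPerGene = 5, minGenesPerCell = 600, doubletCut = 0.3,
              nSimDoublets = NULL, knnK = NULL),
    embed = list(normMethod = "pooled", nTopGenes = 2000, clip = 10,
                 pcMin = 15, pcMax = 30, elbowTol = 1e-3),
    cluster = list(knnK = 20, resolutionStart = 0.2, resolutionStep = 0.2,
                   maxResolution = 3, patience = 2,
                   markerFdr = 0.05, gabaGene = "Slc32a1",
                   gluGene = "Slc17a6"),
    annotate = list(referenceDir = NULL, referenceLabels = NULL, voteK = 15,
                    nSharedPCs = 20, neuronalWhitelist = NULL)
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stopCfg("unknown configuration key: ", path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stopCfg("configuration key ", path, k, " must be a section")
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

.validateConfig <- function(cfg) {
  q <- cfg$qc
  if (q$minCellsPerGene < 1 || q$minGenesPerCell < 1)
    stopCfg("QC thresholds must be strictly positive")
  if (q$doubletCut <= 0 || q$doubletCut >= 1)
    stopCfg("doubletCut must lie in (0, 1)")
  e <- cfg$embed
  if (e$pcMin < 1 || e$pcMax < e$pcMin)
    stopCfg("need 1 <= pcMin <= pcMax")
  cl <- cfg$cluster
  if (cl$resolutionStart <= 0 || cl$resolutionStep <= 0 || cl$patience < 1)
    stopCfg("resolution start/step must be > 0 and patience >= 1")
  if (cfg$annotate$voteK < 1) stopCfg("voteK must be >= 1")
  cfg
}

#' Read and validate a pipeline run configuration
#'
#' JSON is the native format; YAML is accepted when the `yaml` package is
#' available. Unknown keys are an error (they are usually threshold typos).
#' Missing keys take the documented defaults; see `runPipeline()` for the
#' meaning of each section.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file, or a named list.
#' @return a validated configuration list.
#' @export
readRunConfig <- function(path) {
  user <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopCfg("YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .validateConfig(.mergeConfig(.configDefaults(), user))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
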