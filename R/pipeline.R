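# End-to-end orchestration: QC waterfall, doublet removal, optional reference
# annotation, embedding, the resolution scan, markers and naming, with every
# intermediate written as TSV/JSON and a per-stage log.

#' Run the full population-discovery pipeline
#'
#' Reads a 10x-style counts directory and runs, in order: gene/cell QC
#' filtering, simulated-doublet scoring with the cluster-median removal rule,
#' optional reference label transfer with nonneuronal removal, pooled
#' normalization, variable-gene selection, scaling, PCA with elbow retention,
#' the silhouette-maximizing resolution scan, hierarchical cluster ordering,
#' marker detection and population naming. Each stage logs its cell/gene
#' counts (the QC waterfall) to stderr and `run.log`, and each intermediate
#' is written under `outDir`. Outputs are identical for identical inputs,
#' configuration and seed.
#'
#' @param config a configuration list or path to a JSON/YAML file; see
#'   [readRunConfig()]. Sections: `stages` (toggles qc/doublets/annotate/
#'   cluster), `qc` (minCellsPerGene, minGenesPerCell, doubletCut, ...),
#'   `embed` (normMethod, nTopGenes, clip, pcMin, pcMax, elbowTol),
#'   `cluster` (knnK, resolutionStart/Step, maxResolution, patience,
#'   markerFdr, indicator genes), `annotate` (referenceDir, referenceLabels
#'   TSV with barcode/type columns, voteK, neuronalWhitelist).
#' @return (invisibly) a list with the final `sce`, `embedding`, `solution`,
#'   `markers`, `clusterNames`, `assignment` (or NULL), the QC `waterfall`,
#'   and `files` (paths of all written artifacts).
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  if (is.null(cfg$countsDir)) stopCfg("config needs countsDir")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(cfg$outDir, "run.log")
  cat("", file = logFile) # truncate
  files <- c(log = logFile)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  msgLog("reading counts from ", cfg$countsDir, logFile = logFile)
  sce <- stage("read", readCounts10x(cfg$countsDir, species = cfg$species))
  waterfall <- c(input = ncol(sce))
  msgLog("input: ", nrow(sce), " genes x ", ncol(sce), " cells",
         logFile = logFile)

  if (isTRUE(cfg$stages$qc)) {
    fm <- stage("qc", filterMatrix(sce, cfg$qc$minCellsPerGene,
                                   cfg$qc$minGenesPerCell))
    sce <- fm$sce
    waterfall["geneFiltered"] <- ncol(sce)
    msgLog("qc: ", fm$report["genesRetained"], "/", fm$report["genesIn"],
           " genes, ", fm$report["cellsRetained"], "/", fm$report["cellsIn"],
           " cells retained", logFile = logFile)
  } else msgLog("qc: stage skipped", logFile = logFile)

  if (isTRUE(cfg$stages$doublets)) {
    det <- stage("doublets",
      scoreDoublets(sce, nSimDoublets = cfg$qc$nSimDoublets,
                    knnK = cfg$qc$knnK, seed = stageSeed(cfg$seed, 1L),
                    details = TRUE))
    provisional <- stage("doublets",
      clusterOnce(det$coords, resolution = 1,
                  knnK = min(cfg$cluster$knnK, ncol(sce) - 1),
                  seed = stageSeed(cfg$seed, 2L)))
    keep <- applyDoubletFilter(det$scores, provisional, cfg$qc$doubletCut)
    files["doublet_scores"] <- file.path(cfg$outDir, "doublet_scores.tsv")
    .writeTsv(data.frame(barcode = names(det$scores),
                         doublet_score = det$scores,
                         provisional_cluster = as.character(provisional),
                         retained = keep),
              files["doublet_scores"])
    sce <- sce[, keep]
    waterfall["doubletFiltered"] <- ncol(sce)
    msgLog("doublets: removed ", sum(!keep), " cells (cut ",
           cfg$qc$doubletCut, "); ", ncol(sce), " remain",
           logFile = logFile)
  } else msgLog("doublets: stage skipped", logFile = logFile)

  norm <- stage("normalize",
                normalizeCounts(sce, method = cfg$embed$normMethod))

  assignment <- NULL
  if (isTRUE(cfg$stages$annotate)) {
    an <- cfg$annotate
    if (is.null(an$referenceDir) || is.null(an$referenceLabels))
      stopCfg("annotate stage needs referenceDir and referenceLabels")
    ref <- stage("annotate", readCounts10x(an$referenceDir))
    lab <- read.table(an$referenceLabels, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    refTypes <- setNames(lab$type, lab$barcode)[colnames(ref)]
    assignment <- stage("annotate",
      transferLabels(norm, ref, refTypes, voteK = an$voteK,
                     nSharedPCs = an$nSharedPCs,
                     seed = stageSeed(cfg$seed, 3L)))
    files["assignment"] <- file.path(cfg$outDir, "type_assignment.tsv")
    .writeTsv(data.frame(barcode = names(assignedType(assignment)),
                         type = assignedType(assignment),
                         vote_fraction = voteFraction(assignment)),
              files["assignment"])
    if (!is.null(an$neuronalWhitelist)) {
      keep <- dropNonneuronal(assignment, an$neuronalWhitelist)
      sce <- sce[, keep]
      waterfall["neuronal"] <- ncol(sce)
      msgLog("annotate: removed ", sum(!keep), " nonneuronal cells; ",
             ncol(sce), " remain", logFile = logFile)
      norm <- stage("normalize",
                    normalizeCounts(sce, method = cfg$embed$normMethod))
    }
  } else msgLog("annotate: stage skipped", logFile = logFile)

  hvg <- stage("embed", selectVariableGenes(
    norm, nTop = min(cfg$embed$nTopGenes, nrow(norm))))
  scaled <- stage("embed", scaleCenter(norm, hvg, clip = cfg$embed$clip))
  emb <- stage("embed", pcaElbow(scaled, pcMin = cfg$embed$pcMin,
                                 pcMax = cfg$embed$pcMax,
                                 elbowTol = cfg$embed$elbowTol,
                                 seed = stageSeed(cfg$seed, 4L)))
  msgLog("embed: ", length(hvg), " variable genes, ", nPCs(emb),
         " PCs retained", logFile = logFile)
  files["embedding"] <- file.path(cfg$outDir, "embedding.tsv")
  .writeTsv(data.frame(barcode = rownames(pcCoords(emb)), pcCoords(emb)),
            files["embedding"])
  files["embedding_meta"] <- file.path(cfg$outDir, "embedding.json")
  jsonlite::write_json(list(nPCs = nPCs(emb),
                            varianceFraction = varianceFraction(emb)),
                       files["embedding_meta"], auto_unbox = TRUE,
                       digits = NA)

  solution <- markers <- clusterNames <- NULL
  if (isTRUE(cfg$stages$cluster)) {
    cl <- cfg$cluster
    solution <- stage("cluster", optimizeResolution(
      emb, knnK = cl$knnK, resolutionStart = cl$resolutionStart,
      resolutionStep = cl$resolutionStep, maxResolution = cl$maxResolution,
      patience = cl$patience, seed = stageSeed(cfg$seed, 5L)))
    labels <- clusterLabels(solution)
    msgLog("cluster: ", nClusters(solution), " clusters at resolution ",
           solution@resolution,
           sprintf(" (mean silhouette %.3f)", meanSilhouette(solution)),
           logFile = logFile)
    ord <- stage("cluster", orderClusters(emb, labels))
    markers <- stage("cluster", findClusterMarkers(norm, labels))
    clusterNames <- stage("cluster", nameClusters(
      markers, norm, labels, treeOrder = ord$order, fdrCut = cl$markerFdr,
      gabaGene = cl$gabaGene, gluGene = cl$gluGene))

    files["scan_log"] <- file.path(cfg$outDir, "scan_log.tsv")
    .writeTsv(scanLog(solution), files["scan_log"])
    files["cluster_table"] <- file.path(cfg$outDir, "cluster_table.tsv")
    .writeTsv(data.frame(barcode = names(labels),
                         cluster = as.character(labels),
                         population = clusterNames[as.character(labels)],
                         resolution = solution@resolution),
              files["cluster_table"])
    files["marker_table"] <- file.path(cfg$outDir, "marker_table.tsv")
    .writeTsv(markers, files["marker_table"])
  } else msgLog("cluster: stage skipped", logFile = logFile)

  files["qc_report"] <- file.path(cfg$outDir, "qc_report.json")
  jsonlite::write_json(list(waterfall = as.list(waterfall),
                            seed = cfg$seed,
                            qc = cfg$qc[!vapply(cfg$qc, is.null, TRUE)]),
                       files["qc_report"], auto_unbox = TRUE, digits = NA)
  msgLog("done; outputs in ", cfg$outDir, logFile = logFile)

  invisible(list(sce = sce, embedding = emb, solution = solution,
                 markers = markers, clusterNames = clusterNames,
                 assignment = assignment, waterfall = waterfall,
                 files = files))
}
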