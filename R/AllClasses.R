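#' Principal-component embedding of cells
#'
#' Cells-by-PC coordinates together with the fraction of total variance each
#' retained component explains. Produced by [pcaElbow()] and consumed by the
#' clustering, annotation and harmonization stages.
#'
#' @slot coords numeric matrix, cells x retained PCs; rownames are barcodes.
#' @slot varianceFraction per-PC fraction of total variance, nonincreasing.
#' @slot nPCs number of retained components.
#' @export
setClass("PCEmbedding",
  representation(coords = "matrix", varianceFraction = "numeric",
                 nPCs = "integer"))

setValidity("PCEmbedding", function(object) {
  msg <- NULL
  if (ncol(object@coords) != object@nPCs)
    msg <- c(msg, "ncol(coords) must equal nPCs")
  if (length(object@varianceFraction) != object@nPCs)
    msg <- c(msg, "varianceFraction must have one entry per retained PC")
  vf <- object@varianceFraction
  if (length(vf) && (any(!is.finite(vf)) || any(diff(vf) > 1e-8)))
    msg <- c(msg, "variance fractions must be finite and nonincreasing")
  if (sum(vf) > 1 + 1e-6)
    msg <- c(msg, "variance fractions must sum to <= 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PCEmbedding cell coordinates (cells x PCs)
#' @param x,object a `PCEmbedding`
#' @export
pcCoords <- function(x) x@coords

#' @describeIn PCEmbedding per-PC variance fractions
#' @export
varianceFraction <- function(x) x@varianceFraction

#' @describeIn PCEmbedding number of retained PCs
#' @export
nPCs <- function(x) x@nPCs

#' @export
setMethod("show", "PCEmbedding", function(object) {
  cat("PCEmbedding:", nrow(object@coords), "cells x", object@nPCs, "PCs;",
      sprintf("%.1f%%", 100 * sum(object@varianceFraction)),
      "of variance retained\n")
})

#' Clustering solution at a given resolution
#'
#' A partition of cells from SNN-graph Leiden clustering, the resolution that
#' produced it, its mean silhouette width in PC space, and the full resolution
#' scan log when produced by [optimizeResolution()].
#'
#' @slot labels factor of per-cell cluster ids (names are barcodes).
#' @slot resolution the resolution parameter that produced the partition.
#' @slot meanSilhouette mean silhouette width over (subsampled) cells;
#'   `-Inf` for a single-cluster partition.
#' @slot scanLog data.frame with one row per evaluated resolution
#'   (columns resolution, nClusters, meanSilhouette).
#' @export
setClass("ClusterSolution",
  representation(labels = "factor", resolution = "numeric",
                 meanSilhouette = "numeric", scanLog = "data.frame"))

setValidity("ClusterSolution", function(object) {
  msg <- NULL
  if (anyNA(object@labels))
    msg <- c(msg, "labels must partition all cells (no NA)")
  if (length(object@resolution) != 1 || object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number")
  if (length(object@meanSilhouette) != 1)
    msg <- c(msg, "meanSilhouette must be a single number")
  if (nlevels(object@labels) >= 2 && !is.finite(object@meanSilhouette))
    msg <- c(msg, "meanSilhouette must be finite for >= 2 clusters")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterSolution per-cell cluster labels (factor)
#' @param x,object a `ClusterSolution`
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterSolution mean silhouette of the partition
#' @export
meanSilhouette <- function(x) x@meanSilhouette

#' @describeIn ClusterSolution the resolution scan log
#' @export
scanLog <- function(x) x@scanLog

#' @describeIn ClusterSolution number of clusters
#' @export
nClusters <- function(x) nlevels(x@labels)

#' @export
setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution:", length(object@labels), "cells in",
      nlevels(object@labels), "clusters at resolution", object@resolution,
      sprintf("(mean silhouette %.3f;", object@meanSilhouette),
      nrow(object@scanLog), "resolutions scanned)\n")
})

#' Reference cell-type assignment of query cells
#'
#' Per-cell type call from kNN-vote label transfer: the winning type, the
#' fraction of the voting neighborhood whose individual best type agrees with
#' the winner, and the full per-type score matrix.
#'
#' @slot type character vector of assigned type names (names are barcodes).
#' @slot voteFraction votes for the winner / vote_k, in (0, 1].
#' @slot scores numeric matrix cells x reference types of summed
#'   neighborhood similarity scores.
#' @export
setClass("TypeAssignment",
  representation(type = "character", voteFraction = "numeric",
                 scores = "matrix"))

setValidity("TypeAssignment", function(object) {
  msg <- NULL
  n <- length(object@type)
  if (length(object@voteFraction) != n || nrow(object@scores) != n)
    msg <- c(msg, "type, voteFraction and scores must agree on cell count")
  if (n && (any(object@voteFraction <= 0) || any(object@voteFraction > 1)))
    msg <- c(msg, "voteFraction must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn TypeAssignment assigned type per cell
#' @param x,object a `TypeAssignment`
#' @export
assignedType <- function(x) x@type

#' @describeIn TypeAssignment vote fraction per cell
#' @export
voteFraction <- function(x) x@voteFraction

#' @describeIn TypeAssignment per-cell per-type score matrix
#' @export
typeScores <- function(x) x@scores

#' @export
setMethod("show", "TypeAssignment", function(object) {
  tab <- sort(table(object@type), decreasing = TRUE)
  cat("TypeAssignment:", length(object@type), "cells,",
      ncol(object@scores), "reference types; top:",
      paste0(names(head(tab, 3)), " (", head(tab, 3), ")", collapse = ", "),
      "\n")
})

#' Conserved-population map from a combined multi-species clustering
#'
#' One row per (combined cluster, reference population) assignment plus rows
#' for unmatched populations and unassigned clusters. Produced by
#' [matchConserved()].
#'
#' @slot mapping data.frame with columns `cluster` (combined cluster id,
#'   possibly a subcluster id like "3.1"), `population` (reference population
#'   name or NA), `overlap` (fraction of the population's cells inside the
#'   cluster), `status` (one of "matched", "contested-resolved", "unmatched",
#'   "unassigned").
#' @slot threshold the overlap threshold used (default 0.8).
#' @export
setClass("ConservedMap",
  representation(mapping = "data.frame", threshold = "numeric"))

setValidity("ConservedMap", function(object) {
  msg <- NULL
  need <- c("cluster", "population", "overlap", "status")
  if (!all(need %in% names(object@mapping)))
    msg <- c(msg, paste("mapping must have columns:", paste(need, collapse = ", ")))
  else {
    ov <- object@mapping$overlap
    if (any(!is.na(ov) & (ov < 0 | ov > 1)))
      msg <- c(msg, "overlap fractions must lie in [0, 1]")
    pop <- object@mapping$population
    pop <- pop[!is.na(pop) & object@mapping$status != "unmatched"]
    if (anyDuplicated(pop))
      msg <- c(msg, "each reference population may be assigned to at most one cluster")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ConservedMap the mapping table as a data.frame
#' @param x,object a `ConservedMap`
#' @export
conservedMapping <- function(x) x@mapping

#' @export
setMethod("show", "ConservedMap", function(object) {
  m <- object@mapping
  cat("ConservedMap:", sum(m$status %in% c("matched", "contested-resolved")),
      "populations matched,", sum(m$status == "unmatched"), "unmatched",
      sprintf("(threshold %.2f)\n", object@threshold))
})

#' Signed leptin-response gene signature
#'
#' Genes significantly regulated by leptin in TRAP-seq bead samples, with the
#' direction of regulation. Built by [buildSignature()] and consumed by
#' [scoreSignature()].
#'
#' @slot genes character vector of gene ids.
#' @slot sign +1 for up under leptin, -1 for down (aligned with `genes`).
#' @slot alpha the FDR threshold used.
#' @export
setClass("LeptinSignature",
  representation(genes = "character", sign = "numeric", alpha = "numeric"))

setValidity("LeptinSignature", function(object) {
  msg <- NULL
  if (length(object@genes) == 0)
    msg <- c(msg, "signature must be nonempty to be scoreable")
  if (length(object@sign) != length(object@genes))
    msg <- c(msg, "one sign per gene required")
  if (length(object@sign) && !all(object@sign %in% c(-1, 1)))
    msg <- c(msg, "signs must be -1 or +1")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene ids in signature")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn LeptinSignature signature gene ids
#' @param x,object a `LeptinSignature`
#' @export
signatureGenes <- function(x) x@genes

#' @describeIn LeptinSignature per-gene signs (+1 up / -1 down under leptin)
#' @export
signatureSigns <- function(x) setNames(x@sign, x@genes)

#' @export
setMethod("show", "LeptinSignature", function(object) {
  cat("LeptinSignature:", length(object@genes), "genes (",
      sum(object@sign > 0), "up /", sum(object@sign < 0),
      "down under leptin ) at FDR <", object@alpha, "\n")
})
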