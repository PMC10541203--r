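# Cross-species integration: 1:1 ortholog restriction, centroid-based batch
# harmonization, and conserved-population matching under the 80% rule.

#' Restrict a count matrix to 1:1 orthologs and rename to reference ids
#'
#' Keeps only genes present in the map's `sourceId` column and renames them to
#' the corresponding `referenceId`. Cells are unchanged.
#'
#' @param x a `SingleCellExperiment` (or matrix) with species-local gene ids.
#' @param map data.frame with columns `sourceId` and `referenceId`, strictly
#'   1:1 (both columns duplicate-free).
#' @return the restricted, renamed object.
#' @export
restrictToOrthologs <- function(x, map) {
  if (!all(c("sourceId", "referenceId") %in% names(map)))
    stopCfg("map must have columns sourceId and referenceId")
  if (anyDuplicated(map$sourceId) || anyDuplicated(map$referenceId))
    stopCfg("input error: ortholog map is not 1:1")
  ids <- if (is(x, "SummarizedExperiment")) rownames(x) else rownames(.counts(x))
  keep <- which(ids %in% map$sourceId)
  out <- x[keep, ]
  rownames(out) <- map$referenceId[match(ids[keep], map$sourceId)]
  out
}

#' Harmonize batches in PC space by soft-cluster centroid matching
#'
#' First removes the global batch offsets (each batch is translated so its
#' mean matches the overall mean), then iteratively (1) soft-assigns cells to
#' `nClusters` clusters with Gaussian responsibilities in the embedding, and
#' (2) moves each cell by its responsibility-weighted sum of (global centroid
#' - its batch's centroid), pulling per-batch cluster centroids together
#' while leaving within-cluster structure intact. Stops when the largest
#' per-cell shift falls below `tol` times the embedding scale, or after
#' `maxIters` iterations. Cell count and dimensionality are unchanged.
#'
#' @param embedding a [PCEmbedding] or cells x dims matrix.
#' @param batch per-cell batch (species/dataset) labels; >= 2 levels required.
#' @param nClusters number of soft clusters (default: `min(20, n/50)`,
#'   at least 2).
#' @param maxIters maximum correction iterations (default 20).
#' @param tol relative convergence tolerance on the largest cell shift.
#' @param minBatchCells batches smaller than this trigger a warning.
#' @param seed seed for the k-means initialization.
#' @return a [PCEmbedding] with corrected coordinates (same variance
#'   fractions and dimensionality as the input).
#' @export
harmonizeBatches <- function(embedding, batch, nClusters = NULL,
                             maxIters = 20, tol = 1e-3, minBatchCells = 20,
                             seed = 1) {
  isEmb <- is(embedding, "PCEmbedding")
  Z <- if (isEmb) pcCoords(embedding) else as.matrix(embedding)
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) < 2) stopCfg("need at least 2 batches")
  if (length(batch) != nrow(Z)) stopCfg("batch labels and cells misaligned")
  small <- names(which(table(batch) < minBatchCells))
  if (length(small))
    warning("small batch(es): ", paste(small, collapse = ", "))

  n <- nrow(Z)
  # global offset removal: translate each batch onto the overall mean
  gm <- colMeans(Z)
  for (b in levels(batch)) {
    ib <- batch == b
    Z[ib, ] <- sweep(Z[ib, , drop = FALSE], 2, colMeans(Z[ib, , drop = FALSE]) - gm)
  }
  if (is.null(nClusters))
    nClusters <- max(2L, min(20L, floor(n / 50)))
  km <- withSeed(seed, kmeans(Z, centers = nClusters, nstart = 3,
                              iter.max = 50))
  centers <- km$centers
  sigma2 <- mean(rowSums((Z - centers[km$cluster, , drop = FALSE])^2))
  sigma2 <- max(sigma2, 1e-8)
  scale <- sqrt(mean(rowSums(Z^2)))

  for (it in seq_len(maxIters)) {
    d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") -
      2 * Z %*% t(centers)
    R <- exp(-(d2 - matrixStats::rowMins(d2)) / (2 * sigma2))
    R <- R / rowSums(R)
    w <- colSums(R)
    mu <- crossprod(R, Z) / w

    delta <- matrix(0, n, ncol(Z))
    for (b in levels(batch)) {
      ib <- batch == b
      Rb <- R[ib, , drop = FALSE]
      wb <- colSums(Rb)
      mub <- mu # clusters with (almost) no mass in this batch: no correction
      ok <- wb > 1e-3
      mub[ok, ] <- crossprod(Rb[, ok, drop = FALSE], Z[ib, , drop = FALSE]) /
        wb[ok]
      delta[ib, ] <- Rb %*% (mu - mub)
    }
    Z <- Z + delta
    centers <- mu
    if (max(sqrt(rowSums(delta^2))) < tol * scale) break
  }
  if (isEmb)
    new("PCEmbedding", coords = Z,
        varianceFraction = varianceFraction(embedding),
        nPCs = nPCs(embedding))
  else Z
}

#' Match combined clusters to reference populations (80% rule)
#'
#' For each reference population, finds the combined cluster holding the
#' largest share of its cells; if that share reaches `threshold` the cluster
#' is named after the population. When two or more populations place
#' `threshold` of their cells in the same combined cluster, that cluster is
#' subclustered (a resolution scan restricted to its cells) and each
#' contested population is assigned to the subcluster holding the most of its
#' cells (processing populations by decreasing size, then lexicographic name;
#' a subcluster already claimed goes to the earlier-processed population and
#' the later one takes its next-best free subcluster). Populations that never
#' reach `threshold` are reported as "unmatched"; combined clusters with no
#' assignment keep their numeric id.
#'
#' @param combined factor of combined-analysis cluster labels, named by cell.
#' @param refPopulations factor of reference population labels, named by the
#'   reference dataset's cells (a subset of `names(combined)`).
#' @param embedding a [PCEmbedding] or coordinate matrix over all combined
#'   cells (rownames = cells); required if any cluster is contested.
#' @param threshold overlap threshold (default 0.8; the fraction is of the
#'   population's cells inside the cluster, and the comparison is `>=`).
#' @param speciesLabels optional per-cell species labels (named by cell) used
#'   to report each cluster's species composition.
#' @param subKnnK kNN size for the subcluster resolution scan.
#' @param seed seed for the subcluster scan.
#' @return a [ConservedMap].
#' @export
matchConserved <- function(combined, refPopulations, embedding = NULL,
                           threshold = 0.8, speciesLabels = NULL,
                           subKnnK = 20, seed = 1) {
  if (threshold <= 0.5 || threshold > 1)
    stopCfg("threshold must lie in (0.5, 1]")
  combined <- as.factor(combined)
  if (is.null(names(combined))) stopCfg("combined labels must be named by cell")
  refPopulations <- as.factor(refPopulations)
  cells <- names(refPopulations)
  if (is.null(cells) || !all(cells %in% names(combined)))
    stopCfg("input error: reference cells absent from the combined clustering")

  tab <- table(refPopulations, as.character(combined[cells]))
  share <- tab / rowSums(tab)
  pops <- rownames(tab)
  bestCl <- colnames(tab)[apply(share, 1, which.max)]
  bestShare <- apply(share, 1, max)
  names(bestCl) <- names(bestShare) <- pops

  comp <- function(cellsIn) {
    if (is.null(speciesLabels)) return(NA_character_)
    t <- table(speciesLabels[cellsIn])
    paste(sprintf("%s:%.2f", names(t), t / sum(t)), collapse = ",")
  }

  rows <- list()
  assignedClusters <- character(0)
  reached <- pops[bestShare >= threshold]
  for (cl in unique(bestCl[reached])) {
    contest <- reached[bestCl[reached] == cl]
    inCl <- names(combined)[combined == cl]
    if (length(contest) == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, population = contest, overlap = bestShare[contest],
        status = "matched", composition = comp(inCl))
      assignedClusters <- c(assignedClusters, cl)
      next
    }
    # contested: subcluster the cells of this combined cluster
    if (is.null(embedding))
      stopCfg("contested cluster ", cl, " requires an embedding to subcluster")
    coords <- if (is(embedding, "PCEmbedding")) pcCoords(embedding)
              else as.matrix(embedding)
    sub <- optimizeResolution(coords[inCl, , drop = FALSE],
                              knnK = min(subKnnK, length(inCl) - 1),
                              seed = seed)
    subLab <- setNames(paste0(cl, ".", clusterLabels(sub)), inCl)
    ord <- contest[order(-as.vector(table(refPopulations)[contest]), contest,
                         method = "radix")]
    taken <- character(0)
    for (p in ord) {
      pc <- intersect(cells[refPopulations == p], inCl)
      cnt <- sort(table(subLab[pc]), decreasing = TRUE)
      cnt <- cnt[!(names(cnt) %in% taken)]
      if (!length(cnt)) {
        rows[[length(rows) + 1]] <- data.frame(
          cluster = NA_character_, population = p,
          overlap = bestShare[p], status = "unmatched",
          composition = NA_character_)
        next
      }
      sc <- names(cnt)[1]
      taken <- c(taken, sc)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = sc, population = p,
        overlap = as.vector(cnt[1]) / sum(refPopulations == p),
        status = "contested-resolved",
        composition = comp(names(subLab)[subLab == sc]))
    }
    assignedClusters <- c(assignedClusters, cl)
  }
  for (p in setdiff(pops, reached))
    rows[[length(rows) + 1]] <- data.frame(
      cluster = NA_character_, population = p, overlap = bestShare[p],
      status = "unmatched", composition = NA_character_)
  for (cl in setdiff(levels(combined), assignedClusters))
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, population = NA_character_, overlap = NA_real_,
      status = "unassigned",
      composition = comp(names(combined)[combined == cl]))

  mapping <- do.call(rbind, rows)
  rownames(mapping) <- NULL
  new("ConservedMap", mapping = mapping, threshold = threshold)
}
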