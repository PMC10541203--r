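# SNN-graph Leiden clustering, silhouette-driven resolution scan, hierarchical
# cluster ordering, one-vs-rest marker detection and population naming.

# Shared-nearest-neighbor graph: kNN sets (including the cell itself) with
# Jaccard edge weights, pruned below `pruneJaccard` (Seurat's 1/15 default).
.snnGraph <- function(coords, knnK = 20, pruneJaccard = 1 / 15) {
  n <- nrow(coords)
  if (knnK >= n) stopCfg("size error: knnK (", knnK, ") must be < cells (", n, ")")
  nn <- BiocNeighbors::findKNN(coords, k = knnK)$index
  M <- Matrix::sparseMatrix(i = rep(seq_len(n), knnK + 1),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(M)
  sharedT <- as(as(shared, "generalMatrix"), "TsparseMatrix")
  jac <- sharedT@x / (2 * (knnK + 1) - sharedT@x)
  keep <- jac >= pruneJaccard & sharedT@i < sharedT@j
  igraph::graph_from_data_frame(
    data.frame(from = sharedT@i[keep] + 1L, to = sharedT@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

.leiden <- function(graph, resolution, seed) {
  mem <- withSeed(seed,
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity", resolution = resolution,
      weights = igraph::E(graph)$weight, n_iterations = 10)))
  # relabel clusters 1..K by decreasing size for stable, readable ids
  sizes <- sort(table(mem), decreasing = TRUE)
  factor(match(as.character(mem), names(sizes)),
         levels = seq_along(sizes))
}

#' Cluster cells once at a fixed resolution
#'
#' Builds a kNN graph on the PC coordinates, weights edges by the Jaccard
#' overlap of (self-inclusive) neighbor sets, and runs Leiden modularity
#' community detection at the given resolution. Deterministic given `seed`.
#'
#' @param embedding a [PCEmbedding] (or a cells x dims coordinate matrix).
#' @param resolution Leiden resolution parameter.
#' @param knnK neighbors for the SNN graph (default 20).
#' @param pruneJaccard minimum Jaccard weight for an SNN edge.
#' @param seed integer seed.
#' @return factor of cluster labels (named by barcode), levels ordered by
#'   decreasing cluster size.
#' @export
clusterOnce <- function(embedding, resolution, knnK = 20,
                        pruneJaccard = 1 / 15, seed = 1) {
  coords <- if (is(embedding, "PCEmbedding")) pcCoords(embedding) else embedding
  g <- .snnGraph(coords, knnK, pruneJaccard)
  labels <- .leiden(g, resolution, seed)
  names(labels) <- rownames(coords)
  labels
}

.meanSilhouette <- function(labels, d, idx) {
  li <- as.integer(labels)[idx]
  if (length(unique(li)) < 2) return(-Inf)
  mean(cluster::silhouette(li, d)[, "sil_width"])
}

#' Silhouette-maximizing resolution scan
#'
#' Evaluates Leiden clusterings at resolutions `resolutionStart`,
#' `resolutionStart + resolutionStep`, ... and scores each partition by its
#' mean silhouette width in PC space (Euclidean distance, subsampled to at
#' most `silhouetteMax` cells with a fixed seed). The scan stops once the
#' running maximum has not improved for `patience` consecutive steps or
#' `maxResolution` is reached; the argmax solution over all evaluated
#' resolutions is returned. Single-cluster partitions score `-Inf` and are
#' never selected while any multi-cluster partition exists.
#'
#' @inheritParams clusterOnce
#' @param resolutionStart,resolutionStep scan grid origin and spacing
#'   (defaults 0.2 and 0.2).
#' @param maxResolution hard cap on the scan (default 3).
#' @param patience consecutive non-improving steps before stopping (default 2).
#' @param silhouetteMax cell cap for the silhouette computation (default 5000).
#' @return a [ClusterSolution]; its `scanLog()` has one row per evaluated
#'   resolution.
#' @export
optimizeResolution <- function(embedding, knnK = 20, resolutionStart = 0.2,
                               resolutionStep = 0.2, maxResolution = 3,
                               patience = 2, pruneJaccard = 1 / 15,
                               silhouetteMax = 5000, seed = 1) {
  if (resolutionStart <= 0 || resolutionStep <= 0)
    stopCfg("resolution start and step must be > 0")
  if (patience < 1) stopCfg("patience must be >= 1")
  coords <- if (is(embedding, "PCEmbedding")) pcCoords(embedding) else embedding
  n <- nrow(coords)
  if (n < 3) stopCfg("size error: need at least 3 cells")
  g <- .snnGraph(coords, knnK, pruneJaccard)

  idx <- if (n > silhouetteMax)
    withSeed(stageSeed(seed, 7L), sort(sample.int(n, silhouetteMax)))
  else seq_len(n)
  d <- dist(coords[idx, , drop = FALSE])

  log <- data.frame(resolution = numeric(), nClusters = integer(),
                    meanSilhouette = numeric())
  best <- NULL
  sinceImprove <- 0L
  res <- resolutionStart
  while (res <= maxResolution + 1e-9) {
    labels <- .leiden(g, res, seed)
    sil <- .meanSilhouette(labels, d, idx)
    log[nrow(log) + 1L, ] <- list(res, nlevels(droplevels(labels)), sil)
    if (is.null(best) || sil > best$sil) {
      best <- list(labels = labels, res = res, sil = sil)
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
    }
    if (sinceImprove >= patience) break
    res <- res + resolutionStep
  }
  labels <- droplevels(best$labels)
  names(labels) <- rownames(coords)
  if (nlevels(labels) < 2)
    warning("all evaluated resolutions yielded a single cluster")
  new("ClusterSolution", labels = labels, resolution = best$res,
      meanSilhouette = best$sil, scanLog = log)
}

#' Hierarchically order clusters by centroid distance
#'
#' Average-linkage hierarchical clustering of the cluster centroids in PC
#' space (Euclidean distance); the returned order is the left-to-right leaf
#' order of the tree.
#'
#' @param embedding a [PCEmbedding] or coordinate matrix.
#' @param labels per-cell cluster labels.
#' @return a list: `order` (cluster ids in tree order) and `hclust` (the
#'   linkage object, NULL for a single cluster).
#' @export
orderClusters <- function(embedding, labels) {
  coords <- if (is(embedding, "PCEmbedding")) pcCoords(embedding) else embedding
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    return(list(order = levels(labels), hclust = NULL))
  cents <- rowsum(coords, labels) / as.vector(table(labels))
  hc <- hclust(dist(cents), method = "average")
  list(order = rownames(cents)[hc$order], hclust = hc)
}

# Vectorized two-sided Mann-Whitney test with normal approximation, tie
# correction and continuity correction (matching wilcox.test(exact = FALSE)).
.rankSumRows <- function(m, inGroup) {
  n <- ncol(m)
  n1 <- sum(inGroup)
  n2 <- n - n1
  ranks <- matrixStats::rowRanks(m, ties.method = "average")
  W <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
  tieSum <- apply(m, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tieSum / (n * (n - 1))))
  mu <- n1 * n2 / 2
  z <- (abs(W - mu) - 0.5) / sigma
  z[sigma == 0] <- 0
  pmin(1, 2 * pnorm(-z))
}

#' One-vs-rest marker detection per cluster
#'
#' For each cluster, genes detected in at least `minFrac` of its cells with
#' `|log2FC| >= minLog2fc` versus all other cells are tested with a
#' rank-sum (Mann-Whitney) test on log-expression; p-values are BH-adjusted
#' across the tested genes within each cluster. Fold changes are computed on
#' de-logged mean expression with a pseudocount of 1.
#'
#' @param x a normalized `SingleCellExperiment` (with `logcounts`).
#' @param labels per-cell cluster labels.
#' @param minFrac minimum in-cluster detection fraction (default 0.25).
#' @param minLog2fc minimum absolute log2 fold change (default 0.25).
#' @return data.frame with columns cluster, gene, log2fc, fracIn, fracOut,
#'   p, fdr; ordered by cluster then p.
#' @export
findClusterMarkers <- function(x, labels, minFrac = 0.25, minLog2fc = 0.25) {
  logc <- .logcounts(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopCfg("need at least 2 clusters")
  det <- logc > 0
  expc <- expm1(logc)
  out <- vector("list", nlevels(labels))
  for (k in seq_len(nlevels(labels))) {
    cl <- levels(labels)[k]
    inG <- labels == cl
    if (sum(inG) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    fracIn <- Matrix::rowMeans(det[, inG, drop = FALSE])
    fracOut <- Matrix::rowMeans(det[, !inG, drop = FALSE])
    mIn <- Matrix::rowMeans(expc[, inG, drop = FALSE])
    mOut <- Matrix::rowMeans(expc[, !inG, drop = FALSE])
    l2fc <- log2(mIn + 1) - log2(mOut + 1)
    cand <- which(fracIn >= minFrac & abs(l2fc) >= minLog2fc)
    if (!length(cand)) next
    p <- .rankSumRows(as.matrix(logc[cand, , drop = FALSE]), inG)
    df <- data.frame(cluster = cl, gene = rownames(logc)[cand],
                     log2fc = l2fc[cand], fracIn = fracIn[cand],
                     fracOut = fracOut[cand], p = p,
                     fdr = p.adjust(p, "BH"), row.names = NULL)
    out[[k]] <- df[order(df$p, -df$log2fc), ]
  }
  do.call(rbind, out)
}

#' Name clusters by unique markers or neurochemical identity
#'
#' A cluster is named after its top unique marker: the highest-log2FC gene
#' that is a significant marker (FDR < `fdrCut`, positive fold change,
#' detection outside the cluster <= `maxFracOut`) of that cluster and of no
#' other. Clusters without a unique marker are labeled by neurochemical
#' identity: GABA if the mean log-expression of `gabaGene` exceeds that of
#' `gluGene`, else GLU; the first GABA-group cluster in tree order is "GABA"
#' and later ones "GABA2", ..., while GLU-group clusters are numbered "GLU1",
#' "GLU2", ... If neither indicator gene is present the cluster is named
#' "UNK-n" (and a message is emitted).
#'
#' @param markers marker table from [findClusterMarkers()].
#' @param x the normalized `SingleCellExperiment` (for indicator expression).
#' @param labels per-cell cluster labels.
#' @param treeOrder cluster ids in dendrogram order (from [orderClusters()]);
#'   defaults to label levels.
#' @param fdrCut FDR threshold for a usable marker (default 0.05).
#' @param maxFracOut maximum outside-detection fraction of a unique marker.
#' @param gabaGene,gluGene indicator gene ids (defaults Slc32a1, Slc17a6).
#' @return named character vector: cluster id -> population name.
#' @export
nameClusters <- function(markers, x, labels, treeOrder = NULL,
                         fdrCut = 0.05, maxFracOut = 0.1,
                         gabaGene = "Slc32a1", gluGene = "Slc17a6") {
  labels <- droplevels(as.factor(labels))
  cl <- levels(labels)
  if (is.null(treeOrder)) treeOrder <- cl
  logc <- .logcounts(x)

  sig <- markers[!is.na(markers$fdr) & markers$fdr < fdrCut &
                 markers$fracOut <= maxFracOut & markers$log2fc > 0, ]
  markCount <- table(sig$gene)
  uniqueGenes <- names(markCount)[markCount == 1]
  sigU <- sig[sig$gene %in% uniqueGenes, ]

  nm <- setNames(rep(NA_character_, length(cl)), cl)
  for (k in cl) {
    cand <- sigU[sigU$cluster == k, ]
    if (nrow(cand)) {
      cand <- cand[order(-cand$log2fc, cand$gene, method = "radix"), ]
      nm[k] <- cand$gene[1]
    }
  }

  unnamed <- treeOrder[is.na(nm[treeOrder])]
  if (length(unnamed)) {
    haveInd <- c(gabaGene, gluGene) %in% rownames(logc)
    groups <- character(0)
    for (k in unnamed) {
      if (!all(haveInd)) {
        groups[k] <- "UNK"
        next
      }
      inG <- labels == k
      g1 <- mean(logc[gabaGene, inG])
      g2 <- mean(logc[gluGene, inG])
      groups[k] <- if (g1 > g2) "GABA" else "GLU"
    }
    if (any(groups == "UNK"))
      message("indicator genes missing: ", sum(groups == "UNK"),
              " cluster(s) named UNK-n")
    for (grp in unique(groups)) {
      ks <- names(groups)[groups == grp]
      nm[ks] <- switch(grp,
        GABA = ifelse(seq_along(ks) == 1, "GABA",
                      paste0("GABA", seq_along(ks))),
        GLU = paste0("GLU", seq_along(ks)),
        paste0("UNK-", seq_along(ks)))
    }
  }
  nm
}
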