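# Quality control: gene/cell retention thresholds and simulated-doublet
# scoring with the cluster-median removal rule.

#' Filter genes and cells by detection thresholds
#'
#' Genes detected (count > 0) in at least `minCellsPerGene` cells are retained
#' first; then cells with at least `minGenesPerCell` detected genes among the
#' retained genes are kept. Both thresholds are inclusive ("at least").
#'
#' @param x a `SingleCellExperiment` with a `counts` assay.
#' @param minCellsPerGene minimum number of cells a gene must be detected in
#'   (default 5).
#' @param minGenesPerCell minimum number of detected genes per cell
#'   (default 600).
#' @return a list: `sce` (the filtered object) and `report` (named integer
#'   vector of cell/gene counts before and after each step).
#' @export
filterMatrix <- function(x, minCellsPerGene = 5, minGenesPerCell = 600) {
  if (minCellsPerGene < 1 || minGenesPerCell < 1)
    stopCfg("thresholds must be strictly positive")
  cnt <- .counts(x)
  if (nrow(cnt) == 0 || ncol(cnt) == 0)
    stopCfg("empty result: input matrix has no cells or genes")
  det <- cnt > 0
  geneKeep <- Matrix::rowSums(det) >= minCellsPerGene
  det <- det[geneKeep, , drop = FALSE]
  cellKeep <- Matrix::colSums(det) >= minGenesPerCell
  if (!any(cellKeep))
    stopCfg("empty result: no cell has >= ", minGenesPerCell,
            " detected genes among retained genes")
  report <- c(genesIn = nrow(cnt), cellsIn = ncol(cnt),
              genesRetained = sum(geneKeep), cellsRetained = sum(cellKeep))
  list(sce = x[geneKeep, cellKeep], report = report)
}

#' Score cells for doublet likelihood with simulated doublets
#'
#' Simulates `nSimDoublets` synthetic doublets as sums of random observed cell
#' pairs, co-embeds observed and simulated cells in the top `nPCs` principal
#' components of the log-normalized union matrix, and scores each observed
#' cell by the fraction of simulated doublets among its `knnK` nearest
#' neighbors, rescaled to [0, 1] as the excess over the null simulated
#' fraction: `score = max(0, (f - rho) / (1 - rho))` with
#' `rho = nSim / (nObs + nSim)`.
#'
#' Simulated homotypic doublets carry a weak but usable signal (a summed
#' profile has lower relative dispersion than a singlet), so the default
#' simulates two doublets per observed cell: the denser simulated
#' neighborhoods make that signal detectable alongside the strong
#' heterotypic one.
#'
#' @param x a `SingleCellExperiment` (filtered).
#' @param nSimDoublets number of simulated doublets (default: two per cell).
#' @param knnK neighborhood size (default `round(0.5 * sqrt(n))` over the
#'   union, the usual heuristic for this scorer).
#' @param nPCs number of principal components for the co-embedding.
#' @param seed integer seed.
#' @param details if TRUE, return a list with the scores and the observed
#'   cells' co-embedding coordinates (useful for the provisional clustering
#'   pass of the removal rule).
#' @return named numeric vector of per-cell scores in [0, 1]; or, with
#'   `details = TRUE`, a list with elements `scores` and `coords`.
#' @export
scoreDoublets <- function(x, nSimDoublets = NULL, knnK = NULL, nPCs = 30,
                          seed = 1, details = FALSE) {
  cnt <- .counts(x)
  n <- ncol(cnt)
  if (is.null(nSimDoublets)) nSimDoublets <- 2L * n
  nTot <- n + nSimDoublets
  if (is.null(knnK)) knnK <- max(5L, round(0.5 * sqrt(nTot)))
  if (n < 2 * knnK) stopCfg("too few cells (", n, ") for knnK = ", knnK)

  withSeed(seed, {
    p1 <- sample.int(n, nSimDoublets, replace = TRUE)
    shift <- sample.int(n - 1, nSimDoublets, replace = TRUE)
    p2 <- ((p1 - 1 + shift) %% n) + 1  # distinct from p1 by construction
    sim <- cnt[, p1, drop = FALSE] + cnt[, p2, drop = FALSE]
    union <- cbind(cnt, sim)

    # library-size normalize + log1p, PCA on centered genes
    libs <- Matrix::colSums(union)
    libs[libs == 0] <- 1
    norm <- log1p(Matrix::t(Matrix::t(union) * (mean(libs) / libs)))
    # degenerate input: if all normalized profiles coincide there is no
    # geometry to score against; every cell gets the null score
    gv <- Matrix::rowMeans(norm^2) - Matrix::rowMeans(norm)^2
    degenerate <- sum(gv) < 1e-10 * max(1, sum(Matrix::rowMeans(norm)^2))
    if (degenerate) {
      message("degenerate input: all cells identical after normalization; ",
              "doublet scores set to 0")
      scores <- setNames(rep(0, n), colnames(cnt))
      coords <- matrix(0, nTot, 1)
    } else {
      nPCs <- min(nPCs, nTot - 1L, nrow(norm) - 1L)
      sv <- irlba::irlba(Matrix::t(norm), nv = nPCs,
                         center = Matrix::rowMeans(norm))
      coords <- sv$u %*% diag(sv$d, nPCs, nPCs)

      nn <- BiocNeighbors::findKNN(coords, k = knnK,
                                   subset = seq_len(n))$index
      isSim <- nn > n
      f <- rowMeans(isSim)
      rho <- nSimDoublets / nTot
      scores <- pmin(1, pmax(0, (f - rho) / (1 - rho)))
      names(scores) <- colnames(cnt)
    }
    if (details) {
      obs <- coords[seq_len(n), , drop = FALSE]
      rownames(obs) <- colnames(cnt)
      list(scores = scores, coords = obs)
    } else {
      scores
    }
  })
}

#' Apply the doublet removal rule
#'
#' Removes every cell in a cluster whose median doublet score is strictly
#' greater than `cut`, plus any remaining individual cell with a score
#' strictly greater than `cut`.
#'
#' @param scores per-cell doublet scores.
#' @param clusters per-cell provisional cluster labels, aligned with `scores`.
#' @param cut removal threshold (default 0.3, strict inequality).
#' @return logical mask of retained cells (TRUE = keep), named by cell.
#' @export
applyDoubletFilter <- function(scores, clusters, cut = 0.3) {
  if (length(scores) != length(clusters))
    stopCfg("scores and clusters must be aligned")
  med <- tapply(scores, clusters, median)
  inBadCluster <- as.vector(med[as.character(clusters)] > cut)
  keep <- !(inBadCluster | scores > cut)
  names(keep) <- names(scores)
  keep
}
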