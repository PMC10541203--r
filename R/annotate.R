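# Reference label projection: CCA-style joint embedding of query and
# reference, per-cell per-type similarity scores, and the 15-cell
# neighborhood vote.

.hvgUnion <- function(qx, rx, shared, nTopGenes) {
  nTop <- min(nTopGenes, length(shared))
  hq <- selectVariableGenes(qx[shared, ], nTop = nTop)
  hr <- selectVariableGenes(rx[shared, ], nTop = nTop)
  union(hq, hr)
}

#' Transfer reference cell-type labels onto query cells
#'
#' Builds a joint low-rank embedding of the query and reference on shared
#' variable genes: both scaled matrices are cross-decomposed with a truncated
#' SVD of their gene-space cross-product (a CCA-style alignment), and rows are
#' L2-normalized so distances reflect cosine similarity. Each query cell gets
#' a per-type score: the mean similarity of its `knnKRef` nearest reference
#' cells of that type (0 for types absent from the neighborhood). The final
#' label of a cell is the type with the highest score summed over the cell
#' and its `voteK - 1` nearest query-side neighbors; ties break by
#' lexicographic type name. The vote fraction is the share of those `voteK`
#' cells whose own best type equals the winner.
#'
#' @param query,reference `SingleCellExperiment`s (or count matrices); both
#'   are normalized internally if no `logcounts` assay is present.
#' @param refTypes per-reference-cell type labels.
#' @param voteK neighborhood size of the vote, the cell itself included
#'   (default 15: the cell and its 14 nearest neighbors).
#' @param nSharedPCs rank of the joint embedding (default 20).
#' @param knnKRef reference neighbors used for the per-type scores.
#' @param nTopGenes variable genes taken from each dataset (union used).
#' @param seed integer seed for the truncated SVD.
#' @return a [TypeAssignment].
#' @export
transferLabels <- function(query, reference, refTypes, voteK = 15,
                           nSharedPCs = 20, knnKRef = 20, nTopGenes = 2000,
                           seed = 1) {
  if (voteK < 1) stopCfg("voteK must be >= 1")
  refTypes <- as.factor(refTypes)
  if (nlevels(refTypes) < 2) stopCfg("reference needs at least 2 types")
  small <- names(which(table(refTypes) < 3))
  if (length(small))
    warning("reference type(s) with < 3 cells: ", paste(small, collapse = ", "))

  norm <- function(x) {
    if (is(x, "SummarizedExperiment") &&
        "logcounts" %in% SummarizedExperiment::assayNames(x)) x
    else normalizeCounts(x, method = "libsize")
  }
  qx <- norm(query)
  rx <- norm(reference)
  shared <- intersect(rownames(.logcounts(qx)), rownames(.logcounts(rx)))
  if (!length(shared)) stopCfg("no shared genes between query and reference")
  hvg <- .hvgUnion(qx, rx, shared, nTopGenes)

  Sq <- scaleCenter(qx, hvg) # genes x query cells
  Sr <- scaleCenter(rx, hvg)
  d <- min(nSharedPCs, ncol(Sq) - 1L, ncol(Sr) - 1L, length(hvg) - 1L)
  cc <- withSeed(seed, irlba::irlba(crossprod(Sq, Sr), nv = d))
  # weight dimensions by singular value, then L2-normalize rows so that
  # Euclidean neighbor distances reflect cosine similarity
  U <- cc$u %*% diag(cc$d, d, d) # query cells x d
  V <- cc$v %*% diag(cc$d, d, d) # reference cells x d
  U <- U / sqrt(pmax(rowSums(U^2), 1e-12))
  V <- V / sqrt(pmax(rowSums(V^2), 1e-12))

  nq <- nrow(U)
  types <- levels(refTypes)
  knnKRef <- min(knnKRef, nrow(V))
  nn <- BiocNeighbors::queryKNN(V, U, k = knnKRef)
  sim <- 1 - nn$distance^2 / 2 # cosine similarity on unit rows
  tIdx <- matrix(as.integer(refTypes)[nn$index], nq, knnKRef)

  i <- rep(seq_len(nq), knnKRef)
  sums <- as.matrix(Matrix::sparseMatrix(i = i, j = as.vector(tIdx),
                                         x = as.vector(sim),
                                         dims = c(nq, length(types))))
  cnts <- as.matrix(Matrix::sparseMatrix(i = i, j = as.vector(tIdx), x = 1,
                                         dims = c(nq, length(types))))
  scores <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  colnames(scores) <- types

  own <- max.col(scores, ties.method = "first") # per-cell best type
  if (voteK > 1) {
    k <- min(voteK - 1L, nq - 1L)
    qnn <- BiocNeighbors::findKNN(U, k = k)$index
    group <- cbind(seq_len(nq), qnn)
  } else {
    group <- matrix(seq_len(nq), ncol = 1)
  }
  summed <- matrix(0, nq, length(types), dimnames = list(NULL, types))
  for (j in seq_len(ncol(group)))
    summed <- summed + scores[group[, j], , drop = FALSE]
  win <- max.col(summed, ties.method = "first") # types sorted: lexicographic
  voteFrac <- rowMeans(matrix(own[group] == win[row(group)], nrow = nq))

  barcodes <- colnames(.logcounts(qx))
  rownames(summed) <- barcodes
  new("TypeAssignment",
      type = setNames(types[win], barcodes),
      voteFraction = setNames(pmax(voteFrac, 1 / ncol(group)), barcodes),
      scores = summed)
}

#' Drop cells not assigned to a whitelisted (neuronal) type
#'
#' @param assignment a [TypeAssignment].
#' @param whitelist reference type names to retain.
#' @return logical mask of retained cells (TRUE = keep), named by barcode.
#' @export
dropNonneuronal <- function(assignment, whitelist) {
  if (length(whitelist) == 0)
    stopCfg("configuration error: empty neuronal whitelist")
  keep <- assignedType(assignment) %in% whitelist
  if (!any(keep))
    warning("whitelist is disjoint from assigned types; all cells removed")
  names(keep) <- names(assignedType(assignment))
  keep
}
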