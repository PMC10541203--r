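# PCA with elbow-based selection of the number of retained components.

#' Principal-component embedding with elbow-based dimension retention
#'
#' Computes `pcMax + 1` principal components of the scaled matrix (cells as
#' observations) and retains the smallest `k` in `[pcMin, pcMax]` such that
#' the drop in variance fraction from PC `k` to PC `k + 1` falls below
#' `elbowTol`; if no such elbow exists, `pcMax` components are retained.
#' Each PC is oriented so its largest-magnitude gene loading is positive.
#'
#' @param scaled genes x cells matrix from [scaleCenter()].
#' @param pcMin,pcMax bounds on the number of retained PCs (defaults 15, 30).
#' @param elbowTol variance-fraction drop below which the scree curve is
#'   considered flat (default 1e-3).
#' @param seed seed for the truncated SVD initialization.
#' @return a [PCEmbedding].
#' @export
pcaElbow <- function(scaled, pcMin = 15, pcMax = 30, elbowTol = 1e-3,
                     seed = 1) {
  X <- t(scaled) # cells x genes
  n <- nrow(X)
  if (pcMin < 1 || pcMax < pcMin) stopCfg("need 1 <= pcMin <= pcMax")
  if (n <= pcMax)
    stopCfg("size error: need more cells (", n, ") than pcMax (", pcMax, ")")
  k <- min(pcMax + 1L, n - 1L, ncol(X) - 1L)
  if (k < pcMin) stopCfg("size error: too few genes for pcMin = ", pcMin)

  ctr <- colMeans(X)
  sv <- withSeed(seed, irlba::irlba(X, nv = k, center = ctr))
  # deterministic orientation: largest-magnitude loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  totalVar <- sum(matrixStats::colVars(X))
  vf <- (sv$d^2 / (n - 1)) / totalVar

  nPCs <- min(pcMax, k)
  if (k > pcMin) {
    drops <- vf[-length(vf)] - vf[-1]
    cand <- seq(pcMin, min(pcMax, k - 1))
    hit <- cand[drops[cand] < elbowTol]
    if (length(hit)) nPCs <- hit[1]
  }
  coords <- sv$u[, seq_len(nPCs), drop = FALSE] %*%
    diag(sv$d[seq_len(nPCs)], nPCs, nPCs)
  rownames(coords) <- colnames(scaled)
  colnames(coords) <- paste0("PC", seq_len(nPCs))
  new("PCEmbedding", coords = coords, varianceFraction = vf[seq_len(nPCs)],
      nPCs = as.integer(nPCs))
}
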