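# Normalization (pooled size-factor deconvolution), variable-gene selection
# and per-gene scaling.

# Simplified one-round pooled deconvolution. Cells are ordered by library
# size on a ring; each of the n pools sums `poolSize` consecutive cells. The
# median ratio of pooled counts to a reference pseudo-cell estimates the sum
# of the pooled cells' factors; the resulting linear system is solved by
# ridge-regularized least squares, with weak per-cell library-size equations
# guaranteeing identifiability.
.pooledSizeFactors <- function(cnt, poolSize = 21, regWeight = 0.1) {
  n <- ncol(cnt)
  libs <- Matrix::colSums(cnt)
  if (any(libs == 0))
    stopCfg("cell with zero total count: run filterMatrix() first")
  s <- min(poolSize, n)
  ord <- order(libs)
  ring <- c(ord, ord[seq_len(s - 1)])

  ref <- as.numeric(Matrix::rowSums(cnt) / sum(libs) * mean(libs))
  pos <- ref > 0

  # pool incidence matrix P (pools x cells)
  ii <- rep(seq_len(n), each = s)
  jj <- as.vector(vapply(seq_len(n), function(j) ring[j:(j + s - 1)],
                         integer(s)))
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  B <- as.matrix(cnt[pos, , drop = FALSE] %*% Matrix::t(P))  # genes x pools
  ratio <- apply(B / ref[pos], 2, median)

  lambdaBar <- mean(ratio) / s
  target <- libs / mean(libs) * lambdaBar
  M <- Matrix::crossprod(P) + Matrix::Diagonal(n, regWeight^2)
  rhs <- as.numeric(Matrix::crossprod(P, ratio)) + regWeight^2 * target
  lambda <- as.numeric(Matrix::solve(M, rhs))
  if (any(lambda <= 0)) {
    warning("non-positive deconvolved factors; falling back to library size")
    lambda <- pmax(lambda, 1e-8)
    lambda[lambda <= 1e-8] <- (libs / mean(libs))[lambda <= 1e-8]
  }
  lambda / mean(lambda)
}

#' Normalize counts and add a log-expression assay
#'
#' Computes per-cell size factors (mean 1) and stores
#' `logcounts = log1p(counts / sizeFactor)`. The default `"pooled"` method is
#' a single-round pooled deconvolution (pool sums regressed against a
#' reference pseudo-cell); `"libsize"` uses plain library-size factors.
#'
#' @param x a filtered `SingleCellExperiment`.
#' @param method `"pooled"` (default) or `"libsize"`.
#' @param poolSize number of cells per pool for the pooled method.
#' @return `x` with a `logcounts` assay and size factors set.
#' @export
normalizeCounts <- function(x, method = c("pooled", "libsize"),
                            poolSize = 21) {
  method <- match.arg(method)
  cnt <- .counts(x)
  libs <- Matrix::colSums(cnt)
  if (any(libs == 0))
    stopCfg("cell with zero total count: run filterMatrix() first")
  sf <- switch(method,
    pooled = .pooledSizeFactors(cnt, poolSize),
    libsize = libs / mean(libs))
  logc <- log1p(Matrix::t(Matrix::t(cnt) / sf))
  if (!is(x, "SingleCellExperiment"))
    x <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = cnt))
  SummarizedExperiment::assay(x, "logcounts") <- logc
  SingleCellExperiment::sizeFactors(x) <- sf
  x
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by the variance of clipped z-scores under a mean-variance
#' trend: a loess curve of log10 variance on log10 mean of the raw counts
#' gives each gene an expected standard deviation; counts are standardized
#' against it, clipped at `sqrt(n cells)`, and the variance of the clipped
#' values is the ranking statistic. Ties are broken by lexicographic gene id.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay, or a counts matrix.
#' @param nTop number of genes to return (default 2000).
#' @param span loess span for the mean-variance trend.
#' @return character vector of `nTop` gene ids, ranked.
#' @export
selectVariableGenes <- function(x, nTop = 2000, span = 0.3) {
  cnt <- .counts(x)
  if (nTop > nrow(cnt))
    stopCfg("nTop (", nTop, ") exceeds the number of genes (", nrow(cnt), ")")
  n <- ncol(cnt)
  mu <- Matrix::rowMeans(cnt)
  v <- Matrix::rowMeans(cnt^2) - mu^2
  v <- v * n / max(1, n - 1)

  stdVar <- numeric(nrow(cnt))
  fit <- mu > 0 & v > 0
  if (sum(fit) >= 10 && length(unique(mu[fit])) >= 5) {
    tr <- loess(log10(v[fit]) ~ log10(mu[fit]), span = span, degree = 2)
    sdExp <- numeric(nrow(cnt))
    sdExp[fit] <- sqrt(10^predict(tr))
    sdExp[!fit & mu > 0] <- sqrt(pmax(v[!fit & mu > 0], mu[!fit & mu > 0]))
    use <- sdExp > 0
    m <- as.matrix(cnt[use, , drop = FALSE])
    clipMax <- sqrt(n)
    z <- (m - mu[use]) / sdExp[use]
    z[z > clipMax] <- clipMax
    z[z < -clipMax] <- -clipMax
    stdVar[use] <- matrixStats::rowVars(z)
  } else {
    stdVar <- as.numeric(v) # too few genes for a trend: raw variance
  }
  ids <- rownames(cnt)
  ord <- order(-stdVar, ids, method = "radix")
  ids[ord][seq_len(nTop)]
}

#' Center and scale genes, with clipping
#'
#' Scales each selected gene of the log-expression matrix to mean 0 and unit
#' variance, clipping values to `[-clip, clip]`. Zero-variance genes are left
#' at 0 and reported via the `"zeroVarianceGenes"` attribute (and a message).
#'
#' @param x a normalized `SingleCellExperiment` (with `logcounts`) or a matrix.
#' @param genes gene ids to scale (default: all).
#' @param clip absolute value cap after scaling (default 10).
#' @return dense numeric matrix, genes x cells.
#' @export
scaleCenter <- function(x, genes = NULL, clip = 10) {
  logc <- .logcounts(x)
  if (is.null(genes)) genes <- rownames(logc)
  missing <- setdiff(genes, rownames(logc))
  if (length(missing))
    stopCfg("genes not present in the matrix: ", paste(head(missing, 5),
            collapse = ", "))
  m <- as.matrix(logc[genes, , drop = FALSE])
  mu <- rowMeans(m)
  sdv <- matrixStats::rowSds(m)
  zero <- sdv == 0 | !is.finite(sdv)
  sdv[zero] <- 1
  s <- (m - mu) / sdv
  s[zero, ] <- 0
  s[s > clip] <- clip
  s[s < -clip] <- -clip
  if (any(zero))
    message(sum(zero), " zero-variance gene(s) left at 0")
  attr(s, "zeroVarianceGenes") <- rownames(m)[zero]
  s
}
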