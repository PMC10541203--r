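# TRAP-seq differential expression (paired bead/sup enrichment; leptin
# response on bead samples) and PC1 signature scoring.

#' Negative-binomial differential expression for TRAP-seq designs
#'
#' Fits per-gene negative-binomial GLMs with DESeq2 under one of the two
#' study designs: `"enrichment"` tests bead vs sup with a per-pair effect
#' (`~ pair + fraction`, all samples), `"leptin"` tests leptin vs PBS with a
#' genotype covariate (`~ genotype + treatment`, bead samples only). Wald
#' p-values are BH-adjusted across genes whose mean count reaches
#' `filterFloor` (others get `padj = NA`).
#'
#' @param counts integer matrix, genes x samples.
#' @param samples data.frame with columns `sample`, `pair`,
#'   `fraction` ("bead"/"sup"), `genotype`, `treatment` ("PBS"/"leptin");
#'   rows aligned with `colnames(counts)` via `sample`.
#' @param design `"enrichment"` or `"leptin"`.
#' @param filterFloor minimum mean count for a gene to enter the BH
#'   correction (default 1).
#' @return data.frame: gene, baseMean, log2FoldChange, lfcSE, pvalue, padj.
#' @export
fitTrapDE <- function(counts, samples, design = c("enrichment", "leptin"),
                      filterFloor = 1) {
  design <- match.arg(design)
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) stopCfg("samples table does not cover all columns")
  if (any(counts < 0)) stopCfg("counts must be nonnegative")

  if (design == "enrichment") {
    ok <- vapply(split(samples$fraction, samples$pair),
                 function(f) setequal(f, c("bead", "sup")), TRUE)
    if (!all(ok))
      stopCfg("design error: every pair needs exactly one bead and one sup sample")
    cd <- data.frame(pair = factor(samples$pair),
                     fraction = factor(samples$fraction,
                                       levels = c("sup", "bead")))
    if (nlevels(cd$pair) < 2)
      stopCfg("design error: paired model needs >= 2 pairs")
    fm <- ~ pair + fraction
    coef <- "fraction_bead_vs_sup"
  } else {
    keep <- samples$fraction == "bead"
    counts <- counts[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    cd <- data.frame(genotype = factor(samples$genotype),
                     treatment = factor(samples$treatment,
                                        levels = c("PBS", "leptin")))
    if (any(table(cd$treatment) < 2))
      stopCfg("design error: need >= 2 bead samples per treatment level")
    fm <- if (nlevels(cd$genotype) >= 2) ~ genotype + treatment else ~ treatment
    coef <- "treatment_leptin_vs_PBS"
  }

  dds <- tryCatch(
    DESeq2::DESeqDataSetFromMatrix(countData = round(counts),
                                   colData = cd, design = fm),
    error = function(e) stopCfg("design error: ", conditionMessage(e)))
  fit <- tryCatch(
    DESeq2::DESeq(dds, quiet = TRUE),
    error = function(e) DESeq2::DESeq(dds, quiet = TRUE, fitType = "mean"))
  res <- DESeq2::results(fit, name = coef, independentFiltering = FALSE)

  out <- data.frame(gene = rownames(res), baseMean = res$baseMean,
                    log2FoldChange = res$log2FoldChange, lfcSE = res$lfcSE,
                    pvalue = res$pvalue, padj = NA_real_,
                    row.names = NULL)
  tested <- out$baseMean >= filterFloor & !is.na(out$pvalue)
  out$padj[tested] <- p.adjust(out$pvalue[tested], "BH")
  out
}

#' Build a signed leptin-response signature from a DE result
#'
#' Genes with `padj < alpha` from the leptin design, signed by the direction
#' of the leptin fold change.
#'
#' @param de data.frame from [fitTrapDE()] (leptin design).
#' @param alpha FDR threshold (default 0.05).
#' @return a [LeptinSignature].
#' @export
buildSignature <- function(de, alpha = 0.05) {
  hit <- !is.na(de$padj) & de$padj < alpha & de$log2FoldChange != 0
  if (!any(hit))
    stopCfg("empty signature at alpha = ", alpha, "; consider raising alpha")
  new("LeptinSignature", genes = de$gene[hit],
      sign = sign(de$log2FoldChange[hit]), alpha = alpha)
}

#' Score cells and populations against a leptin-response signature
#'
#' Restricts expression to the signature genes, scales each gene, and
#' projects cells onto the first principal component of the restricted
#' matrix. The PC sign is aligned so that the sum of (gene loading x
#' signature sign) is positive, making higher scores mean stronger
#' leptin-like regulation. Both the signed per-cell coordinate (the default
#' headline score) and its absolute value (the literal PC1 "magnitude") are
#' returned, with per-population means of each.
#'
#' @param x a normalized `SingleCellExperiment` (with `logcounts`) or a
#'   genes x cells expression matrix.
#' @param signature a [LeptinSignature].
#' @param populations optional per-cell population labels for the
#'   per-population aggregate.
#' @param pseudobulk if TRUE, population-mean expression profiles are scored
#'   instead of single cells (per-population score only).
#' @return a list: `perCell`, `perCellAbs`, `perPopulation`,
#'   `perPopulationAbs`, `loadings`, `genesUsed`.
#' @export
scoreSignature <- function(x, signature, populations = NULL,
                           pseudobulk = FALSE) {
  m <- .logcounts(x)
  sg <- signatureSigns(signature)
  genes <- intersect(rownames(m), names(sg))
  if (length(genes) < 2)
    stopCfg("fewer than 2 signature genes present in the matrix")
  mm <- as.matrix(m[genes, , drop = FALSE])

  if (pseudobulk) {
    if (is.null(populations)) stopCfg("pseudobulk scoring needs populations")
    mm <- t(rowsum(t(mm), populations) / as.vector(table(populations)))
  }
  sdv <- matrixStats::rowSds(mm)
  use <- sdv > 0
  if (sum(use) < 2)
    stopCfg("scoring error: signature genes have zero variance")
  S <- (mm[use, , drop = FALSE] - rowMeans(mm[use, , drop = FALSE])) /
    sdv[use]
  genes <- genes[use]

  sv <- svd(t(S), nu = 1, nv = 1)
  v <- sv$v[, 1]
  if (sum(v * sg[genes]) < 0) v <- -v
  perCell <- as.numeric(t(S) %*% v)
  names(perCell) <- colnames(S)
  loadings <- setNames(v, genes)

  if (pseudobulk) {
    return(list(perCell = NULL, perCellAbs = NULL,
                perPopulation = perCell, perPopulationAbs = abs(perCell),
                loadings = loadings, genesUsed = genes))
  }
  perPop <- perPopAbs <- NULL
  if (!is.null(populations)) {
    perPop <- tapply(perCell, populations, mean)
    perPopAbs <- tapply(abs(perCell), populations, mean)
  }
  list(perCell = perCell, perCellAbs = abs(perCell),
       perPopulation = perPop, perPopulationAbs = perPopAbs,
       loadings = loadings, genesUsed = genes)
}
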