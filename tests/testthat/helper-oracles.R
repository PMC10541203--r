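# Shared fixtures and independent oracles. Expensive fixtures are computed
# once per session and cached.

suppressPackageStartupMessages(library(SingleCellExperiment))

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# rank-based AUROC, independent of any package scorer
aurocOracle <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive)
  nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

ariOracle <- function(a, b) mclust::adjustedRandIndex(a, b)

# small atlas used by several module tests (not the acceptance conditions)
smallAtlas <- function() cachedFixture("smallAtlas",
  simulateAtlas(nPopulations = 4, cellsPerPopulation = 100, nGenes = 800,
                markersPerPopulation = 20, markerLog2fc = 3, seed = 101))

# the acceptance-criteria atlas: 6 populations x 300 cells, 2000 genes,
# 40 markers per population at log2FC 3, with 10% injected doublets,
# taken through QC -> doublet scoring -> embedding -> resolution scan once
criterionPipeline <- function(seed = 1) cachedFixture(
  paste0("criterionPipeline", seed), {
  sce <- simulateAtlas(nPopulations = 6, cellsPerPopulation = 300,
                       nGenes = 2000, markersPerPopulation = 40,
                       markerLog2fc = 3, seed = seed)
  sce <- injectDoublets(sce, 0.1, seed = seed + 1)
  filtered <- filterMatrix(sce)$sce
  det <- scoreDoublets(filtered, seed = seed + 2, details = TRUE)
  provisional <- clusterOnce(det$coords, resolution = 1, seed = seed + 3)
  keep <- applyDoubletFilter(det$scores, provisional, 0.3)
  retained <- filtered[, keep]
  norm <- normalizeCounts(retained)
  hvg <- selectVariableGenes(norm, 2000)
  emb <- pcaElbow(scaleCenter(norm, hvg), seed = seed + 4)
  sol <- optimizeResolution(emb, seed = seed + 5)
  list(sce = sce, filtered = filtered, scores = det$scores,
       provisional = provisional, keep = keep, retained = retained,
       norm = norm, hvg = hvg, embedding = emb, solution = sol)
})
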