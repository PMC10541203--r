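test_that("generators are bit-reproducible given a seed", {
  a <- simulateAtlas(nPopulations = 3, cellsPerPopulation = 30, nGenes = 200,
                     markersPerPopulation = 10, seed = 7)
  b <- simulateAtlas(nPopulations = 3, cellsPerPopulation = 30, nGenes = 200,
                     markersPerPopulation = 10, seed = 7)
  expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))

  t1 <- simulateTrap(nPairs = 4, nGenes = 300, seed = 9)
  t2 <- simulateTrap(nPairs = 4, nGenes = 300, seed = 9)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$truth, t2$truth)

  p1 <- simulateSpeciesPanel(nGenes = 300, cellsPerPopulation = 20, seed = 5)
  p2 <- simulateSpeciesPanel(nGenes = 300, cellsPerPopulation = 20, seed = 5)
  expect_identical(as.matrix(counts(p1[[2]]$sce)),
                   as.matrix(counts(p2[[2]]$sce)))
  expect_identical(p1[[1]]$map, p2[[1]]$map)
})

test_that("marker genes are elevated by the planted fold change", {
  # sampling oracle: in-population marker mean over >= 500 cells should
  # exceed the non-member mean by ~2^3, within 10%
  sce <- simulateAtlas(nPopulations = 3, cellsPerPopulation = 200,
                       nGenes = 600, markersPerPopulation = 40,
                       markerLog2fc = 3, libsizeCV = 0, seed = 42)
  cnt <- as.matrix(counts(sce))
  mk <- S4Vectors::metadata(sce)$markers
  for (p in names(mk)) {
    inP <- sce$population == p
    ratio <- mean(cnt[mk[[p]], inP]) / mean(cnt[mk[[p]], !inP])
    expect_gt(ratio, 8 * 0.9)
    expect_lt(ratio, 8 * 1.1)
  }
})

test_that("counts follow the negative-binomial mean-variance relation", {
  sce <- simulateAtlas(nPopulations = 1, cellsPerPopulation = 1000,
                       nGenes = 400, markersPerPopulation = 0,
                       markerLog2fc = 0, dispersion = 0.2, libsizeCV = 0,
                       indicatorGenes = FALSE, seed = 8)
  m <- as.matrix(counts(sce))
  mu <- rowMeans(m)
  v <- matrixStats::rowVars(m)
  keep <- mu > 0.5
  ratio <- v[keep] / (mu[keep] + 0.2 * mu[keep]^2)
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("single-population, zero-fold-change atlas carries no signal", {
  sce <- simulateAtlas(nPopulations = 1, cellsPerPopulation = 50,
                       nGenes = 100, markersPerPopulation = 5,
                       markerLog2fc = 0, indicatorGenes = FALSE, seed = 3)
  expect_equal(nlevels(droplevels(sce$population)), 1)
  # marker columns are not elevated
  mk <- S4Vectors::metadata(sce)$markers[[1]]
  cnt <- as.matrix(counts(sce))
  expect_lt(abs(log2(mean(cnt[mk, ]) /
                     mean(cnt[setdiff(rownames(sce), mk), ]))), 1)
})

test_that("injected doublets are exact parent sums and correctly counted", {
  sce <- smallAtlas()
  n <- ncol(sce)
  aug <- injectDoublets(sce, 0.1, seed = 13)
  nd <- round(0.1 * n)
  expect_equal(ncol(aug), n + nd)
  expect_equal(sum(aug$isDoublet), nd)
  cd <- SummarizedExperiment::colData(aug)
  dbl <- which(aug$isDoublet)
  for (i in dbl[1:10]) {
    expected <- counts(sce)[, cd$parent1[i]] + counts(sce)[, cd$parent2[i]]
    expect_identical(as.numeric(counts(aug)[, i]), as.numeric(expected))
    expect_false(cd$parent1[i] == cd$parent2[i])
  }
  # rate 0 leaves the object unchanged
  expect_identical(ncol(injectDoublets(sce, 0, seed = 1)), n)
  expect_error(injectDoublets(sce, 0.6), "0, 0.5")
})

test_that("species panel has strictly 1:1 ortholog maps at the set coverage", {
  panel <- simulateSpeciesPanel(nSpecies = 2, orthologCoverage = 0.8,
                                nGenes = 1000, cellsPerPopulation = 20,
                                markersPerPopulation = 20, seed = 17)
  for (sp in panel) {
    expect_equal(nrow(sp$map), 800)
    expect_false(anyDuplicated(sp$map$sourceId) > 0)
    expect_false(anyDuplicated(sp$map$referenceId) > 0)
    # map sources exist in the species matrix
    expect_true(all(sp$map$sourceId %in% rownames(sp$sce)))
    # shared populations present in every species
    expect_setequal(levels(droplevels(sp$sce$population)),
                    paste0("Pop", 1:6))
  }
  # species-local ids for non-reference species
  expect_true(all(startsWith(rownames(panel[[2]]$sce), "sp2_")))
  # genes absent from the map are dropped downstream
  r2 <- restrictToOrthologs(panel[[2]]$sce, panel[[2]]$map)
  expect_equal(nrow(r2), 800)
  dropped <- setdiff(rownames(panel[[2]]$sce), panel[[2]]$map$sourceId)
  expect_false(any(sub("^sp2_", "", dropped) %in% rownames(r2)))
})

test_that("TRAP generator plants the configured gene sets with signs", {
  tr <- simulateTrap(nPairs = 4, nGenes = 2000, fracEnriched = 0.1,
                     fracLeptinResponsive = 0.05, seed = 19)
  expect_equal(sum(tr$truth$enrichmentLog2fc > 0), 200)
  expect_equal(sum(tr$truth$leptinLog2fc != 0), 100)
  expect_true(all(tr$truth$leptinLog2fc %in% c(-1.5, 0, 1.5)))
  # disjoint sets
  expect_false(any(tr$truth$enrichmentLog2fc != 0 &
                   tr$truth$leptinLog2fc != 0))
  # each bead sample has exactly one sup partner
  expect_true(all(table(tr$samples$pair, tr$samples$fraction) == 1))
  # zero effect sizes give an effect-free truth table
  tr0 <- simulateTrap(nPairs = 4, nGenes = 200, enrichmentLog2fc = 0,
                      leptinLog2fc = 0, seed = 20)
  expect_true(all(tr0$truth$enrichmentLog2fc == 0))
  expect_true(all(tr0$truth$leptinLog2fc == 0))
  expect_error(simulateTrap(nPairs = 1), "unidentifiable")
})
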