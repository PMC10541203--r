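test_that("ortholog restriction keeps mapped genes, renames, and is idempotent", {
  sce <- smallAtlas()
  ids <- rownames(sce)
  idMap <- data.frame(sourceId = ids, referenceId = ids)
  same <- restrictToOrthologs(sce, idMap)
  expect_setequal(rownames(same), ids)
  expect_equal(dim(same), dim(sce))

  sub <- data.frame(sourceId = ids[1:300],
                    referenceId = paste0("ref_", ids[1:300]))
  r <- restrictToOrthologs(sce, sub)
  expect_equal(nrow(r), 300)
  expect_true(all(startsWith(rownames(r), "ref_")))
  expect_identical(colnames(r), colnames(sce))
  # genes absent from the map are absent from the output
  expect_false(any(ids[301:length(ids)] %in% rownames(r)))
  # idempotent with the identity sub-map
  idem <- restrictToOrthologs(same, idMap)
  expect_equal(as.matrix(counts(idem)[ids, ]), as.matrix(counts(same)[ids, ]))

  bad <- data.frame(sourceId = ids[1:3], referenceId = c("x", "x", "y"))
  expect_error(restrictToOrthologs(sce, bad), "not 1:1")
})

conserveFixture <- function() cachedFixture("conserveFixture", {
  sce <- smallAtlas()
  norm <- normalizeCounts(sce)
  hvg <- selectVariableGenes(norm, 300)
  pcaElbow(scaleCenter(norm, hvg), pcMin = 5, pcMax = 10)
})

test_that("harmonization is a near no-op on identical batches", {
  emb <- conserveFixture()
  Z <- pcCoords(emb)
  dup <- rbind(Z, Z) # second batch is an exact replica of the first
  rownames(dup) <- paste0("c", seq_len(2 * nrow(Z)))
  batch <- rep(c("b1", "b2"), each = nrow(Z))
  har <- harmonizeBatches(dup, batch, tol = 1e-3, seed = 1)
  disp <- sqrt(rowSums((har - dup)^2))
  scale <- sqrt(mean(rowSums(dup^2)))
  expect_lt(max(disp), 1e-3 * 10 * scale)
  # cell count and dimensionality unchanged (also on the S4 route)
  har2 <- harmonizeBatches(emb, rep(c("b1", "b2"),
                                    length.out = nrow(Z)), seed = 1)
  expect_identical(dim(pcCoords(har2)), dim(Z))
  expect_identical(nPCs(har2), nPCs(emb))
})

test_that("harmonization removes a pure batch shift and mixes batches", {
  emb <- conserveFixture()
  Z <- pcCoords(emb)
  delta <- rep(0, ncol(Z)); delta[1:2] <- c(8, -6)
  Z2 <- sweep(Z, 2, -delta) # second batch shifted
  rownames(Z2) <- paste0("dup_", rownames(Z))
  both <- rbind(Z, Z2)
  batch <- rep(c("b1", "b2"), each = nrow(Z))

  gapBefore <- sqrt(sum((colMeans(Z) - colMeans(Z2))^2))
  har <- harmonizeBatches(both, batch, seed = 2)
  gapAfter <- sqrt(sum((colMeans(har[batch == "b1", ]) -
                        colMeans(har[batch == "b2", ]))^2))
  expect_lt(gapAfter, 0.1 * gapBefore) # >= 90% shrinkage

  # within-population structure preserved: re-clustering matches truth
  truth <- rep(smallAtlas()$population, 2)
  sol <- optimizeResolution(har, knnK = 15, seed = 3)
  expect_gte(ariOracle(clusterLabels(sol), truth), 0.9)

  # batch-mixing entropy increases
  entropy <- function(coords) {
    nn <- BiocNeighbors::findKNN(coords, k = 15)$index
    b <- matrix(batch[nn], nrow = nrow(nn))
    mean(apply(b, 1, function(r) {
      p <- table(factor(r, levels = unique(batch))) / length(r)
      -sum(ifelse(p > 0, p * log(p), 0))
    }))
  }
  expect_gt(entropy(har), entropy(both))
})

test_that("conserved matching applies the 80% rule and handles splits", {
  # population P: 85% of cells in cluster c1 -> matched with overlap 0.85
  # population Q: 50/50 split -> unmatched
  cells <- paste0("r", 1:200)
  combined <- setNames(c(rep("c1", 85), rep("c2", 15),
                         rep("c2", 50), rep("c3", 50)), cells)
  refPop <- setNames(factor(rep(c("P", "Q"), each = 100)), cells)
  cm <- matchConserved(combined, refPop)
  m <- conservedMapping(cm)
  expect_equal(m$cluster[which(m$population == "P")], "c1")
  expect_equal(m$overlap[which(m$population == "P")], 0.85)
  expect_equal(m$status[which(m$population == "P")], "matched")
  expect_equal(m$status[which(m$population == "Q")], "unmatched")
  expect_true("c3" %in% m$cluster[m$status == "unassigned"])
  expect_error(matchConserved(combined, refPop, threshold = 0.4),
               "threshold")
})

test_that("contested clusters are resolved by planted subcluster geometry", {
  # P and Q both land 100% in combined cluster "c1", but occupy two
  # well-separated regions of the embedding: subclustering must split them
  nP <- 80; nQ <- 60
  cells <- paste0("r", seq_len(nP + nQ))
  combined <- setNames(rep("c1", nP + nQ), cells)
  refPop <- setNames(factor(rep(c("P", "Q"), c(nP, nQ))), cells)
  coords <- withr::with_seed(92, rbind(
    matrix(rnorm(nP * 2, 0, 0.3), nP, 2),
    matrix(rnorm(nQ * 2, 12, 0.3), nQ, 2)))
  rownames(coords) <- cells
  cm <- matchConserved(combined, refPop, embedding = coords, subKnnK = 10,
                       seed = 4)
  m <- conservedMapping(cm)
  pRow <- m[!is.na(m$population) & m$population == "P", ]
  qRow <- m[!is.na(m$population) & m$population == "Q", ]
  expect_equal(pRow$status, "contested-resolved")
  expect_equal(qRow$status, "contested-resolved")
  expect_true(startsWith(pRow$cluster, "c1."))
  expect_false(pRow$cluster == qRow$cluster)
  expect_gte(pRow$overlap, 0.95)
  expect_gte(qRow$overlap, 0.95)
  # without an embedding the contest cannot be resolved
  expect_error(matchConserved(combined, refPop), "requires an embedding")
})

test_that("a two-species panel recovers every shared population name", {
  panel <- cachedFixture("panelSmall",
    simulateSpeciesPanel(nSpecies = 2, orthologCoverage = 0.8,
                         speciesShiftSd = 0.1, nPopulations = 4,
                         cellsPerPopulation = 120, nGenes = 800,
                         markersPerPopulation = 20, seed = 93))
  r1 <- restrictToOrthologs(panel[[1]]$sce, panel[[1]]$map)
  r2 <- restrictToOrthologs(panel[[2]]$sce, panel[[2]]$map)
  shared <- intersect(rownames(r1), rownames(r2))
  comb <- cbind(counts(r1)[shared, ], counts(r2)[shared, ])
  batch <- setNames(rep(c("sp1", "sp2"), c(ncol(r1), ncol(r2))),
                    colnames(comb))
  norm <- normalizeCounts(comb)
  hvg <- selectVariableGenes(norm, min(500, length(shared)))
  emb <- pcaElbow(scaleCenter(norm, hvg), pcMin = 5, pcMax = 15, seed = 5)
  har <- harmonizeBatches(emb, batch, seed = 6)
  sol <- optimizeResolution(har, seed = 7)
  refPop <- setNames(as.character(r1$population), colnames(r1))
  cm <- matchConserved(clusterLabels(sol), refPop, embedding = har,
                       speciesLabels = batch, seed = 8)
  m <- conservedMapping(cm)
  matched <- m$population[m$status %in% c("matched", "contested-resolved")]
  expect_setequal(matched, paste0("Pop", 1:4))
})
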