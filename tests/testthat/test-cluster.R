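blobs2 <- function(n = 120, sep = 20, seed = 71) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = sep), n, 2))
    rownames(x) <- paste0("c", seq_len(2 * n))
    x
  })
}

test_that("two well-separated blobs give exactly two communities", {
  x <- blobs2()
  labels <- clusterOnce(x, resolution = 0.2, knnK = 15, seed = 1)
  expect_equal(nlevels(droplevels(labels)), 2)
  expect_equal(ariOracle(labels, rep(1:2, each = 120)), 1)
  # determinism
  expect_identical(labels, clusterOnce(x, resolution = 0.2, knnK = 15,
                                       seed = 1))
})

test_that("duplicated cells cluster with their originals", {
  x <- blobs2(n = 60)
  xx <- rbind(x, x)
  rownames(xx) <- paste0("c", seq_len(nrow(xx)))
  labels <- clusterOnce(xx, resolution = 0.2, knnK = 10, seed = 2)
  expect_identical(as.character(labels[1:120]),
                   as.character(labels[121:240]))
})

test_that("the resolution scan walks a 0.2-spaced grid and returns the argmax", {
  pip <- criterionPipeline()
  sol <- pip$solution
  log <- scanLog(sol)
  expect_equal(log$resolution,
               seq(0.2, by = 0.2, length.out = nrow(log)))
  expect_equal(meanSilhouette(sol), max(log$meanSilhouette))
  expect_gte(nrow(log), 2)
})

test_that("two antipodal tight blobs score a high silhouette", {
  x <- blobs2(n = 100, sep = 30, seed = 73)
  sol <- optimizeResolution(x, knnK = 15, seed = 3)
  expect_equal(nClusters(sol), 2)
  expect_gt(meanSilhouette(sol), 0.8)
})

test_that("cluster ordering follows centroid linkage geometry", {
  # centroids on a line at 0, 1, 10: the 0/1 clusters are adjacent leaves
  withr::with_seed(74, {
    x <- cbind(c(rnorm(30, 0, .01), rnorm(30, 1, .01), rnorm(30, 10, .01)),
               rnorm(90, 0, .01))
  })
  rownames(x) <- paste0("c", 1:90)
  labels <- factor(rep(c("at0", "at1", "at10"), each = 30))
  ord <- orderClusters(x, labels)$order
  expect_setequal(ord, levels(labels))
  expect_true(which(ord == "at10") %in% c(1, 3)) # outermost leaf
  expect_equal(abs(which(ord == "at0") - which(ord == "at1")), 1)
  # label permutation changes names only: same leaf geometry
  relab <- factor(rep(c("B", "C", "A"), each = 30))
  ord2 <- orderClusters(x, relab)$order
  translate <- c(B = "at0", C = "at1", A = "at10")
  o2 <- unname(translate[ord2])
  expect_true(identical(o2, ord) || identical(o2, rev(ord)))
  # degenerate cases
  two <- orderClusters(x[1:60, ], droplevels(labels[1:60]))
  expect_setequal(two$order, c("at0", "at1"))
  one <- orderClusters(x[1:30, ], droplevels(labels[1:30]))
  expect_equal(one$order, "at0")
})

test_that("marker p-values agree with a per-gene rank-sum oracle", {
  withr::with_seed(75, {
    m <- matrix(rnbinom(60 * 50, mu = 2, size = 5), 50, 60,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:60)))
    m[1:5, 1:30] <- m[1:5, 1:30] + 6 # markers of cluster 1
  })
  labels <- factor(rep(1:2, each = 30))
  norm <- normalizeCounts(Matrix::Matrix(m, sparse = TRUE), "libsize")
  mk <- findClusterMarkers(norm, labels, minFrac = 0, minLog2fc = 0)
  logc <- SummarizedExperiment::assay(norm, "logcounts")
  mk1 <- mk[mk$cluster == "1", ]
  oracle <- vapply(mk1$gene, function(g)
    suppressWarnings(stats::wilcox.test(
      as.numeric(logc[g, 1:30]), as.numeric(logc[g, 31:60]),
      exact = FALSE, correct = TRUE))$p.value, 1)
  expect_equal(unname(mk1$p), unname(oracle), tolerance = 1e-10)
  expect_true(all(mk$fdr >= mk$p))
  top <- mk1$gene[1:5]
  expect_setequal(top, paste0("g", 1:5))
})

test_that("label permutation yields a calibrated null for markers", {
  withr::with_seed(76, {
    m <- matrix(rnbinom(80 * 120, mu = 3, size = 10), 80, 120,
                dimnames = list(paste0("g", 1:80), paste0("c", 1:120)))
  })
  norm <- normalizeCounts(Matrix::Matrix(m, sparse = TRUE), "libsize")
  fracSig <- vapply(1:20, function(i) {
    lab <- withr::with_seed(100 + i, factor(sample(rep(1:2, each = 60))))
    mk <- findClusterMarkers(norm, lab, minFrac = 0, minLog2fc = 0)
    mean(mk$fdr < 0.05)
  }, 1)
  expect_lte(mean(fracSig), 0.05)
})

test_that("planted markers are all recovered at FDR < 0.05", {
  sce <- smallAtlas() # marker log2FC 3 >= 2
  norm <- normalizeCounts(sce)
  mk <- findClusterMarkers(norm, sce$population)
  planted <- S4Vectors::metadata(sce)$markers
  for (p in names(planted)) {
    hits <- mk[mk$cluster == p & mk$gene %in% planted[[p]], ]
    expect_equal(nrow(hits), length(planted[[p]]))
    expect_true(all(hits$fdr < 0.05))
    expect_true(all(hits$log2fc > 0))
  }
})

test_that("clusters are named by unique markers, else neurochemistry", {
  # cluster A expresses gene uniq in every cell, absent elsewhere
  withr::with_seed(77, {
    m <- matrix(rnbinom(40 * 60, mu = 2, size = 5), 40, 60,
                dimnames = list(c(paste0("g", 1:38), "Slc32a1", "Slc17a6"),
                                paste0("c", 1:60)))
  })
  rownames(m)[1] <- "uniq"
  m["uniq", ] <- c(rpois(30, 8) + 1, rep(0, 30))
  labels <- factor(rep(c("A", "B"), each = 30))
  norm <- normalizeCounts(Matrix::Matrix(m, sparse = TRUE), "libsize")
  mk <- findClusterMarkers(norm, labels, minFrac = 0.25, minLog2fc = 0.25)
  nm <- nameClusters(mk, norm, labels)
  expect_equal(unname(nm["A"]), "uniq")

  # no unique markers anywhere: neurochemical naming with GABA/GLU1
  m2 <- m
  m2["uniq", ] <- rnbinom(60, mu = 2, size = 5)
  m2["Slc32a1", 1:30] <- rpois(30, 10)
  m2["Slc17a6", 31:60] <- rpois(30, 10)
  norm2 <- normalizeCounts(Matrix::Matrix(m2, sparse = TRUE), "libsize")
  nm2 <- nameClusters(data.frame(cluster = character(), gene = character(),
                                 log2fc = numeric(), fracIn = numeric(),
                                 fracOut = numeric(), p = numeric(),
                                 fdr = numeric()),
                      norm2, labels)
  expect_equal(unname(nm2[c("A", "B")]), c("GABA", "GLU1"))
})

test_that("a sparse atlas is named by its planted marker genes", {
  sce <- simulateAtlas(nPopulations = 4, cellsPerPopulation = 120,
                       nGenes = 1000, markersPerPopulation = 15,
                       markerLog2fc = 4, baselineMean = 0.05, seed = 78)
  norm <- normalizeCounts(sce)
  labels <- sce$population
  mk <- findClusterMarkers(norm, labels)
  nm <- nameClusters(mk, norm, labels)
  planted <- S4Vectors::metadata(sce)$markers
  for (p in names(planted))
    expect_true(nm[p] %in% planted[[p]])
})
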