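trapFixture <- function() cachedFixture("trapDefault", {
  tr <- simulateTrap(seed = 201)
  list(tr = tr,
       enr = fitTrapDE(tr$counts, tr$samples, "enrichment"),
       lep = fitTrapDE(tr$counts, tr$samples, "leptin"))
})

test_that("null genes stay near zero fold change with calibrated p-values", {
  # 200 effect-free genes, 6 bead/sup pairs, low biological noise: the large
  # majority must show |log2FC| < 0.2 and p > 0.05
  tr <- simulateTrap(nPairs = 6, nGenes = 200, enrichmentLog2fc = 0,
                     leptinLog2fc = 0, dispersion = 0.002,
                     baselineMean = 200, seed = 202)
  de <- fitTrapDE(tr$counts, tr$samples, "enrichment")
  ok <- abs(de$log2FoldChange) < 0.2 & de$pvalue > 0.05
  expect_gte(mean(ok), 0.9)
})

test_that("confounded or incomplete designs are rejected", {
  tr <- simulateTrap(nPairs = 4, nGenes = 100, seed = 203)
  broken <- tr$samples
  broken$fraction[broken$sample == "P01_sup"] <- "bead"
  expect_error(fitTrapDE(tr$counts, broken, "enrichment"),
               "one bead and one sup")
  # single-treatment leptin design is unidentifiable
  allPbs <- tr$samples
  allPbs$treatment <- "PBS"
  expect_error(fitTrapDE(tr$counts, allPbs, "leptin"), "per treatment level")
})

test_that("signature building recovers planted leptin genes with signs", {
  fx <- trapFixture()
  truth <- fx$tr$truth
  sig <- buildSignature(fx$lep, alpha = 0.05)
  planted <- truth$gene[truth$leptinLog2fc != 0]
  expect_gte(mean(planted %in% signatureGenes(sig)), 0.8) # recall
  expect_gte(mean(signatureGenes(sig) %in% planted), 0.9) # precision
  sg <- signatureSigns(sig)
  trueSign <- setNames(sign(truth$leptinLog2fc), truth$gene)
  hit <- intersect(names(sg), planted)
  expect_true(all(sg[hit] == trueSign[hit])) # every direction matches
  # FDR column dominates p
  expect_true(all(fx$lep$padj >= fx$lep$pvalue, na.rm = TRUE))
  expect_error(buildSignature(fx$lep, alpha = 0), "empty signature")
})

test_that("two correlated up-genes rank cells along the planted gradient", {
  n <- 50
  t <- seq(0.2, 5, length.out = n)
  m <- rbind(g1 = t, g2 = 2 * t)
  colnames(m) <- paste0("c", 1:n)
  sig <- new("LeptinSignature", genes = c("g1", "g2"), sign = c(1, 1),
             alpha = 0.05)
  sc <- scoreSignature(m, sig)
  expect_identical(unname(rank(sc$perCell)), rank(t)) # closed-form 2-gene PC1
})

test_that("scores are invariant to gene order and to added non-signature genes", {
  g <- cachedFixture("gradedAtlas", simulateGradedAtlas(seed = 204))
  norm <- cachedFixture("gradedNorm", normalizeCounts(g$sce))
  sc1 <- scoreSignature(norm, g$signature, populations = g$sce$population)
  flipped <- new("LeptinSignature",
                 genes = rev(signatureGenes(g$signature)),
                 sign = rev(g$signature@sign), alpha = NA_real_)
  sc2 <- scoreSignature(norm, flipped, populations = g$sce$population)
  expect_identical(sc1$perCell, sc2$perCell)

  sub <- scoreSignature(norm[c(signatureGenes(g$signature),
                               rownames(norm)[450:500]), ], g$signature)
  expect_equal(unname(sub$perCell), unname(sc1$perCell), tolerance = 1e-10)
})

test_that("population scores rank exactly with planted responsiveness", {
  g <- cachedFixture("gradedAtlas", simulateGradedAtlas(seed = 204))
  norm <- cachedFixture("gradedNorm", normalizeCounts(g$sce))
  sc <- scoreSignature(norm, g$signature, populations = g$sce$population)
  pops <- names(g$grades)
  expect_equal(cor(sc$perPopulation[pops], g$grades, method = "spearman"), 1)
  # sign alignment makes the score increase with responsiveness
  expect_true(all(diff(sc$perPopulation[pops]) > 0))
  # the absolute-magnitude variant is emitted alongside
  expect_equal(sc$perCellAbs, abs(sc$perCell))
  # pseudobulk option agrees on the ranking
  pb <- scoreSignature(norm, g$signature, populations = g$sce$population,
                       pseudobulk = TRUE)
  expect_equal(cor(pb$perPopulation[pops], g$grades, method = "spearman"), 1)
})

test_that("degenerate signature scoring inputs error out", {
  g <- cachedFixture("gradedAtlas", simulateGradedAtlas(seed = 204))
  norm <- cachedFixture("gradedNorm", normalizeCounts(g$sce))
  other <- new("LeptinSignature", genes = c("nope1", "nope2"),
               sign = c(1, -1), alpha = 0.05)
  expect_error(scoreSignature(norm, other), "fewer than 2 signature genes")
  flat <- matrix(1, 3, 20, dimnames = list(signatureGenes(g$signature)[1:3],
                                           paste0("c", 1:20)))
  expect_error(scoreSignature(flat, g$signature), "zero variance")
})
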