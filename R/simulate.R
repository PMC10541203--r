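# Synthetic-data generators with known ground truth. Counts are negative
# binomial (mean mu, dispersion phi: variance = mu + phi * mu^2), population
# structure is encoded as marker genes elevated by a fixed log2 fold change,
# and per-cell library-size factors are log-normal with a given CV.

.checkAtlasSpec <- function(nPopulations, cellsPerPopulation, nGenes,
                            markersPerPopulation, markerLog2fc, baselineMean,
                            dispersion, libsizeCV, fracContaminant,
                            indicatorGenes) {
  stopifnot(length(nPopulations) == 1, length(nGenes) == 1)
  if (nPopulations < 1 || cellsPerPopulation < 1 || nGenes < 1 ||
      markersPerPopulation < 0)
    stopCfg("population, cell and gene counts must be positive")
  if (markerLog2fc < 0 || baselineMean <= 0 || dispersion <= 0)
    stopCfg("marker fold change must be >= 0; rates strictly positive")
  if (libsizeCV < 0) stopCfg("libsizeCV must be >= 0")
  if (fracContaminant < 0 || fracContaminant >= 1)
    stopCfg("fracContaminant must lie in [0, 1)")
  nBlocks <- nPopulations + (fracContaminant > 0)
  if (markersPerPopulation * nBlocks + 2 * indicatorGenes > nGenes)
    stopCfg("markersPerPopulation x populations (+ indicator genes) exceeds nGenes")
  invisible(TRUE)
}

# Shared gene-level model: baseline means, marker assignments, per-population
# mean vectors and neurochemical identities. Reused by the species panel so
# that populations are shared across species.
.atlasModel <- function(nPopulations, nGenes, markersPerPopulation,
                        markerLog2fc, baselineMean, fracContaminant,
                        indicatorGenes = TRUE) {
  geneIds <- sprintf("g%0*d", nchar(as.character(nGenes)), seq_len(nGenes))
  sdlog <- 0.5
  base <- baselineMean * exp(rnorm(nGenes, -sdlog^2 / 2, sdlog))
  popNames <- paste0("Pop", seq_len(nPopulations))
  markers <- lapply(seq_len(nPopulations), function(p)
    geneIds[((p - 1) * markersPerPopulation + 1):(p * markersPerPopulation)])
  names(markers) <- popNames
  identity <- setNames(ifelse(seq_len(nPopulations) %% 2 == 1, "GABA", "GLU"),
                       popNames)

  if (indicatorGenes) {
    # reserve the last two gene slots for the neurochemical indicator genes;
    # marker blocks are drawn from the front so they never collide
    geneIds[nGenes - 1] <- "Slc32a1"
    geneIds[nGenes]     <- "Slc17a6"
  }

  popMeans <- matrix(base, nGenes, nPopulations,
                     dimnames = list(geneIds, popNames))
  for (p in popNames)
    popMeans[markers[[p]], p] <- popMeans[markers[[p]], p] * 2^markerLog2fc
  if (indicatorGenes) {
    # GABA populations express the vesicular GABA transporter, GLU populations
    # the vesicular glutamate transporter; the other indicator is near-silent
    hi <- baselineMean * 2^3
    lo <- baselineMean * 0.02
    popMeans["Slc32a1", ] <- ifelse(identity == "GABA", hi, lo)
    popMeans["Slc17a6", ] <- ifelse(identity == "GLU", hi, lo)
  }

  contamMeans <- NULL
  contamMarkers <- NULL
  if (fracContaminant > 0) {
    jitter <- exp(rnorm(nGenes, -sdlog^2 / 2, sdlog))
    contamMeans <- base * jitter
    cm <- (nPopulations * markersPerPopulation + 1):
          ((nPopulations + 1) * markersPerPopulation)
    contamMarkers <- geneIds[cm]
    contamMeans[cm] <- contamMeans[cm] * 2^markerLog2fc
    if (indicatorGenes) {
      contamMeans[nGenes - 1] <- baselineMean * 0.02
      contamMeans[nGenes]     <- baselineMean * 0.02
    }
    names(contamMeans) <- geneIds
  }

  list(geneIds = geneIds, popMeans = popMeans, markers = markers,
       identity = identity, contamMeans = contamMeans,
       contamMarkers = contamMarkers)
}

.libFactors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

.nbBlock <- function(meanVec, libFac, dispersion) {
  mu <- outer(meanVec, libFac)
  matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
         nrow = length(meanVec))
}

# Draw one dataset from an atlas model.
.drawAtlas <- function(model, cellsPerPopulation, fracContaminant,
                       libsizeCV, dispersion, barcodePrefix = "cell") {
  nPop <- ncol(model$popMeans)
  nNeuron <- nPop * cellsPerPopulation
  nContam <- if (fracContaminant > 0)
    round(fracContaminant / (1 - fracContaminant) * nNeuron) else 0L
  nCells <- nNeuron + nContam
  lib <- .libFactors(nCells, libsizeCV)

  blocks <- vector("list", nPop + (nContam > 0))
  pop <- character(nCells)
  at <- 0L
  for (p in seq_len(nPop)) {
    idx <- at + seq_len(cellsPerPopulation)
    blocks[[p]] <- .nbBlock(model$popMeans[, p], lib[idx], dispersion)
    pop[idx] <- colnames(model$popMeans)[p]
    at <- at + cellsPerPopulation
  }
  if (nContam > 0) {
    idx <- at + seq_len(nContam)
    blocks[[nPop + 1]] <- .nbBlock(model$contamMeans, lib[idx], dispersion)
    pop[idx] <- "NonNeuronal"
  }
  counts <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
  rownames(counts) <- model$geneIds
  colnames(counts) <- sprintf("%s%0*d", barcodePrefix,
                              nchar(as.character(nCells)), seq_len(nCells))

  cd <- S4Vectors::DataFrame(
    population = factor(pop),
    isDoublet = rep(FALSE, nCells),
    isContaminant = pop == "NonNeuronal",
    row.names = colnames(counts))
  rd <- S4Vectors::DataFrame(
    markerOf = rep(NA_character_, nrow(counts)), row.names = rownames(counts))
  for (p in names(model$markers)) rd[model$markers[[p]], "markerOf"] <- p
  if (!is.null(model$contamMarkers))
    rd[model$contamMarkers, "markerOf"] <- "NonNeuronal"

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = list(markers = model$markers, identity = model$identity,
                    libFactors = setNames(lib, colnames(counts))))
}

#' Simulate a multi-population single-nucleus atlas with known truth
#'
#' Draws negative-binomial counts for `nPopulations` cell populations, each
#' with `markersPerPopulation` marker genes elevated by `markerLog2fc` log2
#' units over baseline, plus an optional block of nonneuronal contaminant
#' cells with an independent mean profile and its own distinctive markers.
#' Per-cell library-size factors are log-normal with coefficient of variation
#' `libsizeCV`. The last two gene slots are renamed to the neurochemical
#' indicator genes (Slc32a1 for GABA, Slc17a6 for GLU populations) unless
#' `indicatorGenes = FALSE`.
#'
#' Ground truth lives in `colData` (population, isDoublet, isContaminant),
#' `rowData(x)$markerOf`, and `metadata(x)$markers`.
#'
#' @param nPopulations number of neuron populations.
#' @param cellsPerPopulation cells drawn per population.
#' @param nGenes total number of genes.
#' @param markersPerPopulation marker genes planted per population.
#' @param markerLog2fc log2 elevation of marker genes over baseline.
#' @param baselineMean expected counts per gene at library factor 1.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsizeCV coefficient of variation of library-size factors.
#' @param fracContaminant fraction of all cells that are contaminants, in [0,1).
#' @param indicatorGenes rename the last two genes to Slc32a1/Slc17a6 and give
#'   them identity-specific expression.
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return a [SingleCellExperiment::SingleCellExperiment] (genes x cells).
#' @export
simulateAtlas <- function(nPopulations = 6, cellsPerPopulation = 300,
                          nGenes = 2000, markersPerPopulation = 40,
                          markerLog2fc = 3, baselineMean = 0.5,
                          dispersion = 0.1, libsizeCV = 0.2,
                          fracContaminant = 0, indicatorGenes = TRUE,
                          seed = 1) {
  .checkAtlasSpec(nPopulations, cellsPerPopulation, nGenes,
                  markersPerPopulation, markerLog2fc, baselineMean,
                  dispersion, libsizeCV, fracContaminant, indicatorGenes)
  withSeed(seed, {
    model <- .atlasModel(nPopulations, nGenes, markersPerPopulation,
                         markerLog2fc, baselineMean, fracContaminant,
                         indicatorGenes)
    .drawAtlas(model, cellsPerPopulation, fracContaminant, libsizeCV,
               dispersion)
  })
}

#' Append simulated doublets to an atlas
#'
#' Appends `round(rate * ncol(x))` doublet cells, each the element-wise sum of
#' the counts of two distinct randomly chosen singlet cells, and flags them in
#' the truth columns (`isDoublet`, `population = "Doublet"`, parent barcodes).
#'
#' @param x a `SingleCellExperiment` from [simulateAtlas()].
#' @param rate doublet rate relative to the current cell count, in [0, 0.5].
#' @param seed integer seed.
#' @return the augmented `SingleCellExperiment`.
#' @export
injectDoublets <- function(x, rate, seed = 1) {
  if (rate < 0 || rate > 0.5) stopCfg("doublet rate must lie in [0, 0.5]")
  n <- ncol(x)
  nd <- round(rate * n)
  if (nd == 0) return(x)
  singlets <- which(!x$isDoublet)
  if (length(singlets) < 2) stopCfg("need at least two singlets")
  withSeed(seed, {
    p1 <- sample(singlets, nd, replace = TRUE)
    p2 <- vapply(p1, function(i) sample(setdiff(singlets, i), 1L), 1L)
  })
  cnt <- .counts(x)
  dbl <- cnt[, p1, drop = FALSE] + cnt[, p2, drop = FALSE]
  colnames(dbl) <- sprintf("doublet%0*d", nchar(as.character(nd)), seq_len(nd))

  cd <- SummarizedExperiment::colData(x)
  if (!"parent1" %in% names(cd)) {
    cd$parent1 <- NA_character_
    cd$parent2 <- NA_character_
  }
  pops <- levels(cd$population)
  if (!"Doublet" %in% pops) pops <- c(pops, "Doublet")
  cdd <- S4Vectors::DataFrame(
    population = factor(rep("Doublet", nd), levels = pops),
    isDoublet = rep(TRUE, nd),
    isContaminant = rep(FALSE, nd),
    parent1 = colnames(x)[p1], parent2 = colnames(x)[p2],
    row.names = colnames(dbl))
  cd$population <- factor(cd$population, levels = pops)

  out <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cbind(cnt, dbl)),
    colData = rbind(cd, cdd),
    rowData = SummarizedExperiment::rowData(x),
    metadata = S4Vectors::metadata(x))
  out
}

#' Simulate a multi-species panel of shared populations with 1:1 orthologs
#'
#' All species share the same population structure (drawn once), with a
#' per-species per-gene log-scale expression offset of standard deviation
#' `speciesShiftSd`. Species 1 is the reference and keeps reference gene ids;
#' species s >= 2 use local ids `sp<s>_<refid>`. Each species comes with a
#' strictly 1:1 ortholog map covering `orthologCoverage` of genes (drawn
#' independently per species).
#'
#' @param nSpecies number of species (>= 2).
#' @param orthologCoverage fraction of genes present in each ortholog map.
#' @param speciesShiftSd sd of the per-gene natural-log expression offset
#'   applied to each non-reference species.
#' @inheritParams simulateAtlas
#' @return a list with one element per species, each a list with elements
#'   `sce` (counts with species-local gene ids, species tag in
#'   `metadata()$species` and `colData()$species`) and `map` (data.frame with
#'   columns `sourceId`, `referenceId`).
#' @export
simulateSpeciesPanel <- function(nSpecies = 2, orthologCoverage = 0.8,
                                 speciesShiftSd = 0.1, nPopulations = 6,
                                 cellsPerPopulation = 300, nGenes = 2000,
                                 markersPerPopulation = 40, markerLog2fc = 3,
                                 baselineMean = 0.5, dispersion = 0.1,
                                 libsizeCV = 0.2, indicatorGenes = TRUE,
                                 seed = 1) {
  if (nSpecies < 2) stopCfg("nSpecies must be >= 2")
  if (orthologCoverage <= 0 || orthologCoverage > 1)
    stopCfg("orthologCoverage must lie in (0, 1]")
  if (speciesShiftSd < 0) stopCfg("speciesShiftSd must be >= 0")
  .checkAtlasSpec(nPopulations, cellsPerPopulation, nGenes,
                  markersPerPopulation, markerLog2fc, baselineMean,
                  dispersion, libsizeCV, 0, indicatorGenes)
  withSeed(seed, {
    model <- .atlasModel(nPopulations, nGenes, markersPerPopulation,
                         markerLog2fc, baselineMean, 0, indicatorGenes)
    refIds <- model$geneIds
    nMap <- round(orthologCoverage * nGenes)
    lapply(seq_len(nSpecies), function(s) {
      m <- model
      if (s > 1) {
        shift <- exp(rnorm(nGenes, 0, speciesShiftSd))
        m$popMeans <- m$popMeans * shift
        m$geneIds <- paste0("sp", s, "_", refIds)
        rownames(m$popMeans) <- m$geneIds
        m$markers <- lapply(m$markers, function(g) paste0("sp", s, "_", g))
      }
      sce <- .drawAtlas(m, cellsPerPopulation, 0, libsizeCV, dispersion,
                        barcodePrefix = sprintf("sp%d_cell", s))
      sce$species <- sprintf("species%d", s)
      S4Vectors::metadata(sce)$species <- sprintf("species%d", s)
      covered <- sort(sample.int(nGenes, nMap))
      map <- data.frame(sourceId = m$geneIds[covered],
                        referenceId = refIds[covered],
                        stringsAsFactors = FALSE)
      list(sce = sce, map = map)
    })
  })
}

#' Simulate a paired bead/sup TRAP-seq experiment
#'
#' Generates negative-binomial counts for `nPairs` bead/sup sample pairs with
#' per-pair per-gene baseline effects. A fraction `fracEnriched` of genes is
#' elevated by `enrichmentLog2fc` in bead vs sup samples; a disjoint fraction
#' `fracLeptinResponsive` is shifted by `leptinLog2fc` (random sign per gene)
#' in the bead samples of leptin-treated pairs. Genotype (WT / ob/ob) and
#' treatment (PBS / leptin) are balanced across pairs.
#'
#' @param nPairs number of bead/sup pairs (>= 2).
#' @param nGenes number of genes.
#' @param fracEnriched fraction of genes bead-enriched, in (0, 1).
#' @param enrichmentLog2fc bead-vs-sup log2 fold change of enriched genes.
#' @param fracLeptinResponsive fraction of genes leptin-responsive, in (0, 1).
#' @param leptinLog2fc absolute log2 fold change of leptin-responsive genes in
#'   leptin-treated bead samples; the per-gene sign is random and recorded.
#' @param genotypes genotype labels cycled across pairs.
#' @param dispersion NB dispersion.
#' @param pairEffectSd sd of the per-pair per-gene natural-log baseline offset.
#' @param baselineMean expected baseline counts per gene.
#' @param libsizeCV coefficient of variation of per-sample depth factors.
#' @param seed integer seed.
#' @return a list: `counts` (integer matrix genes x samples), `samples`
#'   (data.frame: sample, pair, fraction, genotype, treatment), `truth`
#'   (data.frame: gene, enrichmentLog2fc, leptinLog2fc with sign; zero where
#'   no effect was planted).
#' @export
simulateTrap <- function(nPairs = 16, nGenes = 2000, fracEnriched = 0.1,
                         enrichmentLog2fc = 2, fracLeptinResponsive = 0.1,
                         leptinLog2fc = 1.5, genotypes = c("WT", "ob/ob"),
                         dispersion = 0.1, pairEffectSd = 0.2,
                         baselineMean = 50, libsizeCV = 0.2, seed = 1) {
  if (nPairs < 2) stopCfg("nPairs must be >= 2 (paired model unidentifiable)")
  if (fracEnriched <= 0 || fracEnriched >= 1 ||
      fracLeptinResponsive <= 0 || fracLeptinResponsive >= 1)
    stopCfg("gene-set fractions must lie in (0, 1)")
  if (fracEnriched + fracLeptinResponsive > 1)
    stopCfg("enriched and leptin-responsive fractions overlap")
  if (dispersion <= 0 || baselineMean <= 0) stopCfg("rates must be positive")

  withSeed(seed, {
    geneIds <- sprintf("g%0*d", nchar(as.character(nGenes)), seq_len(nGenes))
    pairs <- sprintf("P%02d", seq_len(nPairs))
    genotype <- rep(genotypes, length.out = nPairs)
    treatment <- character(nPairs)
    for (g in unique(genotype)) {
      idx <- which(genotype == g)
      treatment[idx] <- rep(c("PBS", "leptin"), length.out = length(idx))
    }
    # one bead + one sup sample per pair
    samples <- data.frame(
      sample = c(paste0(pairs, "_bead"), paste0(pairs, "_sup")),
      pair = rep(pairs, 2),
      fraction = rep(c("bead", "sup"), each = nPairs),
      genotype = rep(genotype, 2),
      treatment = rep(treatment, 2),
      stringsAsFactors = FALSE)
    samples <- samples[order(samples$pair, samples$fraction), ]
    rownames(samples) <- samples$sample

    sdlog <- 1
    mu0 <- baselineMean * exp(rnorm(nGenes, -sdlog^2 / 2, sdlog))
    pairEff <- matrix(exp(rnorm(nGenes * nPairs, -pairEffectSd^2 / 2,
                                pairEffectSd)),
                      nGenes, nPairs, dimnames = list(geneIds, pairs))
    depth <- .libFactors(nrow(samples), libsizeCV)

    nE <- round(fracEnriched * nGenes)
    nL <- round(fracLeptinResponsive * nGenes)
    enriched <- sample.int(nGenes, nE)
    leptin <- sample(setdiff(seq_len(nGenes), enriched), nL)
    lSign <- sample(c(-1, 1), nL, replace = TRUE)

    eLfc <- rep(0, nGenes); eLfc[enriched] <- enrichmentLog2fc
    lLfc <- rep(0, nGenes); lLfc[leptin] <- lSign * leptinLog2fc

    counts <- matrix(0L, nGenes, nrow(samples),
                     dimnames = list(geneIds, samples$sample))
    for (j in seq_len(nrow(samples))) {
      s <- samples[j, ]
      mu <- mu0 * pairEff[, s$pair] * depth[j]
      if (s$fraction == "bead") {
        mu <- mu * 2^eLfc
        if (s$treatment == "leptin") mu <- mu * 2^lLfc
      }
      counts[, j] <- rnbinom(nGenes, size = 1 / dispersion, mu = mu)
    }
    truth <- data.frame(gene = geneIds, enrichmentLog2fc = eLfc,
                        leptinLog2fc = lLfc, stringsAsFactors = FALSE)
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate an atlas whose populations express a signature with graded strength
#'
#' Populations 1..n express the signature's up-genes progressively more
#' strongly (and its down-genes progressively less), with planted grades
#' spaced evenly in [0, 1]; grade g shifts up-genes by `g * responseLog2fc`
#' log2 units and down-genes by `-g * responseLog2fc`. Used to validate that
#' signature scoring ranks populations by their planted responsiveness.
#'
#' @param nSignatureGenes number of signature genes (half up, half down).
#' @param responseLog2fc log2 shift of signature genes at grade 1.
#' @inheritParams simulateAtlas
#' @return a list: `sce` (counts with truth labels), `signature`
#'   (a [LeptinSignature]), `grades` (named numeric, planted per-population
#'   responsiveness).
#' @export
simulateGradedAtlas <- function(nPopulations = 5, cellsPerPopulation = 100,
                                nGenes = 500, nSignatureGenes = 40,
                                responseLog2fc = 2, baselineMean = 1,
                                dispersion = 0.1, libsizeCV = 0.2, seed = 1) {
  if (nSignatureGenes < 2 || nSignatureGenes > nGenes)
    stopCfg("need 2 <= nSignatureGenes <= nGenes")
  withSeed(seed, {
    geneIds <- sprintf("g%0*d", nchar(as.character(nGenes)), seq_len(nGenes))
    sdlog <- 0.5
    base <- baselineMean * exp(rnorm(nGenes, -sdlog^2 / 2, sdlog))
    nUp <- ceiling(nSignatureGenes / 2)
    sigIdx <- seq_len(nSignatureGenes)
    sign <- c(rep(1, nUp), rep(-1, nSignatureGenes - nUp))
    grades <- setNames(seq(0, 1, length.out = nPopulations),
                       paste0("Pop", seq_len(nPopulations)))
    n <- nPopulations * cellsPerPopulation
    lib <- .libFactors(n, libsizeCV)
    blocks <- vector("list", nPopulations)
    for (p in seq_len(nPopulations)) {
      m <- base
      m[sigIdx] <- m[sigIdx] * 2^(grades[p] * responseLog2fc * sign)
      idx <- (p - 1) * cellsPerPopulation + seq_len(cellsPerPopulation)
      blocks[[p]] <- .nbBlock(m, lib[idx], dispersion)
    }
    counts <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
    rownames(counts) <- geneIds
    colnames(counts) <- sprintf("cell%0*d", nchar(as.character(n)), seq_len(n))
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        population = factor(rep(names(grades), each = cellsPerPopulation)),
        isDoublet = FALSE, isContaminant = FALSE,
        row.names = colnames(counts)))
    sig <- new("LeptinSignature", genes = geneIds[sigIdx], sign = sign,
               alpha = NA_real_)
    list(sce = sce, signature = sig, grades = grades)
  })
}
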