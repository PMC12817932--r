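test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  set.seed(123); before <- .Random.seed
  s1 <- smallSim(seed = 7)
  expect_identical(.Random.seed, before)
  s2 <- smallSim(seed = 7)
  expect_identical(counts(s1$counts), counts(s2$counts))
  expect_identical(s1$truth@latent, s2$truth@latent)
  s3 <- smallSim(seed = 8)
  expect_false(identical(counts(s1$counts), counts(s3$counts)))
})

test_that("planted coupling drives the latent pair towards |r| = 1 and 0", {
  ## coupling 1, vanishing noise: trajectories equal up to sign, counts follow
  pl <- data.frame(taxonA = 1, featureA = 1, taxonB = 2, featureB = 2,
                   sign = -1, coupling = 1)
  ## background programs flat, so the planted trajectory is the only
  ## source of biological variation
  sim <- simulateCommunity(communityConfig(
    nTaxa = 2, genesPerTaxon = 40, nSamples = 24, plantedInteractions = pl,
    noiseSd = 1e-3, dispersion = 1e-3, confounderStrength = 0,
    programLoadingRange = c(0, 0), plantedLoadingRange = c(1, 1), seed = 3))
  zA <- sim$truth@latent[["tx1"]][1, ]
  zB <- sim$truth@latent[["tx2"]][2, ]
  expect_equal(zB, -zA, tolerance = 1e-12)
  ## after per-taxon normalization, the planted genes' profiles follow the
  ## coupled trajectories
  norm <- suppressWarnings(normalizePerTaxon(filterLowExpression(sim$counts)))
  nv <- normValues(norm)
  expect_gt(abs(cor(nv["tx1_g0001", ], nv["tx2_g0002", ])), 0.95)

  ## coupling 0, no confounder: planted latent pairs are null-correlated
  nS <- 30
  rs <- vapply(1:8, function(s) {
    pl0 <- data.frame(taxonA = 1, featureA = 1, taxonB = 2, featureB = 1,
                      sign = 1, coupling = 0)
    sim0 <- simulateCommunity(communityConfig(
      nTaxa = 2, genesPerTaxon = 20, nSamples = nS,
      plantedInteractions = pl0, confounderStrength = 0, seed = 100 + s))
    cor(sim0$truth@latent[["tx1"]][1, ], sim0$truth@latent[["tx2"]][1, ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(nS - 1))
})

test_that("expected per-taxon column sums track library size x abundance", {
  sim <- simulateCommunity(communityConfig(seed = 3))
  m <- counts(sim$counts); taxa <- geneTaxa(sim$counts)
  ## each sample's realized total stands in for its library size; the
  ## per-taxon share must then follow the relative abundances
  expTotal <- colSums(m)
  relErr <- vapply(rownames(sim$truth@relAbundance), function(t) {
    obs <- colSums(m[taxa == t, , drop = FALSE])
    expe <- sim$truth@relAbundance[t, ] * expTotal
    mean(obs / expe) - 1
  }, numeric(1))
  expect_lt(max(abs(relErr)), 0.05)
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(communityConfig(dispersion = 0), "dispersion")
  expect_error(communityConfig(nTaxa = 0), "nTaxa")
  bad <- data.frame(taxonA = 1, featureA = 9, taxonB = 2, featureB = 1,
                    sign = 1, coupling = 0.5)
  expect_error(communityConfig(nPrograms = 6, plantedInteractions = bad),
               "more planted features")
  bad2 <- data.frame(taxonA = 1, featureA = 1, taxonB = 2, featureB = 1,
                     sign = 1, coupling = 1.5)
  expect_error(communityConfig(plantedInteractions = bad2), "coupling")
})

test_that("toy genomes realize requested intergenic gaps exactly", {
  tg <- simulateToyGenome(list(
    list(contig = "ctg1", taxon = "tx1", nGenes = 3, gaps = c(100, 301),
         cores = integer(0)),
    list(contig = "ctg2", taxon = "tx1", nGenes = 2, gaps = 50,
         cores = 1)))
  r1 <- tg$regions[tg$regions$contig == "ctg1", ]
  expect_identical(r1$start[-1] - r1$end[-nrow(r1)] - 1, c(100, 301))
  ## a region with zero core genes is allowed
  expect_false(any(r1$core))
  ## genes grouped per contig and sorted
  expect_identical(
    as.character(unique(GenomicRanges::seqnames(tg$genes))),
    c("ctg1", "ctg2"))
  ## overlapping genes are a config error
  expect_error(simulateToyGenome(list(
    list(contig = "c", nGenes = 2, gaps = -5, cores = 1))), "overlap")
})

test_that("generated module databases map planted modules onto planted genes", {
  sim <- smallSim(seed = 5)
  md <- simulateModuleDb(sim$truth, nModules = 6, seed = 2)
  expect_length(md$db, 6)
  expect_named(md$plantedModules, c("producer", "consumer"))
  ## the producer module's KOs are exactly the reserved KOs of the planted
  ## program's genes in taxon A
  gp <- sim$truth@genePrograms
  plantedGenes <- gp$gene_id[gp$taxon == "tx1" & gp$program == 1]
  kos <- md$koTable$ko[md$koTable$gene_id %in% plantedGenes]
  expect_setequal(unique(kos), moduleKOs(md$db, "MP0001"))
  ## background modules never sample reserved planted KOs
  for (id in setdiff(moduleIds(md$db), md$plantedModules))
    expect_false(any(grepl("^K[AB]", moduleKOs(md$db, id))))
  ## single-module database
  sim0 <- simulateCommunity(communityConfig(nTaxa = 2, genesPerTaxon = 20,
                                            nSamples = 8, seed = 1))
  md0 <- simulateModuleDb(sim0$truth, nModules = 1, stepsRange = c(3, 3),
                          seed = 1)
  expect_length(md0$db, 1)
  expect_length(moduleSteps(md0$db, moduleIds(md0$db)), 3)
})

test_that("confounding inflates cross-species correlations stochastically", {
  maxAbs <- function(strength, seed) {
    sim <- simulateCommunity(communityConfig(
      nTaxa = 3, genesPerTaxon = 40, nSamples = 25,
      confounderStrength = strength, seed = seed))
    norm <- suppressWarnings(normalizePerTaxon(filterLowExpression(sim$counts)))
    nv <- normValues(norm); taxa <- geneTaxa(norm)
    ok <- colSums(is.na(nv)) == 0
    cm <- suppressWarnings(cor(t(nv[, ok, drop = FALSE])))
    cross <- outer(taxa, taxa, "!=") & upper.tri(cm)
    mean(abs(cm[cross]), na.rm = TRUE)
  }
  with0 <- vapply(1:4, function(s) maxAbs(0, 40 + s), numeric(1))
  with2 <- vapply(1:4, function(s) maxAbs(2, 40 + s), numeric(1))
  expect_true(all(with2 > with0))
})

test_that("truth objects serialize and round-trip through JSON", {
  sim <- smallSim(seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  writeTruth(sim$truth, f)
  tr <- readTruth(f)
  expect_equal(tr@planted$coupling, sim$truth@planted$coupling)
  expect_equal(tr@relAbundance, sim$truth@relAbundance, tolerance = 1e-12)
  expect_equal(tr@confounder, sim$truth@confounder, tolerance = 1e-12)
  expect_equal(unname(tr@latent[["tx2"]]), unname(sim$truth@latent[["tx2"]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(tr@genePrograms$gene_id, sim$truth@genePrograms$gene_id)
})
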