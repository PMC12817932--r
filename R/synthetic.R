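## Synthetic multi-species metatranscriptome generator. The model:
## counts ~ NB(mean = libSize_s * relAbund_{t,s} * prop_{g,s}, 1/dispersion)
## where prop is the within-taxon expression proportion of gene g derived
## from log-normal latent programs, a shared environmental confounder with
## taxon-specific loadings, and gene-level noise. Planted cross-species
## pairs share a latent trajectory with a stated sign and coupling.

## standardized AR(1) trajectory; moderate autocorrelation emulates the
## temporal coherence of expression programs without the spurious
## correlations of integrated (random-walk) processes
.arTrajectory <- function(n, phi) {
  x <- as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
  if (stats::sd(x) == 0) x <- stats::rnorm(n)
  as.numeric(scale(x))
}

#' Configuration of the synthetic community generator
#'
#' Defaults describe a stable engineered gut community sampled
#' longitudinally: 8 taxa of 300 genes over 40 ordered samples, library
#' sizes log-uniform over 1e5--1e7 (wide multiplexed-run depth variation),
#' per-taxon log-random-walk relative abundances, negative-binomial counts
#' (dispersion 0.1), six latent expression programs per taxon following
#' standardized AR(1) trajectories, a shared environmental confounder with
#' taxon-specific loadings, and modest gene-level log noise.
#'
#' @param nTaxa number of taxa.
#' @param genesPerTaxon genes per taxon.
#' @param nSamples number of ordered samples.
#' @param librarySizeRange range of total library sizes; sizes are drawn
#'   log-uniformly.
#' @param abundanceWalkSd per-step s.d. of the per-taxon log relative
#'   abundance random walk.
#' @param nPrograms latent expression programs per taxon.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param confounderStrength s.d. of the taxon/program-specific loadings on
#'   the shared environmental confounder; 0 disables confounding.
#' @param noiseSd s.d. of gene-level log-expression noise.
#' @param latentAr AR(1) coefficient of latent program trajectories.
#' @param programLoadingRange range of per-gene loadings on ordinary
#'   (background) latent programs; most genes respond weakly to any one
#'   program, as for housekeeping genes.
#' @param plantedLoadingRange range of per-gene loadings for genes of a
#'   planted program: a planted interaction involves a coherent, strongly
#'   regulated pathway.
#' @param plantedInteractions `data.frame` with columns `taxonA`,
#'   `featureA`, `taxonB`, `featureB` (taxon and program indices), `sign`
#'   (-1/+1) and `coupling` (in `[0, 1]`): planted cross-species
#'   co-expressed program pairs.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated [CommunityConfig-class].
#' @export
communityConfig <- function(nTaxa = 8, genesPerTaxon = 300, nSamples = 40,
                            librarySizeRange = c(1e5, 1e7),
                            abundanceWalkSd = 0.2, nPrograms = 6,
                            dispersion = 0.1, confounderStrength = 0.25,
                            noiseSd = 0.3, latentAr = 0.3,
                            programLoadingRange = c(0.2, 0.6),
                            plantedLoadingRange = c(0.8, 1.2),
                            plantedInteractions = NULL, seed = 1) {
  if (is.null(plantedInteractions))
    plantedInteractions <- data.frame(
      taxonA = integer(0), featureA = integer(0), taxonB = integer(0),
      featureB = integer(0), sign = numeric(0), coupling = numeric(0))
  methods::new("CommunityConfig",
    nTaxa = nTaxa, genesPerTaxon = genesPerTaxon, nSamples = nSamples,
    librarySizeRange = librarySizeRange, abundanceWalkSd = abundanceWalkSd,
    nPrograms = nPrograms, dispersion = dispersion,
    confounderStrength = confounderStrength, noiseSd = noiseSd,
    latentAr = latentAr, programLoadingRange = programLoadingRange,
    plantedLoadingRange = plantedLoadingRange,
    plantedInteractions = plantedInteractions, seed = seed)
}

#' Simulate a multi-species community metatranscriptome
#'
#' Draws gene-by-sample negative-binomial counts under the generative model
#' described in [communityConfig()], together with the planted ground
#' truth. Identical config and seed give identical output; the caller's RNG
#' state is left untouched.
#'
#' @param config a [CommunityConfig-class].
#' @return list with elements `counts` (a [CommunityCounts-class]) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateCommunity(communityConfig(nTaxa = 2, genesPerTaxon = 20,
#'                                          nSamples = 10, seed = 5))
#' dim(counts(sim$counts))
#' @export
simulateCommunity <- function(config) {
  methods::validObject(config)
  withr::with_seed(config@seed, .simulateCommunity(config))
}

.simulateCommunity <- function(cfg) {
  S <- cfg@nSamples; T <- cfg@nTaxa; G <- cfg@genesPerTaxon
  taxa <- sprintf("tx%d", seq_len(T))
  samples <- sprintf("s%02d", seq_len(S))
  lib <- exp(stats::runif(S, log(cfg@librarySizeRange[1]),
                          log(cfg@librarySizeRange[2])))
  la <- t(vapply(seq_len(T), function(t)
    cumsum(c(stats::rnorm(1), stats::rnorm(S - 1, 0, cfg@abundanceWalkSd))),
    numeric(S)))
  relAb <- apply(la, 2, function(col) exp(col) / sum(exp(col)))
  dimnames(relAb) <- list(taxa, samples)
  conf <- .arTrajectory(S, cfg@latentAr)
  z <- lapply(seq_len(T), function(t) {
    m <- t(vapply(seq_len(cfg@nPrograms),
                  function(p) .arTrajectory(S, cfg@latentAr), numeric(S)))
    rownames(m) <- sprintf("p%d", seq_len(cfg@nPrograms))
    colnames(m) <- samples
    m
  })
  names(z) <- taxa
  pl <- cfg@plantedInteractions
  for (k in seq_len(nrow(pl))) {
    u <- .arTrajectory(S, cfg@latentAr)
    w <- .arTrajectory(S, cfg@latentAr)
    cc <- pl$coupling[k]
    z[[pl$taxonA[k]]][pl$featureA[k], ] <- u
    z[[pl$taxonB[k]]][pl$featureB[k], ] <-
      pl$sign[k] * (cc * u + sqrt(1 - cc^2) * w)
  }
  lam <- matrix(stats::rnorm(T * cfg@nPrograms, 0, cfg@confounderStrength),
                T, cfg@nPrograms)
  counts <- matrix(0L, T * G, S)
  geneIds <- character(T * G)
  prog <- integer(T * G)
  for (t in seq_len(T)) {
    rows <- (t - 1L) * G + seq_len(G)
    base <- exp(stats::rnorm(G, 0, 1.2))
    pg <- rep_len(seq_len(cfg@nPrograms), G)
    plantedProgs <- unique(c(pl$featureA[pl$taxonA == t],
                             pl$featureB[pl$taxonB == t]))
    lr <- ifelse(pg %in% plantedProgs,
                 list(cfg@plantedLoadingRange), list(cfg@programLoadingRange))
    a <- vapply(lr, function(rg) stats::runif(1, rg[1], rg[2]), numeric(1))
    traj <- z[[t]] + outer(lam[t, ], conf)
    logE <- log(base) + a * traj[pg, , drop = FALSE] +
      matrix(stats::rnorm(G * S, 0, cfg@noiseSd), G, S)
    e <- exp(logE)
    prop <- sweep(e, 2, colSums(e), "/")
    mu <- sweep(prop, 2, lib * relAb[t, ], "*")
    counts[rows, ] <- matrix(
      stats::rnbinom(G * S, mu = mu, size = 1 / cfg@dispersion), G, S)
    geneIds[rows] <- sprintf("%s_g%04d", taxa[t], seq_len(G))
    prog[rows] <- pg
  }
  dimnames(counts) <- list(geneIds, samples)
  cd <- S4Vectors::DataFrame(
    time = seq_len(S), condition = "timecourse",
    replicate = 1L, row.names = samples)
  cc <- CommunityCounts(counts, taxa = rep(taxa, each = G), colData = cd)
  truth <- methods::new("SyntheticTruth",
    planted = pl,
    genePrograms = data.frame(gene_id = geneIds,
                              taxon = rep(taxa, each = G),
                              program = prog, stringsAsFactors = FALSE),
    confounder = conf, relAbundance = relAb, latent = z,
    expectedPresence = sweep(relAb, 2, lib, "*") >= 1000)
  list(counts = cc, truth = truth)
}

#' Generate a toy annotated genome with BGC regions
#'
#' Lays out genes on one or more contigs with exactly the requested
#' intergenic gaps, and records each spec as a BGC region with the flagged
#' core genes. Useful as a fully controlled fixture for boundary-refinement
#' logic.
#'
#' @param regionSpecs list of region specifications; each a list with
#'   elements `contig`, `taxon`, `nGenes`, `gaps` (integer vector of length
#'   `nGenes - 1`, intergenic distances in bp), `cores` (integer positions
#'   of core biosynthetic genes, may be empty) and optionally
#'   `product_class`.
#' @param geneLength length of every gene in bp.
#' @param regionGap distance between consecutive regions on the same
#'   contig.
#' @param firstStart start coordinate of the first gene of each contig.
#' @return list with `genes` (a [GenomicRanges::GRanges], sorted by contig
#'   and start) and `regions` (per-gene `data.frame` in the layout of
#'   [readBgcRegions()]).
#' @export
simulateToyGenome <- function(regionSpecs, geneLength = 900,
                              regionGap = 5000, firstStart = 1000) {
  rows <- list(); grx <- list()
  nextStart <- list(); geneCount <- list()
  for (i in seq_along(regionSpecs)) {
    sp <- regionSpecs[[i]]
    contig <- sp$contig %||% "ctg1"
    taxon <- sp$taxon %||% "tx1"
    n <- sp$nGenes
    gaps <- sp$gaps %||% integer(0)
    if (length(gaps) != n - 1)
      stop("regionSpecs[[", i, "]]: need nGenes - 1 intergenic gaps")
    if (any(gaps < 0))
      stop("regionSpecs[[", i, "]]: negative gap would overlap genes")
    start0 <- nextStart[[contig]] %||% firstStart
    g0 <- geneCount[[contig]] %||% 0L
    starts <- numeric(n); starts[1] <- start0
    for (j in seq_len(n - 1))
      starts[j + 1] <- starts[j] + geneLength + gaps[j]  # gap = next.start - prev.end - 1
    ends <- starts + geneLength - 1
    ids <- sprintf("%s_g%03d", contig, g0 + seq_len(n))
    nextStart[[contig]] <- ends[n] + regionGap + 1
    geneCount[[contig]] <- g0 + n
    rid <- sp$region_id %||% sprintf("BGC_%d", i)
    rows[[i]] <- data.frame(
      region_id = rid, taxon = taxon, contig = contig,
      product_class = sp$product_class %||% "NRPS",
      gene_id = ids, start = starts, end = ends,
      core = seq_len(n) %in% sp$cores, stringsAsFactors = FALSE)
    grx[[i]] <- GenomicRanges::GRanges(
      seqnames = contig, ranges = IRanges::IRanges(starts, ends),
      strand = "+", type = "gene", gene_id = ids,
      product = sp$product_class %||% "NRPS")
  }
  genes <- suppressWarnings(do.call(c, grx))
  genes <- genes[order(as.character(GenomicRanges::seqnames(genes)),
                       GenomicRanges::start(genes))]
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  list(genes = genes, regions = regions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a module database matched to a simulated community
#'
#' Assigns each simulated gene a KO id and builds a module database in
#' which one designated "producer" and one "consumer" module map exactly
#' onto the genes of a planted interaction (so their expected step coverage
#' downstream is 1), while the remaining modules draw KOs from the
#' community-wide KO pool.
#'
#' @param truth a [SyntheticTruth-class] from [simulateCommunity()].
#' @param nModules total number of modules (including the two planted ones
#'   when a planted interaction exists).
#' @param stepsRange integer range of steps per background module.
#' @param koUniverse size of the shared KO universe the background genes
#'   draw from; collisions create KOs shared between taxa.
#' @param plantedSteps number of (single-KO) steps of each planted module.
#' @param seed integer seed.
#' @return list with `db` (a [ModuleDatabase-class]), `koTable`
#'   (`data.frame` gene_id/ko) and `plantedModules` (named character vector
#'   with entries `producer`/`consumer`, or empty when nothing is planted).
#' @export
simulateModuleDb <- function(truth, nModules = 12, stepsRange = c(3, 5),
                             koUniverse = 400, plantedSteps = 10, seed = 1) {
  stopifnot(nModules >= 1, all(stepsRange >= 1))
  withr::with_seed(seed, {
    gp <- truth@genePrograms
    pl <- truth@planted
    ko <- sprintf("K%05d", sample.int(koUniverse, nrow(gp), replace = TRUE))
    plantedModules <- character(0)
    mods <- list()
    if (nrow(pl)) {
      ## reserve distinct KOs for each planted program so the planted
      ## modules are specific to it
      for (k in seq_len(min(1, nrow(pl)))) {
        ## all genes of a planted program get reserved KOs (round-robin over
        ## the module's steps), so background modules cannot sample them and
        ## each planted KO aggregates several genes
        selA <- which(gp$taxon == sprintf("tx%d", pl$taxonA[k]) &
                        gp$program == pl$featureA[k])
        selB <- which(gp$taxon == sprintf("tx%d", pl$taxonB[k]) &
                        gp$program == pl$featureB[k])
        nA <- min(plantedSteps, length(selA))
        nB <- min(plantedSteps, length(selB))
        ko[selA] <- sprintf("KA%04d", rep_len(seq_len(nA), length(selA)))
        ko[selB] <- sprintf("KB%04d", rep_len(seq_len(nB), length(selB)))
        mods[[1]] <- methods::new("ModuleDefinition", id = "MP0001",
          name = "planted producer module",
          steps = lapply(sprintf("KA%04d", seq_len(nA)), function(k) list(k)))
        mods[[2]] <- methods::new("ModuleDefinition", id = "MP0002",
          name = "planted consumer module",
          steps = lapply(sprintf("KB%04d", seq_len(nB)), function(k) list(k)))
        plantedModules <- c(producer = "MP0001", consumer = "MP0002")
      }
    }
    pool <- unique(ko[!startsWith(ko, "KA") & !startsWith(ko, "KB")])
    nBg <- nModules - length(mods)
    for (i in seq_len(nBg)) {
      ss <- seq(stepsRange[1], stepsRange[2])
      nSteps <- if (length(ss) == 1) ss else sample(ss, 1)
      steps <- lapply(seq_len(nSteps), function(s) {
        nAlt <- sample(1:2, 1)
        lapply(seq_len(nAlt), function(a) {
          cplx <- sample(1:2, 1, prob = c(0.8, 0.2))
          sample(pool, cplx)
        })
      })
      mods[[length(mods) + 1L]] <- methods::new("ModuleDefinition",
        id = sprintf("MB%04d", i), name = sprintf("background module %d", i),
        steps = steps)
    }
    list(db = ModuleDatabase(mods),
         koTable = data.frame(gene_id = gp$gene_id, ko = ko,
                              stringsAsFactors = FALSE),
         plantedModules = plantedModules)
  })
}
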