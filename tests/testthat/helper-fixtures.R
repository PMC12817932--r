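## Fixture builders; all fixtures are generated in code at test time.

## a unit-norm, zero-mean vector
.unitCentered <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

## pair of vectors with exactly the requested Pearson correlation
exactCorPair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    z1 <- .unitCentered(rnorm(n))
    z2 <- rnorm(n); z2 <- z2 - mean(z2)
    z2 <- .unitCentered(z2 - sum(z2 * z1) * z1)
    list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}

## chain of vectors where cor(v[i], v[i+1]) == rhos[i] exactly
chainCor <- function(n, rhos, seed = 1) {
  withr::with_seed(seed, {
    out <- list(.unitCentered(rnorm(n)))
    for (i in seq_along(rhos)) {
      prev <- out[[i]]
      e <- rnorm(n); e <- e - mean(e)
      e <- .unitCentered(e - sum(e * prev) * prev)
      out[[i + 1]] <- rhos[i] * prev + sqrt(1 - rhos[i]^2) * e
    }
    do.call(rbind, out)
  })
}

## small GMM flat file as text lines
gmmFixtureText <- function() {
  c("MF0001\tthree single-KO steps",
    "K00001", "K00002", "K00003", "///",
    "MF0002\talternatives and a complex",
    "K00010,K00011", "K00012+K00013", "///")
}

## tiny GFF3 file on disk; returns the path
writeGffFixture <- function(path, contig = "ctg1",
                            starts = c(100, 600), ends = c(400, 900),
                            ids = c("gA", "gB")) {
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     contig, starts, ends, ids))
  writeLines(lines, path)
  path
}

## small community simulation shared by several tests
smallSim <- function(seed = 11, ...) {
  pl <- data.frame(taxonA = 1, featureA = 1, taxonB = 2, featureB = 1,
                   sign = 1, coupling = 0.9)
  simulateCommunity(communityConfig(nTaxa = 3, genesPerTaxon = 60,
                                    nSamples = 20,
                                    plantedInteractions = pl,
                                    seed = seed, ...))
}

## build a region fixture with controlled gaps plus an expression matrix
## whose consecutive-gene correlations are exact
regionFixture <- function(gaps, rhos, cores, n = 24, seed = 1) {
  tg <- simulateToyGenome(list(list(contig = "ctg1", taxon = "tx1",
                                    nGenes = length(gaps) + 1, gaps = gaps,
                                    cores = cores)))
  expr <- chainCor(n, rhos, seed = seed)
  rownames(expr) <- tg$regions$gene_id
  list(region = tg$regions, expr = expr)
}
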