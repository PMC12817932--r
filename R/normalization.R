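## Low-expression filtering, per-taxon TMM normalization and the
## variance-stabilizing transform. Normalizing each taxon against its own
## library (its total assigned reads) removes the strong positive bias that
## shared sequencing depth and shifting species abundances impose on
## correlations between raw counts.

#' Remove genes below the low-expression threshold
#'
#' A gene is kept iff it has at least `minCount` reads in at least
#' `ceiling(minSampleFrac * n_samples)` samples. All samples count towards
#' the denominator, regardless of taxon presence. The filter is idempotent;
#' removed gene ids accumulate in `metadata(x)$removedGenes`.
#'
#' @param x a [CommunityCounts-class].
#' @param minCount minimum read count (default 10).
#' @param minSampleFrac minimum fraction of samples (default 0.5).
#' @return the filtered [CommunityCounts-class]; removed ids available via
#'   [removedGenes()].
#' @export
filterLowExpression <- function(x, minCount = 10, minSampleFrac = 0.5) {
  m <- counts(x)
  need <- ceiling(minSampleFrac * ncol(m))
  keep <- rowSums(m >= minCount) >= need
  out <- x[keep, ]
  S4Vectors::metadata(out)$removedGenes <-
    union(removedGenes(x), rownames(m)[!keep])
  out
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample TMM normalization factors (Robinson & Oshlack) for
#' one taxon's count submatrix via [edgeR::calcNormFactors()]: per-gene
#' log2 ratios of library-scaled proportions against a reference column
#' (the one whose upper quartile is closest to the mean upper quartile),
#' doubly trimmed by M (30%) and by average log expression A (5%), combined
#' as a precision-weighted mean, and rescaled so that the factors have
#' geometric mean 1. Genes with a zero in either column drop out of the
#' trimmed mean.
#'
#' @param mat gene-by-sample count matrix with at least 2 columns.
#' @param logratioTrim fraction trimmed from each tail of the M values.
#' @param sumTrim fraction trimmed from each tail of the A values.
#' @param refColumn optional reference column index; default as above.
#' @return named numeric vector of factors, geometric mean 1. A sample that
#'   shares no expressed gene with the reference gets factor 1 with a
#'   warning.
#' @export
tmmFactors <- function(mat, logratioTrim = 0.30, sumTrim = 0.05,
                       refColumn = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("TMM needs at least two samples")
  f <- suppressWarnings(edgeR::calcNormFactors(
    mat, method = "TMM", refColumn = refColumn,
    logratioTrim = logratioTrim, sumTrim = sumTrim))
  bad <- !is.finite(f)
  if (any(bad)) {
    warning(sum(bad), " sample(s) share no expressed gene with the ",
            "reference; factor set to 1")
    f[bad] <- 1
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(mat)
  f
}

#' Per-taxon TMM normalization to counts-per-million
#'
#' For each taxon, TMM scaling factors are computed on the taxon's count
#' submatrix over the samples in which the taxon is present (total assigned
#' reads >= `minSpeciesReads`), and each count is scaled to per-taxon CPM:
#' `count / (taxon library size * factor) * 1e6`. Samples where a taxon is
#' absent are recorded as missing (`NA`), never zero; taxa present in fewer
#' than two samples are dropped with a warning. Apply
#' [filterLowExpression()] first.
#'
#' @param x a (filtered) [CommunityCounts-class].
#' @param minSpeciesReads minimum total reads for a taxon to count as
#'   present in a sample (default 1000).
#' @return a [NormalizedCommunity-class].
#' @export
normalizePerTaxon <- function(x, minSpeciesReads = 1000) {
  m <- counts(x)
  taxa <- geneTaxa(x)
  taxaU <- unique(unname(taxa))
  presence <- t(vapply(taxaU, function(t)
    colSums(m[taxa == t, , drop = FALSE]) >= minSpeciesReads,
    logical(ncol(m))))
  dimnames(presence) <- list(taxaU, colnames(m))
  dropped <- taxaU[rowSums(presence) < 2]
  if (length(dropped))
    warning("taxa present in < 2 samples dropped: ",
            paste(dropped, collapse = ", "))
  keptTaxa <- setdiff(taxaU, dropped)
  keepGene <- taxa %in% keptTaxa
  vals <- matrix(NA_real_, sum(keepGene), ncol(m),
                 dimnames = list(rownames(m)[keepGene], colnames(m)))
  fact <- lib <- matrix(NA_real_, length(keptTaxa), ncol(m),
                        dimnames = list(keptTaxa, colnames(m)))
  for (t in keptTaxa) {
    sel <- which(presence[t, ])
    sub <- m[taxa == t, sel, drop = FALSE]
    libT <- colSums(sub)
    f <- tmmFactors(sub)
    vals[rownames(sub), sel] <- sweep(sub, 2, libT * f, "/") * 1e6
    fact[t, sel] <- f
    lib[t, sel] <- libT
  }
  methods::new("NormalizedCommunity",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(cpm = vals),
      rowData = S4Vectors::DataFrame(
        taxon = unname(taxa[keepGene]), row.names = rownames(vals)),
      colData = SummarizedExperiment::colData(x)),
    normFactors = fact, libSizes = lib,
    presence = presence[keptTaxa, , drop = FALSE],
    removedGenes = removedGenes(x), droppedTaxa = dropped)
}
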