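## Statistical procedures over correlation sets: matched-module
## cross-species comparisons, bootstrap mean-shift testing, tail-fraction
## bookkeeping and partner ranking.

#' Cross-species correlations of one module across taxa
#'
#' Extracts the expression profiles of a module in every taxon where it
#' passed the coverage filter and computes all unordered taxon-pair
#' correlations over shared samples, after the Pearson-Spearman discrepancy
#' filter.
#'
#' @param moduleExpr module-level
#'   [SummarizedExperiment::SummarizedExperiment] from [scoreModules()].
#' @param moduleId module id.
#' @param presence optional logical taxon-by-sample matrix.
#' @param minShared minimum shared samples per pair (default 5).
#' @param maxDiscrepancy Pearson-Spearman discrepancy threshold (default
#'   0.3).
#' @return list with `module`, `nTaxa` (number of taxa carrying the
#'   module), `values` (surviving correlation values), `pairs` (the edge
#'   rows) and, when fewer than two taxa carry the module, a `reason`.
#' @export
matchedModuleCorrelations <- function(moduleExpr, moduleId, presence = NULL,
                                      minShared = 5, maxDiscrepancy = 0.3) {
  rd <- SummarizedExperiment::rowData(moduleExpr)
  sel <- rd$module == moduleId
  nTaxa <- length(unique(rd$taxon[sel]))
  if (nTaxa < 2)
    return(list(module = moduleId, nTaxa = nTaxa, values = numeric(0),
                pairs = NULL, reason = "module carried by fewer than 2 taxa"))
  vals <- SummarizedExperiment::assay(moduleExpr, "score")[sel, , drop = FALSE]
  edges <- correlateFeatures(vals, taxa = rd$taxon[sel], presence = presence,
                             kinds = rep("module", sum(sel)),
                             minShared = minShared)
  edges <- discrepancyFilter(edges, maxGap = maxDiscrepancy)
  kept <- edges[edges$removed_by == "none", , drop = FALSE]
  list(module = moduleId, nTaxa = nTaxa, values = kept$r, pairs = edges)
}

#' Bootstrap test for a mean shift of a correlation set
#'
#' Draws `iterations` bootstrap sets of `length(observed)` values with
#' replacement from `pool` and compares their means with the observed mean.
#' One-sided empirical p-values carry the add-one correction
#' `p = (1 + #extreme) / (B + 1)`, so no p-value is ever exactly zero. The
#' procedure is deterministic given `seed` and invariant to pool ordering.
#'
#' @param observed numeric vector (>= 1 values), e.g. the matched-module
#'   correlations of one module.
#' @param pool numeric resampling pool, at least as large as `observed`;
#'   by default the union of all cross-species correlation values in the
#'   analysis set.
#' @param iterations bootstrap iterations (default 50000).
#' @param seed integer seed.
#' @return a [BootstrapResult-class].
#' @export
bootstrapMeanShift <- function(observed, pool, iterations = 50000, seed = 1) {
  if (!length(pool)) stop("resampling pool is empty")
  if (!length(observed)) stop("observed set is empty")
  if (length(pool) < length(observed))
    stop("pool must be at least as large as the observed set")
  m <- length(observed)
  obs <- mean(observed)
  pool <- sort(pool)   # canonical order: results do not depend on input order
  nullMeans <- withr::with_seed(seed, {
    chunk <- max(1L, min(iterations, floor(5e7 / m)))
    res <- numeric(0)
    done <- 0L
    while (done < iterations) {
      b <- min(chunk, iterations - done)
      draws <- matrix(sample(pool, b * m, replace = TRUE), nrow = m)
      res <- c(res, colMeans(draws))
      done <- done + b
    }
    res
  })
  methods::new("BootstrapResult",
    observedMean = obs, poolSize = length(pool), setSize = m,
    iterations = iterations, seed = seed,
    pHigh = (1 + sum(nullMeans >= obs)) / (iterations + 1),
    pLow = (1 + sum(nullMeans <= obs)) / (iterations + 1),
    nullMean = mean(nullMeans), nullSd = stats::sd(nullMeans))
}

#' Fraction of cross-species edges beyond a correlation threshold
#'
#' Counts cross-species edges with `|r|` strictly above `threshold`, after
#' removing excluded taxon pairs (e.g. a pair of congeneric species whose
#' shared biology would dominate the tail).
#'
#' @param edges edge `data.frame` from [correlateFeatures()].
#' @param threshold absolute correlation threshold (default 0.8).
#' @param exclude list of length-2 character vectors naming excluded
#'   (unordered) taxon pairs.
#' @return list with `fraction`, `count` and `total` (edges considered).
#' @export
tailFraction <- function(edges, threshold = 0.8, exclude = NULL) {
  sel <- edges$cross_species & !is.na(edges$r)
  if (!is.null(exclude)) {
    key <- paste(pmin(edges$taxon_a, edges$taxon_b),
                 pmax(edges$taxon_a, edges$taxon_b))
    ex <- vapply(exclude, function(p) paste(min(p), max(p)), character(1))
    sel <- sel & !key %in% ex
  }
  total <- sum(sel)
  count <- sum(abs(edges$r[sel]) > threshold)
  list(fraction = if (total) count / total else 0, count = count,
       total = total)
}

#' Rank candidate interaction partners of a focal feature
#'
#' Orders the edges touching a focal node by correlation (descending; by
#' `|r|` on request), breaking ties by the number of shared samples and
#' then by partner label.
#'
#' @param edges edge `data.frame`.
#' @param focal focal node id.
#' @param by `"r"` (default) or `"abs"`.
#' @param keepRemoved include edges flagged by a filter (default FALSE).
#' @return `data.frame` with columns `partner`, `r`, `rho`, `n_shared`,
#'   `cross_species`, `rank`.
#' @export
rankPartners <- function(edges, focal, by = c("r", "abs"),
                         keepRemoved = FALSE) {
  by <- match.arg(by)
  sel <- edges$node_a == focal | edges$node_b == focal
  if (!keepRemoved) sel <- sel & edges$removed_by == "none"
  e <- edges[sel, , drop = FALSE]
  partner <- ifelse(e$node_a == focal, e$node_b, e$node_a)
  keyR <- if (by == "abs") abs(e$r) else e$r
  ord <- order(-keyR, -e$n_shared, partner)
  out <- data.frame(partner = partner[ord], r = e$r[ord], rho = e$rho[ord],
                    n_shared = e$n_shared[ord],
                    cross_species = e$cross_species[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}
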