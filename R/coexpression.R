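## Within- and cross-species co-expression: shared-sample Pearson/Spearman
## correlation, the Pearson-Spearman discrepancy filter, signed power
## scaling of the adjacency, scale-free soft-threshold selection, Fisher-z
## averaged cluster-cluster correlation, and network assembly.

#' Correlate expression features within and across species
#'
#' Computes, for every unordered feature pair, the Pearson and Spearman
#' correlation over the samples in which *both* features' taxa are present
#' and both values are non-missing. Self-comparisons and duplicate pairs
#' are excluded at construction; Spearman ties get average ranks.
#'
#' @param values feature-by-sample numeric matrix (rownames = feature ids).
#' @param taxa character vector assigning each feature (row) to a taxon.
#' @param presence optional logical taxon-by-sample matrix (from
#'   [presenceMatrix()]); default: every taxon present everywhere.
#' @param kinds optional character vector of feature kinds (`"gene"`,
#'   `"module"`, `"cluster"`); default `"feature"`.
#' @param minShared minimum number of shared samples; pairs below it are
#'   marked `removed_by = "min_samples"` (default 5).
#' @return edge `data.frame` with columns `node_a`, `node_b`, `taxon_a`,
#'   `taxon_b`, `kind_a`, `kind_b`, `r`, `rho`, `n_shared`,
#'   `cross_species`, `removed_by` (`"none"`, `"min_samples"` or
#'   `"undefined"` for zero-variance features).
#' @export
correlateFeatures <- function(values, taxa, presence = NULL, kinds = NULL,
                              minShared = 5) {
  values <- as.matrix(values)
  stopifnot(length(taxa) == nrow(values))
  if (is.null(kinds)) kinds <- rep("feature", nrow(values))
  ids <- rownames(values)
  if (is.null(ids)) stop("feature matrix needs rownames")
  taxaU <- unique(taxa)
  if (is.null(presence)) {
    presence <- matrix(TRUE, length(taxaU), ncol(values),
                       dimnames = list(taxaU, colnames(values)))
  }
  out <- list()
  for (a in seq_along(taxaU)) for (b in a:length(taxaU)) {
    ta <- taxaU[a]; tb <- taxaU[b]
    shared <- which(presence[ta, ] & presence[tb, ])
    ia <- which(taxa == ta); ib <- which(taxa == tb)
    va <- values[ia, shared, drop = FALSE]
    vb <- values[ib, shared, drop = FALSE]
    nMat <- (!is.na(va)) %*% t(!is.na(vb))
    suppressWarnings({
      rMat <- stats::cor(t(va), t(vb), use = "pairwise.complete.obs")
      sMat <- stats::cor(t(va), t(vb), use = "pairwise.complete.obs",
                         method = "spearman")
    })
    pairs <- if (ta == tb) which(upper.tri(rMat), arr.ind = TRUE)
             else as.matrix(expand.grid(seq_along(ia), seq_along(ib)))
    if (!nrow(pairs)) next
    out[[length(out) + 1L]] <- data.frame(
      node_a = ids[ia][pairs[, 1]], node_b = ids[ib][pairs[, 2]],
      taxon_a = ta, taxon_b = tb,
      kind_a = kinds[ia][pairs[, 1]], kind_b = kinds[ib][pairs[, 2]],
      r = rMat[pairs], rho = sMat[pairs], n_shared = nMat[pairs],
      cross_species = ta != tb, removed_by = "none",
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) stop("no feature pairs to correlate")
  edges$removed_by[is.na(edges$r) | is.na(edges$rho)] <- "undefined"
  edges$removed_by[edges$removed_by == "none" &
                     edges$n_shared < minShared] <- "min_samples"
  rownames(edges) <- NULL
  edges
}

#' Remove edges with a high Pearson-Spearman discrepancy
#'
#' Pairs whose Pearson and Spearman correlations disagree by strictly more
#' than `maxGap` are typically driven by outlier samples; such edges are
#' marked `removed_by = "discrepancy"`. Edges already removed keep their
#' original reason; the boundary `|r - rho| == maxGap` is kept.
#'
#' @param edges edge `data.frame` from [correlateFeatures()].
#' @param maxGap maximum tolerated `|r - rho|` (default 0.3).
#' @return the edge `data.frame` with updated `removed_by`.
#' @export
discrepancyFilter <- function(edges, maxGap = 0.3) {
  ## strict inequality, guarded against floating-point representation of
  ## differences such as 0.9 - 0.6
  sel <- edges$removed_by == "none" &
    !is.na(edges$r) & !is.na(edges$rho) &
    abs(edges$r - edges$rho) > maxGap + 1e-12
  edges$removed_by[sel] <- "discrepancy"
  edges
}

#' Signed power scaling of correlations
#'
#' `weight = sign(r) * |r|^beta`: a soft-thresholding transform that keeps
#' the sign while shrinking weak correlations for high contrast between
#' strong edges. With the default `beta = 6`, a display cut-off of weight
#' 0.2 corresponds to `|r| > 0.76` and 0.5 to `|r| > 0.89`.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @param beta power, `>= 1` (default 6).
#' @return numeric vector of signed weights.
#' @examples
#' signedPower(c(-1, 0, 1))     # fixed points
#' signedPower(0.76)            # ~ 0.19
#' @export
signedPower <- function(r, beta = 6) {
  stopifnot(beta >= 1)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  sign(r) * abs(r)^beta
}

#' Scale-free fit index of a connectivity vector
#' @noRd
.scaleFreeFit <- function(k, nBreaks = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 3) return(c(fit = NA, slope = NA))
  bins <- cut(log(k), nBreaks)
  dk <- tapply(k, bins, mean)
  p <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & !is.na(p) & p > 0
  if (sum(ok) < 3) return(c(fit = NA, slope = NA))
  fit <- stats::lm(log10(p[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  c(fit = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, node connectivity `k_i = sum_j |r_ij|^beta` is
#' computed, `log(k)` is binned, and `log(frequency)` is regressed on
#' `log(k)`; the signed fit index is `-sign(slope) * R^2` so that only
#' decreasing degree distributions score positively. Returns the smallest
#' power whose fit reaches `targetR2`, or the power with the best fit if
#' none does, together with the full audit table.
#'
#' @param r symmetric correlation matrix over >= 20 nodes (or an edge
#'   `data.frame` from [correlateFeatures()], from which the matrix is
#'   assembled).
#' @param betaGrid candidate powers (default `1:20`).
#' @param targetR2 target signed fit (default 0.8).
#' @param nBreaks connectivity bins (default 10).
#' @return list with `power` and `fitTable` (`data.frame` columns `beta`,
#'   `fit`, `slope`, `meanK`).
#' @export
pickSoftThreshold <- function(r, betaGrid = 1:20, targetR2 = 0.8,
                              nBreaks = 10) {
  if (is.data.frame(r)) r <- .edgesToMatrix(r)
  stopifnot(isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
  if (nrow(r) < 20) stop("soft-threshold selection needs >= 20 nodes")
  off <- abs(r[upper.tri(r)])
  off <- off[!is.na(off)]
  if (length(unique(signif(off, 12))) < 2)
    stop("degenerate network: all correlations have equal magnitude")
  a <- abs(r); diag(a) <- 0; a[is.na(a)] <- 0
  tab <- do.call(rbind, lapply(betaGrid, function(beta) {
    k <- rowSums(a^beta)
    sf <- .scaleFreeFit(k, nBreaks)
    data.frame(beta = beta, fit = sf["fit"], slope = sf["slope"],
               meanK = mean(k), row.names = NULL)
  }))
  hit <- which(!is.na(tab$fit) & tab$fit >= targetR2)
  power <- if (length(hit)) tab$beta[hit[1]] else tab$beta[which.max(tab$fit)]
  list(power = power, fitTable = tab)
}

.edgesToMatrix <- function(edges) {
  ids <- unique(c(edges$node_a, edges$node_b))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m[cbind(edges$node_a, edges$node_b)] <- edges$r
  m[cbind(edges$node_b, edges$node_a)] <- edges$r
  m
}

#' Fisher-z average of correlation coefficients
#'
#' Correlations are clipped to `+/-(1 - 1e-6)`, transformed with `atanh`,
#' averaged, and back-transformed with `tanh`. Equal inputs are a fixed
#' point; the average is odd-symmetric and bounded in `(-1, 1)`.
#'
#' @param r numeric vector of correlations.
#' @param clip clipping bound applied before `atanh`.
#' @return a single correlation value.
#' @examples
#' fisherAverage(c(0.5, 0.9))  # ~ 0.766
#' @export
fisherAverage <- function(r, clip = 1 - 1e-6) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  tanh(mean(atanh(pmin(pmax(r, -clip), clip))))
}

#' Cluster-to-cluster co-expression
#'
#' The co-expression of two gene clusters is the Fisher-z average of all
#' inter-cluster gene-gene Pearson correlations, computed over shared
#' non-missing samples.
#'
#' @param exprA,exprB expression matrices (genes x samples) of the two
#'   clusters' member genes, on a common sample universe.
#' @param minShared minimum shared samples per gene pair.
#' @return list with `r` (the averaged correlation; `NA` with a `reason`
#'   when no valid pair exists) and `nPairs`.
#' @export
clusterCorrelation <- function(exprA, exprB, minShared = 5) {
  exprA <- rbind(exprA); exprB <- rbind(exprB)
  suppressWarnings({
    rMat <- stats::cor(t(exprA), t(exprB), use = "pairwise.complete.obs")
  })
  nMat <- (!is.na(exprA)) %*% t(!is.na(exprB))
  rs <- rMat[!is.na(rMat) & nMat >= minShared]
  if (!length(rs))
    return(list(r = NA_real_, nPairs = 0L, reason = "no valid gene pair"))
  list(r = fisherAverage(rs), nPairs = length(rs))
}

#' Assemble a thresholded co-expression network
#'
#' Computes `weight = sign(r) * |r|^beta` for every surviving edge
#' (`removed_by == "none"`) and retains edges with `|weight| > minWeight`.
#' Within-species edges between module features are annotated with their
#' shared-KO fraction (when a database is supplied) so that consumers can
#' exclude edges inflated by shared enzymes from interpretation.
#'
#' @param edges edge `data.frame` (after any filtering).
#' @param beta soft-threshold power (default 6).
#' @param minWeight retain edges with `|weight|` strictly above this
#'   (default 0.2, i.e. `|r| > 0.2^(1/6) ~ 0.76`).
#' @param db optional [ModuleDatabase-class] for shared-KO annotation.
#' @param dropSingletons drop nodes without a retained edge (default TRUE).
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(edges, beta = 6, minWeight = 0.2, db = NULL,
                         dropSingletons = TRUE) {
  kept <- edges[edges$removed_by == "none", , drop = FALSE]
  kept$weight <- signedPower(kept$r, beta)
  kept <- kept[abs(kept$weight) > minWeight, , drop = FALSE]
  kept$shared_ko_fraction <- rep(NA_real_, nrow(kept))
  if (!is.null(db)) {
    sel <- which(!kept$cross_species & kept$kind_a == "module" &
                   kept$kind_b == "module")
    for (i in sel) {
      ida <- sub("^[^|]*\\|", "", kept$node_a[i])
      idb <- sub("^[^|]*\\|", "", kept$node_b[i])
      if (all(c(ida, idb) %in% moduleIds(db)))
        kept$shared_ko_fraction[i] <- sharedKoFraction(db, ida, idb)
    }
  }
  nodeInfo <- rbind(
    data.frame(id = edges$node_a, taxon = edges$taxon_a, kind = edges$kind_a,
               stringsAsFactors = FALSE),
    data.frame(id = edges$node_b, taxon = edges$taxon_b, kind = edges$kind_b,
               stringsAsFactors = FALSE))
  nodeInfo <- nodeInfo[!duplicated(nodeInfo$id), , drop = FALSE]
  if (dropSingletons)
    nodeInfo <- nodeInfo[nodeInfo$id %in% c(kept$node_a, kept$node_b), ,
                         drop = FALSE]
  rownames(nodeInfo) <- rownames(kept) <- NULL
  methods::new("CoexpressionNetwork", nodes = nodeInfo, edges = kept,
               power = beta,
               thresholds = list(minWeight = minWeight))
}
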