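## KO-level aggregation and taxon-stratified metabolic-module scoring.
## Gene values contributing to the same KO are summed on the normalized
## (pre-transform) scale; the hyperbolic arcsine is applied at KO level.

#' Aggregate normalized gene expression to KO level
#'
#' For every (taxon, KO, sample), the normalized per-taxon CPM values of
#' all genes annotated with that KO are summed and then arcsinh
#' transformed. A gene annotated with several KOs contributes its full
#' value to each. KOs with no gene surviving the low-expression filter are
#' absent from the result; samples in which the taxon is absent stay
#' missing.
#'
#' @param norm a [NormalizedCommunity-class].
#' @param koTable `data.frame` with columns `gene_id`, `ko` (one row per
#'   gene/KO assignment, as from [readKoTable()]).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"ko"`, rownames `"<taxon>|<ko>"` and rowData columns `taxon`, `ko`.
#' @export
aggregateKO <- function(norm, koTable) {
  stopifnot(all(c("gene_id", "ko") %in% colnames(koTable)))
  vals <- normValues(norm, transformed = FALSE)
  taxa <- geneTaxa(norm)
  kt <- koTable[koTable$gene_id %in% rownames(vals), , drop = FALSE]
  if (!nrow(kt)) stop("no annotated gene has an expression row")
  key <- paste(taxa[kt$gene_id], kt$ko, sep = "|")
  groups <- split(kt$gene_id, key)
  agg <- t(vapply(groups, function(g)
    colSums(vals[g, , drop = FALSE]), numeric(ncol(vals))))
  agg <- asinh(agg)
  info <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(ko = agg),
    rowData = S4Vectors::DataFrame(taxon = info[, 1], ko = info[, 2],
                                   row.names = names(groups)),
    colData = SummarizedExperiment::colData(norm))
}

#' Score taxon-stratified metabolic modules
#'
#' Implements module scoring over a KO-level expression matrix with the
#' conventions: an alternative's abundance is the minimum over its complex
#' members (absent KOs count as 0); a step's abundance is the maximum over
#' its alternatives; a step is *detected* iff some alternative has all its
#' complex members present in the KO matrix; coverage = detected steps /
#' total steps; the module score per sample is the `estimator` (median by
#' default) over the *detected* steps' abundances. Modules are scored per
#' taxon and emitted only where coverage >= `minCoverage`.
#'
#' @param ko KO-level [SummarizedExperiment::SummarizedExperiment] from
#'   [aggregateKO()].
#' @param db a [ModuleDatabase-class].
#' @param minCoverage minimum step coverage (default 0.5).
#' @param estimator `"median"` or `"mean"` over detected step abundances.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"score"`, rownames `"<taxon>|<module>"`, rowData columns `taxon`,
#'   `module`, `name`, `coverage`, and per-row step-detection vectors in
#'   `metadata()$stepDetection`.
#' @export
scoreModules <- function(ko, db, minCoverage = 0.5,
                         estimator = c("median", "mean")) {
  if (!is.character(estimator) ||
      !all(estimator %in% c("median", "mean")))
    stop("unknown estimator: ", paste(estimator, collapse = ", "))
  estimator <- match.arg(estimator)
  est <- match.fun(estimator)
  km <- SummarizedExperiment::assay(ko, "ko")
  rd <- SummarizedExperiment::rowData(ko)
  rows <- list(); info <- list(); detection <- list()
  for (t in unique(rd$taxon)) {
    sel <- rd$taxon == t
    sub <- km[sel, , drop = FALSE]
    koIds <- rd$ko[sel]
    rownames(sub) <- koIds
    for (mid in moduleIds(db)) {
      steps <- moduleSteps(db, mid)
      stepAb <- matrix(0, length(steps), ncol(sub))
      detected <- logical(length(steps))
      for (s in seq_along(steps)) {
        altAb <- vapply(steps[[s]], function(members) {
          present <- members %in% koIds
          if (!all(present)) return(rep(0, ncol(sub)))
          apply(sub[members, , drop = FALSE], 2, min)
        }, numeric(ncol(sub)))
        altAb <- matrix(altAb, ncol = length(steps[[s]]))
        detected[s] <- any(vapply(steps[[s]],
                                  function(m) all(m %in% koIds), logical(1)))
        stepAb[s, ] <- apply(altAb, 1, max)
      }
      coverage <- sum(detected) / length(steps)
      if (coverage < minCoverage) next
      score <- apply(stepAb[detected, , drop = FALSE], 2, est)
      key <- paste(t, mid, sep = "|")
      rows[[key]] <- score
      detection[[key]] <- detected
      info[[key]] <- data.frame(taxon = t, module = mid,
                                name = db[[mid]]@name, coverage = coverage,
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no module reaches the minimum coverage in any taxon")
  scores <- do.call(rbind, rows)
  colnames(scores) <- colnames(km)
  rd2 <- do.call(rbind, info)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(score = scores),
    rowData = S4Vectors::DataFrame(rd2, row.names = names(rows)),
    colData = SummarizedExperiment::colData(ko),
    metadata = list(stepDetection = detection,
                    minCoverage = minCoverage, estimator = estimator))
}

#' Fraction of KOs shared by two modules
#'
#' The Jaccard index of the two modules' KO sets (all KOs appearing in any
#' step or alternative). Within-species network edges between modules with
#' a high shared fraction are inflated by construction and should be
#' excluded from interpretation.
#'
#' @param db a [ModuleDatabase-class].
#' @param idA,idB module ids.
#' @return numeric in `[0, 1]`.
#' @examples
#' # identical modules -> 1; disjoint -> 0
#' @export
sharedKoFraction <- function(db, idA, idB) {
  a <- moduleKOs(db, idA); b <- moduleKOs(db, idB)
  length(intersect(a, b)) / length(union(a, b))
}
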