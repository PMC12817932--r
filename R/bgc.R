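## Boundary refinement of biosynthetic gene cluster (BGC) regions:
## antiSMASH-style regions are split into runs of co-located (intergenic
## distance <= 300 bp) and co-expressed (Pearson r > 0.5) genes, and
## retention filters are applied. Coordinates are 1-based inclusive;
## intergenic distance = next.start - prev.end - 1.

.subClusterRow <- function(regionId, suffix, members, cores, status, reason,
                           wholeRegion) {
  data.frame(region_id = regionId, suffix = suffix,
             members = I(list(members)), cores = I(list(cores)),
             n_members = length(members), status = status, reason = reason,
             whole_region = wholeRegion, stringsAsFactors = FALSE)
}

#' Split one BGC region into co-located, co-expressed sub-clusters
#'
#' Member genes are sorted by start coordinate and scanned pairwise: a
#' boundary is drawn between two neighbours when their intergenic distance
#' exceeds `maxGap`, when their expression correlation is not above `rMin`,
#' or when either gene lacks an expression row (genes removed by the
#' low-expression filter cannot be correlated and act as chain breakers;
#' they are recorded as unassigned). The resulting runs become sub-clusters
#' suffixed `"a"`, `"b"`, ... in coordinate order; a sub-cluster without a
#' core biosynthetic gene is marked discarded.
#'
#' @param region per-gene `data.frame` of one region with columns
#'   `gene_id`, `start`, `end`, `core` (and optionally `region_id`), as one
#'   region's rows from [readBgcRegions()].
#' @param expr expression matrix (genes x samples) of genes passing the
#'   low-expression filter, e.g. `normValues(norm)`.
#' @param maxGap maximum intergenic distance in bp (default 300).
#' @param rMin correlation threshold; neighbours must satisfy `r > rMin`
#'   (default 0.5).
#' @param linkage `"adjacent"` (default) tests each genomic neighbour pair;
#'   `"single"` lets a gene join the growing run if it correlates above
#'   `rMin` with *any* member of the run.
#' @return `data.frame` with one row per sub-cluster: `region_id`,
#'   `suffix`, `members` and `cores` (list columns, coordinate order),
#'   `n_members`, `status` (`"retained"`/`"discarded"`), `reason`,
#'   `whole_region`; unassigned gene ids in `attr(, "unassigned")`.
#' @export
refineRegion <- function(region, expr, maxGap = 300, rMin = 0.5,
                         linkage = c("adjacent", "single")) {
  linkage <- match.arg(linkage)
  if (!nrow(region)) stop("region has no member genes")
  region <- region[order(region$start), , drop = FALSE]
  regionId <- if ("region_id" %in% colnames(region)) region$region_id[1] else ""
  expressed <- region$gene_id %in% rownames(expr)
  runs <- list(); run <- integer(0)
  closeRun <- function() {
    if (length(run)) runs[[length(runs) + 1L]] <<- run
    run <<- integer(0)
  }
  for (i in seq_len(nrow(region))) {
    if (!expressed[i]) { closeRun(); next }
    if (!length(run)) { run <- i; next }
    prev <- run[length(run)]
    gap <- region$start[i] - region$end[prev] - 1
    linked <- if (linkage == "adjacent") {
      .pairCor(expr[region$gene_id[prev], ], expr[region$gene_id[i], ]) > rMin
    } else {
      any(vapply(run, function(j)
        .pairCor(expr[region$gene_id[j], ], expr[region$gene_id[i], ]) > rMin,
        logical(1)))
    }
    if (gap > maxGap || !isTRUE(linked)) closeRun()
    run <- c(run, i)
  }
  closeRun()
  out <- do.call(rbind, lapply(seq_along(runs), function(k) {
    idx <- runs[[k]]
    members <- region$gene_id[idx]
    cores <- members[region$core[idx]]
    hasCore <- length(cores) > 0
    .subClusterRow(regionId, .suffixLetter(k), members, cores,
                   status = if (hasCore) "retained" else "discarded",
                   reason = if (hasCore) "" else "no core gene",
                   wholeRegion = length(idx) == nrow(region))
  }))
  if (is.null(out))
    out <- .subClusterRow(regionId, character(0), list(), list(),
                          character(0), character(0), logical(0))[0, ]
  attr(out, "unassigned") <- region$gene_id[!expressed]
  out
}

.suffixLetter <- function(k) {
  if (k <= 26) letters[k]
  else paste0(letters[(k - 1) %/% 26], letters[(k - 1) %% 26 + 1])
}

.pairCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok]))
}

#' Wrap an unrefined region as a single sub-cluster record
#'
#' Lets the retention filters of [filterSubClusters()] be applied directly
#' to a whole region (members may include genes failing the expression
#' filter).
#'
#' @param region per-gene `data.frame` of one region (see [refineRegion()]).
#' @return a one-row sub-cluster `data.frame`.
#' @export
asSubCluster <- function(region) {
  region <- region[order(region$start), , drop = FALSE]
  regionId <- if ("region_id" %in% colnames(region)) region$region_id[1] else ""
  .subClusterRow(regionId, "a", region$gene_id, region$gene_id[region$core],
                 status = "retained", reason = "", wholeRegion = TRUE)
}

#' Apply the BGC retention filters
#'
#' A sub-cluster is discarded when (a) none of its core genes passes the
#' low-expression filter; (b) strictly more than `majorityFrac` of its
#' member genes fail the filter; or (c) no core gene attains a Pearson
#' correlation above `rCore` with any other member gene. A singleton
#' cluster fails rule (c) vacuously and is discarded unless it constitutes
#' the entire region, in which case it is retained with a flag. Every
#' discard is logged with its rule.
#'
#' @param clusters sub-cluster `data.frame` from [refineRegion()] /
#'   [asSubCluster()] (rows already discarded upstream are passed through).
#' @param passedGenes character vector of gene ids passing the
#'   low-expression filter.
#' @param expr expression matrix for the passing genes.
#' @param majorityFrac discard when the fraction of members failing the
#'   filter strictly exceeds this (default 0.7).
#' @param rCore minimum core-gene correlation (default 0.5).
#' @return list with `retained` (sub-cluster rows kept, with a `flag`
#'   column) and `audit` (`data.frame` of every discard: region, suffix,
#'   rule, reason).
#' @export
filterSubClusters <- function(clusters, passedGenes, expr,
                              majorityFrac = 0.7, rCore = 0.5) {
  audit <- list(); keep <- logical(nrow(clusters))
  flag <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    if (cl$status == "discarded") {
      audit[[length(audit) + 1L]] <- data.frame(
        region_id = cl$region_id, suffix = cl$suffix, rule = "core",
        reason = cl$reason, stringsAsFactors = FALSE)
      next
    }
    members <- cl$members[[1]]; cores <- cl$cores[[1]]
    drop <- function(rule, reason) {
      audit[[length(audit) + 1L]] <<- data.frame(
        region_id = cl$region_id, suffix = cl$suffix, rule = rule,
        reason = reason, stringsAsFactors = FALSE)
    }
    coresPass <- intersect(cores, passedGenes)
    if (!length(coresPass)) {
      drop("a", "no core gene passing the expression filter"); next
    }
    if (mean(!members %in% passedGenes) > majorityFrac) {
      drop("b", sprintf("majority of genes (> %d%%) below the expression filter",
                        round(100 * majorityFrac)))
      next
    }
    if (length(members) == 1) {
      if (isTRUE(cl$whole_region)) {
        keep[i] <- TRUE; flag[i] <- "singleton whole region"
      } else drop("c", "singleton: core-gene co-expression undefined")
      next
    }
    exprMembers <- intersect(members, rownames(expr))
    coresPass <- intersect(coresPass, rownames(expr))
    if (!length(coresPass)) {
      drop("c", "no core gene with an expression row"); next
    }
    rmax <- suppressWarnings(max(vapply(coresPass, function(cg) {
      others <- setdiff(exprMembers, cg)
      if (!length(others)) return(-Inf)
      max(vapply(others, function(o)
        .pairCor(expr[cg, ], expr[o, ]), numeric(1)), na.rm = TRUE)
    }, numeric(1)), na.rm = TRUE))
    if (!is.finite(rmax) || rmax <= rCore) {
      drop("c", sprintf("no core gene with r > %g to another member", rCore))
      next
    }
    keep[i] <- TRUE
  }
  retained <- clusters[keep, , drop = FALSE]
  retained$flag <- flag[keep]
  auditDf <- if (length(audit)) do.call(rbind, audit) else
    data.frame(region_id = character(0), suffix = character(0),
               rule = character(0), reason = character(0))
  list(retained = retained, audit = auditDf)
}

#' Eigengene of a gene cluster
#'
#' Summarizes a cluster's activity as the first principal component of its
#' scaled, log-transformed counts: each gene is `log2(count + 1)`
#' transformed and standardized across samples; the eigengene is the first
#' right singular vector (unit norm), sign-aligned so that its correlation
#' with the members' mean profile is non-negative.
#'
#' @param members character vector of at least two gene ids.
#' @param counts count matrix containing the member rows.
#' @return list with `eigengene` (named sample vector, unit norm),
#'   `varianceExplained` (fraction of total variance carried by the first
#'   component) and `nGenesUsed`.
#' @export
clusterEigengene <- function(members, counts) {
  stopifnot(length(members) >= 2)
  missing <- setdiff(members, rownames(counts))
  if (length(missing))
    stop("no expression rows for: ", paste(missing, collapse = ", "))
  x <- log2(counts[members, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene row(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("all member genes are constant")
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  e <- sv$v[, 1]
  meanProfile <- colMeans(xs)
  if (stats::cor(e, meanProfile) < 0) e <- -e
  names(e) <- colnames(counts)
  list(eigengene = e,
       varianceExplained = sv$d[1]^2 / sum(sv$d^2),
       nGenesUsed = nrow(xs))
}
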