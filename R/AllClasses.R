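#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CommunityCounts: community RNA-seq counts with a gene-to-taxon map
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `"counts"`
#' assay of non-negative integer read counts, one row per gene and one
#' column per sample. Each gene is assigned to exactly one taxon via the
#' `taxon` column of `rowData`; sample metadata (condition, time, replicate,
#' bioreactor, ...) live in `colData`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [CommunityCounts()] for the constructor, [readCounts()] to build
#'   one from TSV files.
#' @export
setClass("CommunityCounts", contains = "SummarizedExperiment")

setValidity("CommunityCounts", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts must not contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != floor(m))) msg <- c(msg, "counts must be integral")
    }
  }
  if (!"taxon" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'taxon' column")
  else if (anyNA(SummarizedExperiment::rowData(object)$taxon))
    msg <- c(msg, "every gene must be assigned to a taxon")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityCounts object
#'
#' @param counts gene-by-sample matrix of non-negative integer counts with
#'   row and column names.
#' @param taxa character vector mapping each gene (row) to a taxon, either
#'   named by gene id or in row order.
#' @param colData optional `data.frame`/`DataFrame` of sample metadata,
#'   rows matching the count columns.
#' @param metadata optional list of extra metadata.
#' @return a [CommunityCounts-class] object.
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cc <- CommunityCounts(m, taxa = c("A", "A", "B"))
#' @export
CommunityCounts <- function(counts, taxa, colData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  if (!is.null(names(taxa))) {
    missing <- setdiff(rownames(counts), names(taxa))
    if (length(missing))
      stop("no taxon assigned to gene(s): ", paste(head(missing, 5), collapse = ", "))
    taxa <- taxa[rownames(counts)]
  }
  if (length(taxa) != nrow(counts))
    stop("'taxa' must provide one taxon per gene")
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxon = as.character(taxa),
                                   row.names = rownames(counts)),
    colData = colData, metadata = metadata)
  methods::new("CommunityCounts", se)
}

#' NormalizedCommunity: per-taxon normalized community expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding per-taxon
#' TMM-normalized counts-per-million in the `"cpm"` assay. Samples in which
#' a taxon is not considered present carry `NA` (missing), never zero.
#'
#' @slot normFactors taxon-by-sample matrix of TMM scaling factors (`NA`
#'   where the taxon is absent). Within each taxon the factors over present
#'   samples have geometric mean 1.
#' @slot libSizes taxon-by-sample matrix of per-taxon library sizes.
#' @slot presence logical taxon-by-sample matrix: is the taxon present?
#' @slot removedGenes gene ids removed by the low-expression filter before
#'   normalization (as recorded on the input object).
#' @slot droppedTaxa taxa present in fewer than two samples, excluded.
#' @export
setClass("NormalizedCommunity", contains = "SummarizedExperiment",
  slots = c(normFactors = "matrix", libSizes = "matrix", presence = "matrix",
            removedGenes = "character", droppedTaxa = "character"))

setValidity("NormalizedCommunity", function(object) {
  msg <- character(0)
  if (!"cpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'cpm' is required")
  f <- object@normFactors
  if (any(f[!is.na(f)] <= 0)) msg <- c(msg, "normalization factors must be > 0")
  for (t in rownames(f)) {
    ft <- f[t, !is.na(f[t, ])]
    if (length(ft) && abs(exp(mean(log(ft))) - 1) > 1e-9)
      msg <- c(msg, sprintf("factors of taxon '%s' must have geometric mean 1", t))
  }
  if (any(object@removedGenes %in% rownames(object)))
    msg <- c(msg, "removed genes must be absent from the value matrix")
  if (length(msg)) msg else TRUE
})

#' ModuleDefinition: one metabolic module
#'
#' An ordered list of reaction steps; each step is a list of alternatives;
#' each alternative is a character vector of KEGG-ortholog (KO) ids, with
#' more than one id denoting an enzyme complex whose members are all
#' required.
#'
#' @slot id module identifier (e.g. `"MF0001"`).
#' @slot name human-readable module name.
#' @slot steps list of steps, each a list of KO-id character vectors.
#' @export
setClass("ModuleDefinition",
  representation(id = "character", name = "character", steps = "list"))

setValidity("ModuleDefinition", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "module id must be a single non-empty string")
  if (length(object@steps) < 1L)
    msg <- c(msg, sprintf("module '%s' has no steps", object@id))
  for (s in object@steps) {
    if (!is.list(s) || length(s) < 1L)
      msg <- c(msg, "every step needs at least one alternative")
    else for (alt in s)
      if (!is.character(alt) || length(alt) < 1L || any(!nzchar(alt)))
        msg <- c(msg, "KO ids must be non-empty strings")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' ModuleDatabase: a collection of metabolic module definitions
#'
#' @slot modules named list of [ModuleDefinition-class] objects, names equal
#'   to the module ids.
#' @seealso [readGmmDatabase()] for the flat-file reader.
#' @export
setClass("ModuleDatabase", representation(modules = "list"))

setValidity("ModuleDatabase", function(object) {
  ids <- vapply(object@modules, function(m) m@id, character(1))
  msg <- character(0)
  if (anyDuplicated(ids)) msg <- c(msg, "module ids must be unique")
  if (!identical(names(object@modules), unname(ids)))
    msg <- c(msg, "list names must equal module ids")
  if (length(msg)) msg else TRUE
})

#' ModuleDatabase constructor
#' @param modules list of [ModuleDefinition-class] objects.
#' @return a [ModuleDatabase-class].
#' @export
ModuleDatabase <- function(modules = list()) {
  names(modules) <- vapply(modules, function(m) m@id, character(1))
  methods::new("ModuleDatabase", modules = modules)
}

#' CoexpressionNetwork: thresholded signed co-expression network
#'
#' @slot nodes `data.frame` with columns `id`, `taxon`, `kind`.
#' @slot edges `data.frame` of retained edges (see [correlateFeatures()] for
#'   the column contract, plus `weight` and `shared_ko_fraction`).
#' @slot power soft-threshold power used for the signed adjacency.
#' @slot thresholds list of thresholds applied during construction.
#' @export
setClass("CoexpressionNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 power = "numeric", thresholds = "list"))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  msg <- character(0)
  if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-edges are not allowed")
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (any(abs(e$r) > 1 + 1e-12)) msg <- c(msg, "|r| must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapResult: bootstrap mean-shift test result
#'
#' @slot observedMean mean of the observed correlation set.
#' @slot poolSize,setSize sizes of the resampling pool and the observed set.
#' @slot iterations number of bootstrap iterations.
#' @slot seed seed used for resampling.
#' @slot pHigh,pLow one-sided empirical p-values (add-one corrected) for a
#'   mean higher resp. lower than expected by chance.
#' @slot nullMean,nullSd moments of the bootstrap null distribution.
#' @export
setClass("BootstrapResult",
  representation(observedMean = "numeric", poolSize = "numeric",
                 setSize = "numeric", iterations = "numeric", seed = "numeric",
                 pHigh = "numeric", pLow = "numeric",
                 nullMean = "numeric", nullSd = "numeric"))

setValidity("BootstrapResult", function(object) {
  msg <- character(0)
  if (object@iterations < 1) msg <- c(msg, "iterations must be >= 1")
  if (object@pHigh <= 0 || object@pHigh > 1 || object@pLow <= 0 || object@pLow > 1)
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CommunityConfig: parameters of the synthetic community generator
#'
#' See [communityConfig()] for the meaning and defaults of every parameter.
#' @export
setClass("CommunityConfig",
  representation(nTaxa = "numeric", genesPerTaxon = "numeric",
                 nSamples = "numeric", librarySizeRange = "numeric",
                 abundanceWalkSd = "numeric", nPrograms = "numeric",
                 dispersion = "numeric", confounderStrength = "numeric",
                 noiseSd = "numeric", latentAr = "numeric",
                 programLoadingRange = "numeric",
                 plantedLoadingRange = "numeric",
                 plantedInteractions = "data.frame", seed = "numeric"))

setValidity("CommunityConfig", function(object) {
  msg <- character(0)
  for (s in c("nTaxa", "genesPerTaxon", "nSamples", "nPrograms"))
    if (methods::slot(object, s) < 1) msg <- c(msg, paste(s, "must be >= 1"))
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@confounderStrength < 0) msg <- c(msg, "confounderStrength must be >= 0")
  if (length(object@librarySizeRange) != 2 || any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "librarySizeRange must be an increasing positive pair")
  p <- object@plantedInteractions
  if (nrow(p)) {
    if (any(p$coupling < 0 | p$coupling > 1))
      msg <- c(msg, "coupling strength must lie in [0, 1]")
    if (any(!p$sign %in% c(-1, 1))) msg <- c(msg, "sign must be -1 or +1")
    if (any(c(p$taxonA, p$taxonB) > object@nTaxa) || any(c(p$taxonA, p$taxonB) < 1))
      msg <- c(msg, "planted taxa must index existing taxa")
    if (any(c(p$featureA, p$featureB) > object@nPrograms))
      msg <- c(msg, "more planted features requested than latent programs exist")
    if (any(p$taxonA == p$taxonB & p$featureA == p$featureB))
      msg <- c(msg, "a planted pair must involve two distinct features")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted structure of a simulated community
#'
#' @slot planted `data.frame` of planted cross-species pairs (taxa, latent
#'   program ids, sign, coupling).
#' @slot genePrograms `data.frame` mapping each gene to its taxon and latent
#'   program.
#' @slot confounder shared environmental time-course (standardized).
#' @slot relAbundance taxon-by-sample relative abundance matrix.
#' @slot latent list per taxon of program-by-sample latent trajectories.
#' @slot expectedPresence logical taxon-by-sample matrix of expected
#'   presence at the default detection threshold.
#' @export
setClass("SyntheticTruth",
  representation(planted = "data.frame", genePrograms = "data.frame",
                 confounder = "numeric", relAbundance = "matrix",
                 latent = "list", expectedPresence = "matrix"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  p <- object@planted
  if (nrow(p)) {
    ## planted pairs index taxa (1..nTaxa) and latent programs
    feat <- paste(match(object@genePrograms$taxon,
                        rownames(object@relAbundance)),
                  object@genePrograms$program)
    ref <- c(paste(p$taxonA, p$featureA), paste(p$taxonB, p$featureB))
    if (!all(ref %in% feat))
      msg <- c(msg, "planted pairs must reference existing taxon/program features")
  }
  if (length(msg)) msg else TRUE
})
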