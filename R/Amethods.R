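#' @describeIn geneTaxa method for CommunityCounts
#' @export
setMethod("geneTaxa", "CommunityCounts", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$taxon, rownames(x))
})

#' @describeIn geneTaxa method for NormalizedCommunity
#' @export
setMethod("geneTaxa", "NormalizedCommunity", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$taxon, rownames(x))
})

#' Read counts of a CommunityCounts object
#' @param object a [CommunityCounts-class].
#' @return integer gene-by-sample matrix.
#' @export
setMethod("counts", "CommunityCounts", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @describeIn removedGenes genes recorded on a filtered count object
#' @export
setMethod("removedGenes", "CommunityCounts", function(x) {
  rg <- S4Vectors::metadata(x)$removedGenes
  if (is.null(rg)) character(0) else rg
})

#' @describeIn removedGenes genes removed before normalization
#' @export
setMethod("removedGenes", "NormalizedCommunity", function(x) x@removedGenes)

#' @describeIn presenceMatrix method for NormalizedCommunity
#' @export
setMethod("presenceMatrix", "NormalizedCommunity", function(x) x@presence)

#' @describeIn normFactors method for NormalizedCommunity
#' @export
setMethod("normFactors", "NormalizedCommunity", function(x) x@normFactors)

#' @describeIn normValues method for NormalizedCommunity
#' @export
setMethod("normValues", "NormalizedCommunity", function(x, transformed = TRUE) {
  v <- SummarizedExperiment::assay(x, "cpm")
  if (transformed) asinh(v) else v
})

#' @describeIn arcsinhTransform elementwise on numerics (matrices included)
#' @export
setMethod("arcsinhTransform", "ANY", function(x) {
  stopifnot(is.numeric(x))
  asinh(x)
})

#' @describeIn moduleIds method for ModuleDatabase
#' @export
setMethod("moduleIds", "ModuleDatabase", function(db) names(db@modules))

#' @describeIn moduleSteps method for ModuleDatabase
#' @export
setMethod("moduleSteps", "ModuleDatabase", function(db, id) {
  if (!id %in% names(db@modules)) stop("unknown module id: ", id)
  db@modules[[id]]@steps
})

#' @describeIn moduleKOs method for ModuleDatabase
#' @export
setMethod("moduleKOs", "ModuleDatabase", function(db, id) {
  unique(unlist(moduleSteps(db, id)))
})

#' Number of modules in a database
#' @param x a [ModuleDatabase-class].
#' @export
setMethod("length", "ModuleDatabase", function(x) length(x@modules))

#' Extract one module definition
#' @param x a [ModuleDatabase-class].
#' @param i module id or index.
#' @export
setMethod("[[", "ModuleDatabase", function(x, i) x@modules[[i]])

#' @describeIn networkNodes method for CoexpressionNetwork
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' @describeIn networkEdges method for CoexpressionNetwork
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

setMethod("show", "CommunityCounts", function(object) {
  taxa <- unique(SummarizedExperiment::rowData(object)$taxon)
  cat(sprintf("CommunityCounts: %d genes x %d samples, %d taxa\n",
              nrow(object), ncol(object), length(taxa)))
  methods::callNextMethod()
})

setMethod("show", "NormalizedCommunity", function(object) {
  cat(sprintf(
    "NormalizedCommunity: %d genes x %d samples (per-taxon TMM CPM)\n",
    nrow(object), ncol(object)))
  cat(sprintf("  taxa: %d (%d dropped), removed genes: %d\n",
              nrow(object@presence), length(object@droppedTaxa),
              length(object@removedGenes)))
})

setMethod("show", "ModuleDefinition", function(object) {
  cat(sprintf("ModuleDefinition %s (%s): %d steps\n",
              object@id, object@name, length(object@steps)))
})

setMethod("show", "ModuleDatabase", function(object) {
  cat(sprintf("ModuleDatabase with %d modules\n", length(object@modules)))
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf(
    "CoexpressionNetwork: %d nodes, %d edges (power %g, |weight| > %g)\n",
    nrow(object@nodes), nrow(object@edges), object@power,
    object@thresholds$minWeight))
  if (nrow(object@edges))
    cat(sprintf("  cross-species edges: %d\n", sum(object@edges$cross_species)))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    paste0("BootstrapResult: observed mean %.4f over %d values ",
           "(pool %d, B = %d)\n  p_high = %.3g, p_low = %.3g ",
           "(null %.4f +/- %.4f)\n"),
    object@observedMean, object@setSize, object@poolSize, object@iterations,
    object@pHigh, object@pLow, object@nullMean, object@nullSd))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d planted pairs, %d genes, %d taxa x %d samples\n",
    nrow(object@planted), nrow(object@genePrograms),
    nrow(object@relAbundance), ncol(object@relAbundance)))
})

setMethod("show", "CommunityConfig", function(object) {
  cat(sprintf(
    "CommunityConfig: %d taxa x %d genes x %d samples, %d planted pairs, seed %d\n",
    object@nTaxa, object@genesPerTaxon, object@nSamples,
    nrow(object@plantedInteractions), object@seed))
})
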