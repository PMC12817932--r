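#' Gene-to-taxon assignment
#' @param x a [CommunityCounts-class] or [NormalizedCommunity-class] object.
#' @return named character vector, gene id -> taxon.
#' @export
setGeneric("geneTaxa", function(x) standardGeneric("geneTaxa"))

#' Taxon presence per sample
#' @param x a [NormalizedCommunity-class] object.
#' @return logical taxon-by-sample matrix.
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' Per-taxon TMM normalization factors
#' @param x a [NormalizedCommunity-class] object.
#' @return taxon-by-sample matrix of factors (`NA` where the taxon is absent).
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' Genes removed by the low-expression filter
#' @param x a [CommunityCounts-class] or [NormalizedCommunity-class] object.
#' @return character vector of gene ids.
#' @export
setGeneric("removedGenes", function(x) standardGeneric("removedGenes"))

#' Normalized expression values
#' @param x a [NormalizedCommunity-class] object.
#' @param transformed apply the hyperbolic arcsine transform?
#' @return gene-by-sample numeric matrix with `NA` for absent-taxon samples.
#' @export
setGeneric("normValues", function(x, transformed = TRUE) standardGeneric("normValues"))

#' Hyperbolic arcsine transform
#'
#' `x -> ln(x + sqrt(x^2 + 1))`; a variance-stabilizing transform that is
#' defined at zero and behaves like `log(2x)` for large `x`. Missing values
#' stay missing.
#' @param x numeric vector or matrix.
#' @return object of the same shape.
#' @examples
#' arcsinhTransform(c(0, 1))  # 0 and ln(1 + sqrt(2))
#' @export
setGeneric("arcsinhTransform", function(x) standardGeneric("arcsinhTransform"))

#' Module ids of a database
#' @param db a [ModuleDatabase-class].
#' @return character vector of module ids.
#' @export
setGeneric("moduleIds", function(db) standardGeneric("moduleIds"))

#' Steps of one module
#' @param db a [ModuleDatabase-class].
#' @param id module id.
#' @return list of steps, each a list of KO-id character vectors.
#' @export
setGeneric("moduleSteps", function(db, id) standardGeneric("moduleSteps"))

#' All KOs of one module
#' @param db a [ModuleDatabase-class].
#' @param id module id.
#' @return character vector: the union of KO ids over all steps and
#'   alternatives.
#' @export
setGeneric("moduleKOs", function(db, id) standardGeneric("moduleKOs"))

#' Nodes of a co-expression network
#' @param x a [CoexpressionNetwork-class].
#' @return `data.frame` with columns `id`, `taxon`, `kind`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edges of a co-expression network
#' @param x a [CoexpressionNetwork-class].
#' @return `data.frame` of retained edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
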