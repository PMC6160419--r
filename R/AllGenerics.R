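#' Gene symbols of an interactome
#'
#' @param x a [WeightedInteractome-class] object.
#' @return character vector of node (gene) names.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Number of nodes / edges
#'
#' @param x a [WeightedInteractome-class] object.
#' @return integer scalar.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Canonical edge table of an interactome
#'
#' Returns one row per edge with `from < to` lexicographically, sorted by
#' `from` then `to`, so that two equal graphs produce identical tables.
#'
#' @param x a [WeightedInteractome-class] object.
#' @return `data.frame` with columns `from`, `to`, `weight`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Underlying igraph object
#'
#' @param x a [WeightedInteractome-class] object.
#' @return the wrapped \pkg{igraph} graph (vertex-named, edge attribute
#'   `weight`).
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Members of a module or neighborhood
#'
#' @param x a [DiseaseModule-class] or [NetworkNeighborhood-class] object.
#' @return character vector of gene symbols.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Linker genes of a disease module
#'
#' @param x a [DiseaseModule-class] object.
#' @return character vector of non-terminal linker genes.
#' @export
setGeneric("linkers", function(x) standardGeneric("linkers"))

#' Terminal genes of a disease module
#'
#' @param x a [DiseaseModule-class] object.
#' @return character vector of terminal genes.
#' @export
setGeneric("terminals", function(x) standardGeneric("terminals"))

#' Ranking table of a RankedGeneList
#'
#' @param x a [RankedGeneList-class] object.
#' @return `data.frame` with columns `gene`, `raw`, `adjusted`, `rank`.
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))
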