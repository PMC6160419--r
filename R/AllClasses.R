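#' @import methods
#' @importFrom igraph V E vcount ecount gorder gsize is_igraph
NULL

setOldClass("igraph")

#' Confidence-weighted protein-protein interaction network
#'
#' An undirected interactome whose nodes are gene symbols (uppercase,
#' unique) and whose edges carry a confidence score in \[0, 1\]. The class
#' wraps an \pkg{igraph} object and guarantees a canonical form: no
#' self-loops, no duplicate edges, every edge weighted.
#'
#' Use [WeightedInteractome()] or [readEdgeList()] to construct objects;
#' access the underlying graph with [asIgraph()], the gene symbols with
#' [nodes()], and the canonical edge table with [edgeTable()].
#'
#' @slot graph an undirected, vertex-named \pkg{igraph} object whose
#'   `weight` edge attribute holds the confidence scores.
#'
#' @seealso [readEdgeList()], [networkSummary()]
#' @export
setClass("WeightedInteractome", representation(graph = "igraph"))

setValidity("WeightedInteractome", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("slot 'graph' is not an igraph object")
  if (igraph::is_directed(g)) return("interactome must be undirected")
  if (igraph::gorder(g) > 0L) {
    nm <- igraph::V(g)$name
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      return("all nodes must be named")
    if (anyDuplicated(nm)) return("node names must be unique")
    if (!identical(nm, toupper(trimws(nm))))
      return("node names must be uppercase and whitespace-stripped")
  }
  if (igraph::gsize(g) > 0L) {
    w <- igraph::E(g)$weight
    if (is.null(w)) return("all edges must carry a 'weight' attribute")
    if (anyNA(w) || any(w < 0) || any(w > 1))
      return("edge confidences must lie in [0, 1]")
    if (igraph::any_loop(g)) return("self-loops are not allowed")
    if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  }
  TRUE
})

#' Degree-adjusted random-walk ranking of genes
#'
#' Ordered ranking of the non-seed genes of an interactome produced by
#' [degreeAdjustedRanks()]. Each entry records the raw restart-walk score,
#' the degree-adjusted score (raw score divided by the no-restart
#' stationary score), and the 1-based rank. The ordering merges the raw
#' and adjusted orderings by worst rank, with a lexicographic tie-break
#' on the gene symbol (see [degreeAdjustedRanks()]).
#'
#' @slot entries `data.frame` with columns `gene`, `raw`, `adjusted`,
#'   `rank`.
#' @slot seeds character vector of mapped seed genes (excluded from the
#'   ranking).
#' @slot restart restart probability used for the walk.
#'
#' @export
setClass("RankedGeneList",
  representation(entries = "data.frame", seeds = "character",
                 restart = "numeric"))

setValidity("RankedGeneList", function(object) {
  e <- object@entries
  need <- c("gene", "raw", "adjusted", "rank")
  if (!all(need %in% names(e))) return("entries must have gene/raw/adjusted/rank")
  n <- nrow(e)
  if (n > 0L) {
    if (!identical(sort(e$rank), seq_len(n))) return("ranks must be 1..n without gaps")
    if (is.unsorted(e$rank)) return("entries must be ordered by rank")
  }
  TRUE
})

#' Seed-containing network neighborhood
#'
#' The connected components, among seed genes plus the top-ranked genes,
#' that contain at least one seed. Produced by [buildNeighborhood()].
#'
#' @slot components list of character vectors, one per seed-containing
#'   connected component of the induced subgraph, sorted by decreasing size.
#' @slot neighborhood character vector, the union of all components.
#' @slot seeds mapped seed genes.
#' @slot cutoffK number of top-ranked non-seed genes that were considered.
#' @slot seedless list of character vectors: connected components of the
#'   candidate set containing no seed (reported, not part of the
#'   neighborhood).
#'
#' @export
setClass("NetworkNeighborhood",
  representation(components = "list", neighborhood = "character",
                 seeds = "character", cutoffK = "integer",
                 seedless = "list"))

setValidity("NetworkNeighborhood", function(object) {
  comps <- object@components
  if (length(comps)) {
    all_genes <- unlist(comps, use.names = FALSE)
    if (anyDuplicated(all_genes)) return("components must be disjoint")
    if (!setequal(all_genes, object@neighborhood))
      return("neighborhood must equal the union of its components")
    if (!all(vapply(comps, function(cc) any(cc %in% object@seeds), logical(1))))
      return("every component must contain a seed")
  }
  if (object@cutoffK < 0L) return("cutoffK must be non-negative")
  TRUE
})

#' Parameters of the confidence-weighted closeness statistic
#'
#' Bundle of tuning parameters for the closeness machinery: the grid of
#' `p` values of the edge length `ln(p/w)`, the reporting `p`, the number
#' of random draws, the Z-score significance threshold, and the RNG seed.
#'
#' @slot pGrid numeric vector of `p` values, all `>= 1`; default
#'   `exp(c(0, 1, 2, 10))`.
#' @slot reportP the single `p` at which significance is called (default
#'   `exp(1)`); must be one of `pGrid`.
#' @slot nRand number of random draws for the null (default 10000).
#' @slot zThreshold significance threshold on the Z-score (default -1.6,
#'   the normal quantile for a one-sided p of about 0.05).
#' @slot rngSeed integer seed, or `NA` to leave the RNG stream alone.
#' @slot aggregate `"mean"` (default) or `"sum"`: how node-to-set
#'   distances are aggregated over the target set.
#'
#' @seealso [cabParams()]
#' @export
setClass("CabParams",
  representation(pGrid = "numeric", reportP = "numeric", nRand = "integer",
                 zThreshold = "numeric", rngSeed = "integer",
                 aggregate = "character"))

setValidity("CabParams", function(object) {
  if (any(object@pGrid < 1)) return("all p values must be >= 1")
  if (length(object@reportP) != 1L ||
      !any(abs(object@pGrid - object@reportP) < 1e-12))
    return("reportP must be one of pGrid")
  if (object@nRand < 100L) return("nRand must be at least 100")
  if (!object@aggregate %in% c("mean", "sum"))
    return("aggregate must be 'mean' or 'sum'")
  TRUE
})

#' Assembled disease network module
#'
#' A single connected subnetwork containing all terminal genes (network
#' neighborhood plus significant candidates) and the minimal set of
#' non-terminal linker genes discovered by the greedy Steiner strategy.
#' Produced by [greedySteiner()] / [assembleModule()].
#'
#' @slot terminals terminal genes the tree was required to span.
#' @slot linkers non-terminal genes added to connect the terminals.
#' @slot members union of terminals and linkers.
#' @slot moduleEdges `data.frame` (`from`, `to`, `weight`): the induced
#'   subgraph of the interactome on `members`.
#' @slot treeEdges `data.frame` (`from`, `to`, `cost`): the pruned
#'   Steiner tree itself.
#' @slot treeCost total edge cost of the pruned tree.
#' @slot provenance `data.frame` (`gene`, `role`) labelling members as
#'   seed / neighborhood / candidate / linker (filled by
#'   [assembleModule()]).
#'
#' @export
setClass("DiseaseModule",
  representation(terminals = "character", linkers = "character",
                 members = "character", moduleEdges = "data.frame",
                 treeEdges = "data.frame", treeCost = "numeric",
                 provenance = "data.frame"))

setValidity("DiseaseModule", function(object) {
  if (length(intersect(object@terminals, object@linkers)))
    return("linkers and terminals must be disjoint")
  if (!setequal(object@members, union(object@terminals, object@linkers)))
    return("members must equal terminals plus linkers")
  TRUE
})
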