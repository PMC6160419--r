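#' Greedy Steiner connection of terminal genes
#'
#' Connects a set of terminal genes into a single subnetwork by a
#' distance-based greedy component-merging heuristic (the classical
#' 2-approximation family for Steiner trees): starting from the
#' connected components of the terminal-induced subgraph, the two
#' components with the smallest inter-component shortest path under the
#' `ln(p/w)` edge costs are repeatedly joined along that path, until one
#' component remains; non-terminal leaves of the resulting tree are then
#' pruned. Ties are broken deterministically (smallest endpoint names,
#' then lexicographically smallest path).
#'
#' If the terminals span several connected components of the interactome
#' itself, each is assembled separately with a warning.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param terminalGenes character vector of terminal genes; all must map
#'   to the network.
#' @param p model parameter for the edge costs (default `exp(1)`).
#' @param hops if `TRUE`, use unweighted (unit) edge costs instead.
#' @return a [DiseaseModule-class] object.
#' @examples
#' g <- WeightedInteractome(data.frame(c("A", "X"), c("X", "B"), 0.9))
#' linkers(greedySteiner(g, c("A", "B")))  # "X"
#' @export
greedySteiner <- function(x, terminalGenes, p = exp(1), hops = FALSE) {
  stopifnot(is(x, "WeightedInteractome"))
  terminalGenes <- unique(.canonSymbols(terminalGenes))
  unmapped <- setdiff(terminalGenes, nodes(x))
  if (length(unmapped))
    stop("terminal gene(s) not in the network: ",
         paste(unmapped, collapse = ", "))
  g <- x@graph
  cost <- .edgeCosts(g, p, hops = hops)
  gcomp <- igraph::components(g)$membership
  tsplit <- split(terminalGenes, gcomp[terminalGenes])
  if (length(tsplit) > 1L)
    warning("terminals span ", length(tsplit),
            " interactome components; assembling each separately")
  pieces <- lapply(tsplit, function(tt) .steinerOne(g, cost, tt))
  members <- unlist(lapply(pieces, `[[`, "members"), use.names = FALSE)
  treeEdges <- do.call(rbind, lapply(pieces, `[[`, "treeEdges"))
  rownames(treeEdges) <- NULL
  sub <- igraph::induced_subgraph(g, members)
  moduleEdges <- edgeTable(new("WeightedInteractome", graph = sub))
  new("DiseaseModule",
      terminals = sort(terminalGenes),
      linkers = sort(setdiff(members, terminalGenes)),
      members = sort(members),
      moduleEdges = moduleEdges, treeEdges = treeEdges,
      treeCost = sum(treeEdges$cost),
      provenance = data.frame(gene = character(0), role = character(0)))
}

# Assemble one interactome component. Returns members + tree edges.
.steinerOne <- function(g, cost, terminalGenes) {
  emptyTree <- data.frame(from = character(0), to = character(0),
                          cost = numeric(0), stringsAsFactors = FALSE)
  if (length(terminalGenes) == 1L)
    return(list(members = terminalGenes, treeEdges = emptyTree))
  sub <- igraph::induced_subgraph(g, terminalGenes)
  cl <- igraph::components(sub)
  groups <- lapply(split(igraph::V(sub)$name, cl$membership), sort)
  groups <- unname(groups[order(vapply(groups, `[`, character(1), 1L),
                                method = "radix")])
  edges <- list()
  addPathEdges <- function(path) {
    if (length(path) < 2L) return()
    eid <- igraph::get_edge_ids(g, rbind(path[-length(path)], path[-1L]))
    edges[[length(edges) + 1L]] <<- data.frame(
      from = path[-length(path)], to = path[-1L], cost = cost[eid],
      stringsAsFactors = FALSE)
  }
  while (length(groups) > 1L) {
    allN <- unlist(groups, use.names = FALSE)
    grp <- rep(seq_along(groups), lengths(groups))
    o <- order(allN, method = "radix")
    allN <- allN[o]; grp <- grp[o]
    d <- igraph::distances(g, v = allN, to = allN, weights = cost)
    d[outer(grp, grp, "==")] <- Inf
    best <- min(d)
    if (is.infinite(best))
      stop("internal error: components not connectable")
    hit <- which(d <= best + 1e-12, arr.ind = TRUE)
    # deterministic pick: smallest source name, then target name
    hit <- hit[order(allN[hit[, 1L]], allN[hit[, 2L]],
                     method = "radix"), , drop = FALSE]
    from <- allN[hit[1L, 1L]]; to <- allN[hit[1L, 2L]]
    asp <- igraph::all_shortest_paths(g, from = from, to = to,
                                      weights = cost)
    vp <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
    path <- .lexMinPath(lapply(vp, function(v)
      igraph::V(g)$name[as.integer(v)]))
    addPathEdges(path)
    touched <- vapply(groups, function(gg) any(path %in% gg), logical(1))
    merged <- sort(unique(c(unlist(groups[touched], use.names = FALSE),
                            path)))
    groups <- c(groups[!touched], list(merged))
  }
  treeEdges <- if (length(edges)) do.call(rbind, edges) else emptyTree
  # initial groups may contain induced edges worth keeping in the tree:
  # take the minimum spanning forest of (induced terminal edges + paths)
  vset <- sort(unique(c(terminalGenes, treeEdges$from, treeEdges$to)))
  indSub <- igraph::induced_subgraph(g, vset)
  indTab <- igraph::as_edgelist(indSub)
  eid <- if (nrow(indTab)) igraph::get_edge_ids(g, t(indTab)) else integer(0)
  allEdges <- unique(rbind(treeEdges,
    if (nrow(indTab)) data.frame(from = pmin(indTab[, 1], indTab[, 2]),
                                 to = pmax(indTab[, 1], indTab[, 2]),
                                 cost = cost[eid],
                                 stringsAsFactors = FALSE)
    else emptyTree))
  tg <- igraph::graph_from_data_frame(allEdges, directed = FALSE,
                                      vertices = vset)
  tree <- igraph::mst(tg, weights = allEdges$cost)
  # prune non-terminal leaves until none remain
  repeat {
    deg <- igraph::degree(tree)
    drop <- names(deg)[deg <= 1L & !(names(deg) %in% terminalGenes)]
    if (!length(drop)) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  el <- igraph::as_edgelist(tree)
  te <- if (nrow(el))
    data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
               cost = igraph::E(tree)$cost, stringsAsFactors = FALSE)
  else emptyTree
  list(members = igraph::V(tree)$name, treeEdges = te)
}

#' Assemble the disease network module
#'
#' Takes the network neighborhood and the candidates called significant
#' by the closeness statistic as terminals, connects them with
#' [greedySteiner()], and labels every member by provenance: `seed`,
#' `neighborhood`, `candidate`, or `linker`.
#'
#' @param neighborhood a [NetworkNeighborhood-class] object.
#' @param significant character vector of significant candidate genes
#'   (may be empty).
#' @param x a [WeightedInteractome-class] object.
#' @param p model parameter for the Steiner edge costs (default
#'   `exp(1)`).
#' @param hops if `TRUE`, unweighted Steiner costs.
#' @return a [DiseaseModule-class] object with a filled provenance
#'   table.
#' @export
assembleModule <- function(neighborhood, significant, x, p = exp(1),
                           hops = FALSE) {
  stopifnot(is(neighborhood, "NetworkNeighborhood"),
            is(x, "WeightedInteractome"))
  significant <- unique(.canonSymbols(significant))
  terms <- union(neighborhood@neighborhood, significant)
  mod <- greedySteiner(x, terms, p = p, hops = hops)
  role <- ifelse(mod@members %in% neighborhood@seeds, "seed",
          ifelse(mod@members %in% neighborhood@neighborhood, "neighborhood",
          ifelse(mod@members %in% significant, "candidate", "linker")))
  mod@provenance <- data.frame(gene = mod@members, role = role,
                               stringsAsFactors = FALSE)
  mod
}

#' @rdname members
#' @export
setMethod("members", "DiseaseModule", function(x) x@members)

#' @rdname linkers
#' @export
setMethod("linkers", "DiseaseModule", function(x) x@linkers)

#' @rdname terminals
#' @export
setMethod("terminals", "DiseaseModule", function(x) x@terminals)

setMethod("show", "DiseaseModule", function(object) {
  cat("DiseaseModule:", length(object@members), "genes (",
      length(object@terminals), "terminals +", length(object@linkers),
      "linkers )\n")
  if (length(object@linkers))
    cat("  linkers:", paste(object@linkers, collapse = ", "), "\n")
  if (nrow(object@provenance))
    print(table(object@provenance$role))
  cat("  induced edges:", nrow(object@moduleEdges),
      "; tree cost:", signif(object@treeCost, 6), "\n")
})
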