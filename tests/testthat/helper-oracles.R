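# Independent oracles and small graph builders used across the suite.
# The oracles deliberately avoid the code paths they check: path costs by
# exhaustive simple-path enumeration over a plain adjacency list, walk
# scores by a dense linear solve, clustering by literal triangle counting,
# Steiner optima by exhaustive subset search.

# Build a WeightedInteractome from vectors.
wi <- function(from, to, w = 1) {
  WeightedInteractome(data.frame(from = from, to = to, w = w,
                                 stringsAsFactors = FALSE))
}

# Random connected graph on n nodes with edge probability pe and
# U(0.1, 1) confidences; resamples until connected.
randomConnectedGraph <- function(n, pe = 0.45) {
  nm <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- t(combn(nm, 2))
    keep <- runif(nrow(pairs)) < pe
    if (sum(keep) < n - 1) next
    g <- wi(pairs[keep, 1], pairs[keep, 2], runif(sum(keep), 0.1, 1))
    if (numNodes(g) == n &&
        igraph::is_connected(asIgraph(g))) return(g)
  }
}

# Exhaustive minimum path cost between two nodes under ln(p/w) edge
# costs, by depth-first enumeration of all simple paths on an adjacency
# list (no graph library involved).
enumMinDist <- function(g, from, to, p) {
  et <- edgeTable(g)
  adj <- list()
  addE <- function(a, b, w) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(nb = b, w = w))
  }
  for (i in seq_len(nrow(et))) {
    addE(et$from[i], et$to[i], et$weight[i])
    addE(et$to[i], et$from[i], et$weight[i])
  }
  best <- Inf
  walk <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    nbrs <- adj[[node]]
    if (is.null(nbrs)) return()
    for (i in seq_len(nrow(nbrs))) {
      nb <- nbrs$nb[i]
      if (nb %in% visited) next
      walk(nb, c(visited, nb), cost + log(p / nbrs$w[i]))
    }
  }
  walk(from, from, 0)
  best
}

# Dense linear-solve oracle for the restart walk restricted to the
# component(s) containing the seeds.
denseRWR <- function(g, seeds, restart, weighted = TRUE) {
  ig <- asIgraph(g)
  comp <- igraph::components(ig)$membership
  keep <- names(comp)[comp %in% comp[seeds]]
  A <- igraph::as_adjacency_matrix(ig, attr = if (weighted) "weight",
                                   sparse = FALSE)[keep, keep,
                                                   drop = FALSE]
  P <- A / rowSums(A)
  u <- ifelse(keep %in% seeds, 1 / length(seeds), 0)
  s <- solve(diag(length(keep)) - (1 - restart) * t(P), restart * u)
  out <- setNames(numeric(numNodes(g)), nodes(g))
  out[keep] <- s
  out
}

# Brute-force average local clustering (nodes of degree < 2 count 0).
bruteClustering <- function(g) {
  ig <- asIgraph(g)
  nm <- nodes(g)
  vals <- vapply(nm, function(v) {
    nb <- names(igraph::neighbors(ig, v))
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (igraph::are_adjacent(ig, nb[i], nb[j])) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

# Exact minimum Steiner tree cost by exhaustive search over subsets of
# non-terminal nodes: the optimum equals the cheapest spanning tree of
# the induced subgraph over terminals plus some subset.
exactSteinerCost <- function(g, terminalGenes, p = exp(1)) {
  ig <- asIgraph(g)
  cost <- log(p / igraph::E(ig)$weight)
  others <- setdiff(nodes(g), terminalGenes)
  best <- Inf
  for (k in 0:length(others)) {
    combs <- if (k == 0) list(character(0)) else
      asplit(combn(others, k), 2)
    for (extra in combs) {
      vs <- c(terminalGenes, extra)
      sub <- igraph::induced_subgraph(ig, vs)
      if (!igraph::is_connected(sub)) next
      eid <- igraph::get_edge_ids(ig, t(igraph::as_edgelist(sub)))
      subcost <- cost[eid]
      tr <- igraph::mst(sub, weights = subcost)
      trid <- igraph::get_edge_ids(ig, t(igraph::as_edgelist(tr)))
      best <- min(best, sum(cost[trid]))
    }
  }
  best
}

# Default-configuration synthetic study used by several suites.
makeStudy <- function(rngSeed = 1L, ...) {
  cfg <- simConfig(rngSeed = rngSeed, ...)
  g0 <- generateInteractome(cfg)
  pm <- plantModule(g0, cfg)
  pd <- generatePulldown(pm$interactome, pm$module, cfg)
  list(cfg = cfg, interactome = pd$interactome, module = pm$module,
       seeds = pm$seeds, partners = pd$partners, proximal = pd$proximal)
}
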