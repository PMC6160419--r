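#' Closeness statistic parameters
#'
#' Constructor for [CabParams-class]. The edge length used throughout is
#' `ln(p / w)` for an edge of confidence `w`: at `p = 1` the length of a
#' path is `-ln` of the product of its confidences (a path-existence
#' probability), while for large `p` the length approaches
#' `hops * ln(p)` and depends on topology alone.
#'
#' @param pGrid numeric vector of `p` values (default
#'   `exp(c(0, 1, 2, 10))`).
#' @param reportP the `p` at which significance is called (default
#'   `exp(1)`, balancing hop count against confidence).
#' @param nRand random draws for the null (default 10000).
#' @param zThreshold Z-score significance cutoff (default -1.6).
#' @param rngSeed integer seed or `NULL`.
#' @param aggregate `"mean"` (default) or `"sum"` aggregation of
#'   node-to-set distances.
#' @return a [CabParams-class] object.
#' @export
cabParams <- function(pGrid = exp(c(0, 1, 2, 10)), reportP = exp(1),
                      nRand = 10000L, zThreshold = -1.6, rngSeed = NULL,
                      aggregate = c("mean", "sum")) {
  new("CabParams", pGrid = as.numeric(pGrid), reportP = as.numeric(reportP),
      nRand = as.integer(nRand), zThreshold = as.numeric(zThreshold),
      rngSeed = if (is.null(rngSeed)) NA_integer_ else as.integer(rngSeed),
      aggregate = match.arg(aggregate))
}

setMethod("show", "CabParams", function(object) {
  cat("CabParams: p grid {", paste(signif(log(object@pGrid), 3),
      collapse = ", "), "} (log scale), report p = e^",
      signif(log(object@reportP), 3), "\n", sep = "")
  cat("  n_rand =", object@nRand, ", z threshold =", object@zThreshold,
      ", aggregate =", object@aggregate, "\n")
})

#' Confidence-weighted edge length
#'
#' The length assigned to an edge of confidence `w` under model
#' parameter `p`: `ln(p / w)`, which is always non-negative for
#' `0 < w <= 1` and `p >= 1`.
#'
#' @param w edge confidence in (0, 1\].
#' @param p model parameter, `>= 1`.
#' @return non-negative numeric.
#' @examples
#' edgeLength(1, 1)          # 0
#' edgeLength(0.5, exp(1))   # 1 + log(2)
#' @export
edgeLength <- function(w, p) {
  if (any(w <= 0)) stop("zero-confidence edge: drop it upstream")
  stopifnot(all(w <= 1), all(p >= 1))
  log(p / w)
}

#' Minimum confidence-weighted distance between two genes
#'
#' Shortest path between `source` and `target` under edge lengths
#' `ln(p/w)`. Ties between equally short paths are broken by the
#' lexicographically smallest node-name sequence.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param source,target gene symbols present in the network.
#' @param p model parameter (default `exp(1)`).
#' @return list with `source`, `target`, `length` (`Inf` if
#'   unreachable), `hops` (edge count of the chosen path; `NA` if
#'   unreachable), and `path` (character vector of nodes; empty if
#'   unreachable).
#' @export
minWeightedDistance <- function(x, source, target, p = exp(1)) {
  stopifnot(is(x, "WeightedInteractome"))
  g <- x@graph
  source <- .canonSymbols(source); target <- .canonSymbols(target)
  missing <- setdiff(c(source, target), nodes(x))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  if (source == target)
    return(list(source = source, target = target, length = 0,
                hops = 0L, path = source))
  len <- .edgeCosts(g, p)
  d <- as.numeric(igraph::distances(g, v = source, to = target,
                                    weights = len))
  if (is.infinite(d))
    return(list(source = source, target = target, length = Inf,
                hops = NA_integer_, path = character(0)))
  asp <- igraph::all_shortest_paths(g, from = source, to = target,
                                    weights = len)
  vp <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
  paths <- lapply(vp, function(v) igraph::V(g)$name[as.integer(v)])
  path <- .lexMinPath(paths)
  list(source = source, target = target, length = d,
       hops = length(path) - 1L, path = path)
}

# Distance from every node of the graph to a target set: for each gene l,
# the mean (or sum) of shortest-path lengths ln(p/w) from l to the
# reachable members of `module`, excluding l itself when it belongs to
# the set. Returns value vector (NA where nothing is reachable) plus
# per-node reachable counts.
.moduleDistances <- function(g, module, p, aggregate = "mean") {
  len <- .edgeCosts(g, p)
  d <- igraph::distances(g, v = module, to = igraph::V(g), weights = len)
  self <- match(module, colnames(d))
  ok <- !is.na(self)
  d[cbind(which(ok), self[ok])] <- NA       # exclude self-distances
  d[is.infinite(d)] <- NA
  nr <- colSums(!is.na(d))
  tot <- colSums(d, na.rm = TRUE)
  val <- if (aggregate == "mean") tot / nr else tot
  val[nr == 0L] <- NA
  list(value = val, nReachable = nr)
}

#' Distance from a gene to a gene set
#'
#' Mean (default) or sum of minimum weighted path lengths from `source`
#' to the members of `targetSet`, excluding `source` itself and any
#' unreachable members (which are counted separately).
#'
#' @param x a [WeightedInteractome-class] object.
#' @param source gene symbol.
#' @param targetSet non-empty character vector of gene symbols.
#' @param p model parameter (default `exp(1)`).
#' @param aggregate `"mean"` or `"sum"`.
#' @return list with `source`, `mean_length`, `n_reachable`,
#'   `n_unreachable`.
#' @export
setDistance <- function(x, source, targetSet, p = exp(1),
                        aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(x, "WeightedInteractome"))
  source <- .canonSymbols(source)
  targetSet <- unique(.canonSymbols(targetSet))
  if (!length(targetSet)) stop("empty target set")
  missing <- setdiff(c(source, targetSet), nodes(x))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  targets <- setdiff(targetSet, source)
  len <- .edgeCosts(x@graph, p)
  d <- as.numeric(igraph::distances(x@graph, v = source, to = targets,
                                    weights = len))
  reach <- is.finite(d)
  if (!any(reach))
    stop("no member of the target set is reachable from ", source)
  val <- if (aggregate == "mean") mean(d[reach]) else sum(d[reach])
  list(source = source, mean_length = val, n_reachable = sum(reach),
       n_unreachable = sum(!reach))
}

# Draw the null distances for one p: node-to-module distances of nodes
# sampled uniformly (with replacement) from `pool`. If nRand >= |pool|
# the null is computed exhaustively over the pool, which makes the
# Z-scores exactly invariant under node relabelling.
.nullDistances <- function(dvec, pool, nRand) {
  vals <- if (nRand >= length(pool)) dvec[pool]
          else dvec[sample(pool, nRand, replace = TRUE)]
  vals[!is.na(vals)]
}

#' Closeness Z-score of one candidate gene to a module
#'
#' Observed node-to-set distance of `candidate` to `module`, compared
#' with the distances of randomly drawn non-module genes: the Z-score is
#' `(observed - mean(null)) / sd(null)`, negative when the candidate is
#' closer than chance. Computed for every `p` in `params@pGrid`; the
#' `significant` flag applies the threshold `z <= zThreshold`.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param candidate gene symbol, not a member of `module`.
#' @param module character vector of module genes.
#' @param params a [CabParams-class] object.
#' @return `data.frame` with one row per `p`: `candidate`, `p`,
#'   `log_p`, `observed`, `null_mean`, `null_sd`, `z`, `empirical_p`,
#'   `significant`.
#' @export
closenessZscore <- function(x, candidate, module, params = cabParams()) {
  stopifnot(is(x, "WeightedInteractome"), is(params, "CabParams"))
  candidate <- .canonSymbols(candidate)
  module <- unique(.canonSymbols(module))
  if (candidate %in% module) stop("candidate is a module member")
  res <- scoreCandidates(x, candidate, module, params)
  res$results
}

#' Score candidate genes for closeness to a module
#'
#' Computes, for every mapped candidate and every `p` in the grid, the
#' observed distance to the module and its randomization Z-score. All
#' candidates share one null sample per `p` (common random numbers),
#' drawn uniformly from the non-module genes. Significance is called at
#' `params@reportP` with `z <= params@zThreshold`.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param candidates character vector; genes absent from the network are
#'   reported in `unmapped`, candidates with no path to the module in
#'   `unreachable`.
#' @param module character vector of module genes.
#' @param params a [CabParams-class] object.
#' @return list with `results` (`data.frame` sorted by `z` ascending
#'   within each `p`), `significant` (character vector of candidates
#'   significant at the reporting `p`), `unmapped`, and `unreachable`.
#' @export
scoreCandidates <- function(x, candidates, module, params = cabParams()) {
  stopifnot(is(x, "WeightedInteractome"), is(params, "CabParams"))
  candidates <- unique(.canonSymbols(candidates))
  module <- unique(.canonSymbols(module))
  module <- intersect(module, nodes(x))
  if (!length(module)) stop("module does not map to the network")
  unmapped <- setdiff(candidates, nodes(x))
  mapped <- setdiff(candidates, unmapped)
  inModule <- intersect(mapped, module)
  if (length(inModule)) {
    warning("dropping candidate(s) already in the module: ",
            paste(inModule, collapse = ", "))
    mapped <- setdiff(mapped, inModule)
  }
  g <- x@graph
  pool <- setdiff(nodes(x), module)
  rows <- list()
  unreachable <- character(0)
  seed0 <- params@rngSeed
  for (i in seq_along(params@pGrid)) {
    p <- params@pGrid[i]
    md <- .moduleDistances(g, module, p, params@aggregate)
    dvec <- md$value
    null <- .withSeed(if (is.na(seed0)) NULL else seed0 + i,
                      .nullDistances(dvec, pool, params@nRand))
    if (stats::sd(null) == 0)
      stop("degenerate null (zero variance) at p = e^", round(log(p), 3))
    nm <- mean(null); ns <- stats::sd(null)
    obs <- dvec[mapped]
    unreachable <- union(unreachable, mapped[is.na(obs)])
    okc <- mapped[!is.na(obs)]
    if (!length(okc)) next
    obs <- obs[okc]
    z <- (obs - nm) / ns
    rows[[i]] <- data.frame(
      candidate = okc, p = p, log_p = log(p), observed = as.numeric(obs),
      null_mean = nm, null_sd = ns, z = as.numeric(z),
      empirical_p = vapply(obs, function(o) .empiricalP(null, o, "le"),
                           numeric(1)),
      significant = as.numeric(z) <= params@zThreshold,
      stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(results))
    results <- data.frame(candidate = character(0), p = numeric(0),
                          log_p = numeric(0), observed = numeric(0),
                          null_mean = numeric(0), null_sd = numeric(0),
                          z = numeric(0), empirical_p = numeric(0),
                          significant = logical(0))
  o <- order(results$log_p, results$z, results$candidate, method = "radix")
  results <- results[o, , drop = FALSE]
  rownames(results) <- NULL
  atReport <- results[abs(results$p - params@reportP) < 1e-12, ,
                      drop = FALSE]
  sig <- atReport$candidate[atReport$significant]
  list(results = results, significant = sig, unmapped = unmapped,
       unreachable = unreachable)
}

#' Cohesion Z-score of a gene set
#'
#' Tests whether the members of a gene set are closer to each other in
#' the interactome than equally sized random node sets: the observed
#' mean pairwise minimum weighted distance (reachable pairs only) is
#' compared against `nRand` uniformly sampled sets of the same size.
#' Evaluated at `params@reportP`.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param geneSet character vector; at least two members must map.
#' @param params a [CabParams-class] object.
#' @return list of class `netmod_cohesion` with `n_mapped`,
#'   `observed_mean_pairwise`, `null_mean`, `null_sd`, `z`,
#'   `empirical_p`, `n_rand`.
#' @export
cohesionZscore <- function(x, geneSet, params = cabParams()) {
  stopifnot(is(x, "WeightedInteractome"), is(params, "CabParams"))
  geneSet <- unique(.canonSymbols(geneSet))
  mapped <- intersect(geneSet, nodes(x))
  if (length(mapped) < 2L)
    stop("need at least 2 mapped genes (got ", length(mapped), ")")
  g <- x@graph
  len <- .edgeCosts(g, params@reportP)
  meanPairwise <- function(vs) {
    d <- igraph::distances(g, v = vs, to = vs, weights = len)
    vals <- d[upper.tri(d)]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  observed <- meanPairwise(mapped)
  if (is.na(observed)) stop("no reachable pair in the gene set")
  k <- length(mapped)
  all_nodes <- nodes(x)
  null <- .withSeed(if (is.na(params@rngSeed)) NULL else params@rngSeed,
    vapply(seq_len(params@nRand),
           function(i) meanPairwise(sample(all_nodes, k)), numeric(1)))
  null <- null[!is.na(null)]
  out <- list(n_mapped = k, observed_mean_pairwise = observed,
              null_mean = mean(null), null_sd = stats::sd(null),
              z = .zscore(observed, mean(null), stats::sd(null)),
              empirical_p = .empiricalP(null, observed, "le"),
              n_rand = params@nRand)
  class(out) <- "netmod_cohesion"
  out
}

#' @export
print.netmod_cohesion <- function(x, ...) {
  cat(sprintf(
    "Cohesion of %d genes: observed %.3f vs null %.3f +/- %.3f -> z = %.3f (p = %.4g)\n",
    x$n_mapped, x$observed_mean_pairwise, x$null_mean, x$null_sd, x$z,
    x$empirical_p))
  invisible(x)
}
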