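#' Local radiality of a gene with respect to a module
#'
#' Purely topological comparator to the confidence-weighted closeness:
#' the average unweighted shortest-path (hop) distance from `candidate`
#' to the members of `module`. When the candidate itself belongs to the
#' module its self-distance of 0 enters the average. Unreachable members
#' are excluded from the mean and counted. Smaller scores mean closer.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param candidate gene symbol present in the network.
#' @param module non-empty character vector of gene symbols.
#' @return list with `gene`, `score`, `n_reachable`.
#' @examples
#' g <- WeightedInteractome(data.frame(c("A", "B"), c("B", "C"), 1))
#' localRadiality(g, "A", c("B", "C"))$score  # (1 + 2) / 2
#' @export
localRadiality <- function(x, candidate, module) {
  stopifnot(is(x, "WeightedInteractome"))
  candidate <- .canonSymbols(candidate)
  module <- unique(.canonSymbols(module))
  if (!length(module)) stop("empty module")
  if (!candidate %in% nodes(x)) stop("unknown gene: ", candidate)
  mapped <- intersect(module, nodes(x))
  if (!length(mapped)) stop("module does not map to the network")
  d <- as.numeric(igraph::distances(x@graph, v = candidate, to = mapped,
                                    weights = NA))
  reach <- is.finite(d)
  if (!any(reach))
    stop("no module member reachable from ", candidate)
  list(gene = candidate, score = mean(d[reach]),
       n_reachable = sum(reach))
}

#' Rank candidates by local radiality
#'
#' Convenience wrapper applying [localRadiality()] to several candidates
#' and returning them sorted by score ascending (ties broken
#' lexicographically).
#'
#' @inheritParams localRadiality
#' @param candidates character vector of gene symbols; genes absent from
#'   the network are dropped with a message.
#' @return `data.frame` with columns `gene`, `score`, `n_reachable`.
#' @export
localRadialityRank <- function(x, candidates, module) {
  candidates <- unique(.canonSymbols(candidates))
  mapped <- intersect(candidates, nodes(x))
  if (length(mapped) < length(candidates))
    message(length(candidates) - length(mapped),
            " candidate(s) not in the network dropped")
  rows <- lapply(mapped, function(cc) {
    r <- localRadiality(x, cc, module)
    data.frame(gene = r$gene, score = r$score,
               n_reachable = r$n_reachable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the degrees of two gene sets
#'
#' Two-sided rank-sum (Mann-Whitney) test on the interactome degrees of
#' two gene sets, e.g. the top candidates selected by two proximity
#' methods. Reports the mean degree of each set.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param setA,setB non-empty character vectors mapping to the network.
#' @return list with `u` (rank-sum statistic), `p_value`,
#'   `mean_degree_a`, `mean_degree_b`, `n_a`, `n_b`.
#' @export
degreeComparison <- function(x, setA, setB) {
  stopifnot(is(x, "WeightedInteractome"))
  setA <- intersect(unique(.canonSymbols(setA)), nodes(x))
  setB <- intersect(unique(.canonSymbols(setB)), nodes(x))
  if (!length(setA) || !length(setB))
    stop("both gene sets must have at least one mapped member")
  deg <- igraph::degree(x@graph)
  da <- deg[setA]; db <- deg[setB]
  if (identical(sort(as.numeric(da)), sort(as.numeric(db)))) {
    # identical samples: no evidence of a difference
    wt <- list(statistic = stats::setNames(length(da) * length(db) / 2,
                                           "W"), p.value = 1)
  } else {
    wt <- stats::wilcox.test(da, db, alternative = "two.sided",
                             exact = length(da) < 20 && length(db) < 20)
  }
  list(u = unname(wt$statistic), p_value = wt$p.value,
       mean_degree_a = mean(da), mean_degree_b = mean(db),
       n_a = length(da), n_b = length(db))
}
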