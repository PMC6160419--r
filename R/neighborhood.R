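#' Random walk with restart over a weighted interactome
#'
#' Computes the stationary distribution of a random walk that, at every
#' step, restarts with probability `restart` at a uniformly chosen mapped
#' seed and otherwise moves to a neighbor with probability proportional
#' to the edge confidence. The walk runs on the connected component(s)
#' containing seeds; genes elsewhere score exactly 0. Scores sum to 1.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param seeds character vector of seed gene symbols; at least one must
#'   map to the network.
#' @param restart restart probability in (0, 1); default 0.75.
#' @param weighted if `TRUE` (default) transition probabilities are
#'   proportional to edge confidences; if `FALSE` the unweighted topology
#'   is used.
#' @param tol fixed-point residual tolerance (default 1e-10).
#' @param maxIter iteration cap for the power method.
#' @return named numeric vector of scores over all genes, summing to 1.
#' @examples
#' g <- WeightedInteractome(data.frame(c("A"), c("B"), 1))
#' randomWalkRestart(g, "A", restart = 0.5)  # c(A = 2/3, B = 1/3)
#' @export
randomWalkRestart <- function(x, seeds, restart = 0.75, weighted = TRUE,
                              tol = 1e-10, maxIter = 100000L) {
  stopifnot(is(x, "WeightedInteractome"), restart > 0, restart < 1)
  g <- x@graph
  all_nodes <- nodes(x)
  seeds <- unique(.canonSymbols(seeds))
  mapped <- intersect(seeds, all_nodes)
  if (!length(mapped))
    stop("no seed maps to the network; unmapped: ",
         paste(seeds, collapse = ", "))
  comp <- igraph::components(g)$membership
  keep <- which(comp %in% comp[mapped])
  sub <- igraph::induced_subgraph(g, keep)
  sub_nodes <- igraph::V(sub)$name
  A <- igraph::as_adjacency_matrix(sub,
         attr = if (weighted) "weight" else NULL, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) {       # isolated seed: walker stays put
    iso <- which(rs == 0)
    A[cbind(iso, iso)] <- 1
    rs[iso] <- 1
  }
  M <- Matrix::t(Matrix::Diagonal(x = 1 / rs) %*% A)
  u <- numeric(length(sub_nodes))
  u[match(mapped, sub_nodes)] <- 1 / length(mapped)
  s <- u
  for (i in seq_len(maxIter)) {
    s2 <- as.numeric((1 - restart) * (M %*% s)) + restart * u
    if (max(abs(s2 - s)) < tol) { s <- s2; break }
    s <- s2
  }
  out <- stats::setNames(numeric(length(all_nodes)), all_nodes)
  out[sub_nodes] <- s
  out
}

#' Degree-adjusted random-walk ranking
#'
#' Ranks all non-seed genes by merging two orderings of the restart
#' walk: the raw propagation score, and the degree-adjusted score (the
#' raw score divided by the stationary score of the same walk with no
#' restart, which is proportional to node strength). A gene's final
#' position is its worst (largest) rank under the two orderings, ties
#' broken lexicographically by gene symbol. The raw ordering alone is
#' biased toward hubs; the adjusted ordering alone amplifies score
#' noise among weakly connected genes far from the seeds (a tiny score
#' divided by an even tinier reference); the worst-rank merge keeps
#' only genes that both orderings place high. Genes outside the seed
#' components get raw and adjusted scores of 0 and rank last.
#'
#' @inheritParams randomWalkRestart
#' @return a [RankedGeneList-class] object.
#' @export
degreeAdjustedRanks <- function(x, seeds, restart = 0.75, weighted = TRUE) {
  raw <- randomWalkRestart(x, seeds, restart = restart, weighted = weighted)
  g <- x@graph
  all_nodes <- names(raw)
  seeds <- intersect(unique(.canonSymbols(seeds)), all_nodes)
  str <- igraph::strength(g,
           weights = if (weighted) igraph::E(g)$weight
                     else rep(1, igraph::gsize(g)))
  # reference = stationary law of the no-restart walk on the seed
  # component(s): proportional to node strength there, zero elsewhere
  comp <- igraph::components(g)$membership
  walk_nodes <- all_nodes[comp %in% comp[seeds]]
  ref <- stats::setNames(numeric(length(all_nodes)), all_nodes)
  ref[walk_nodes] <- str[walk_nodes] / sum(str[walk_nodes])
  adj <- ifelse(ref > 0, raw / ref, 0)
  keep <- setdiff(all_nodes, seeds)
  df <- data.frame(gene = keep, raw = as.numeric(raw[keep]),
                   adjusted = as.numeric(adj[keep]),
                   stringsAsFactors = FALSE)
  worst <- pmax(rank(-df$raw, ties.method = "average"),
                rank(-df$adjusted, ties.method = "average"))
  o <- order(worst, df$gene, method = "radix")
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  new("RankedGeneList", entries = df, seeds = seeds,
      restart = restart)
}

#' @rdname ranking
#' @export
setMethod("ranking", "RankedGeneList", function(x) x@entries)

setMethod("show", "RankedGeneList", function(object) {
  cat("RankedGeneList:", nrow(object@entries), "genes ranked around",
      length(object@seeds), "seeds (restart =", object@restart, ")\n")
  print(utils::head(object@entries, 5L))
  if (nrow(object@entries) > 5L) cat("  ...\n")
})

#' Neighborhood boundary from gene-level association p-values
#'
#' Slides a window of size `window` down the ranking; at each position a
#' one-sided rank-sum test compares the window's association p-values to
#' all p-values further down the ranking. The boundary is the last gene
#' of the final window of the initial, contiguous run of significant
#' windows (significant at level `alpha`); this contiguous-run rule is
#' what makes the "plateau" operational and is robust to isolated
#' false-positive windows deep in the ranking. Returns 0 when even the
#' first window shows no enrichment.
#'
#' @param ranked a [RankedGeneList-class] object.
#' @param pvals named numeric vector of gene-level association p-values
#'   in (0, 1\]; must cover at least 80\% of the ranked genes (uncovered
#'   genes are skipped with a message).
#' @param window window size (>= 10; default 25).
#' @param alpha significance level for the window test (default 0.05).
#' @param forceK optional integer; when given, returned verbatim without
#'   any detection (the published-analysis override).
#' @return integer cutoff `k`: the number of top-ranked genes inside the
#'   boundary (a rank in the original ranking), or 0.
#' @export
plateauCutoff <- function(ranked, pvals, window = 25L, alpha = 0.05,
                          forceK = NULL) {
  if (!is.null(forceK)) return(as.integer(forceK))
  stopifnot(is(ranked, "RankedGeneList"), window >= 10L)
  e <- ranked@entries
  p <- pvals[e$gene]
  covered <- !is.na(p) & p > 0 & p <= 1
  if (mean(covered) < 0.8)
    stop("association p-values cover only ",
         round(100 * mean(covered)), "% of ranked genes (need >= 80%)")
  if (any(!covered))
    message(sum(!covered), " ranked gene(s) without a p-value skipped")
  pv <- as.numeric(p[covered])
  orig_rank <- e$rank[covered]
  n <- length(pv)
  if (n < window + 1L) stop("fewer ranked genes than the window size")
  last_sig <- 0L
  for (s in seq_len(n - window)) {
    w <- pv[s:(s + window - 1L)]
    bg <- pv[(s + window):n]
    pw <- stats::wilcox.test(w, bg, alternative = "less",
                             exact = FALSE)$p.value
    if (is.na(pw) || pw >= alpha) break
    last_sig <- s
  }
  if (last_sig == 0L) return(0L)
  as.integer(orig_rank[last_sig + window - 1L])
}

#' Constructor for NetworkNeighborhood
#'
#' Direct constructor, mainly useful for assembling a neighborhood from
#' externally defined components (e.g. published gene lists).
#'
#' @param components list of character vectors (each containing at least
#'   one seed).
#' @param seeds character vector of seed genes.
#' @param cutoffK integer: number of added top-ranked genes.
#' @param seedless list of seedless components (default empty).
#' @return a [NetworkNeighborhood-class] object.
#' @export
NetworkNeighborhood <- function(components, seeds, cutoffK = 0L,
                                seedless = list()) {
  components <- lapply(components, .canonSymbols)
  components <- components[order(-lengths(components))]
  new("NetworkNeighborhood", components = components,
      neighborhood = unique(unlist(components, use.names = FALSE)),
      seeds = .canonSymbols(seeds), cutoffK = as.integer(cutoffK),
      seedless = seedless)
}

#' Extract the seed-containing network neighborhood
#'
#' Takes the mapped seeds plus the top `cutoffK` ranked genes, induces
#' their subgraph, and keeps the connected components that contain at
#' least one seed. Genes falling in seedless components are reported in
#' the `seedless` slot but are not part of the neighborhood.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param ranked a [RankedGeneList-class] from [degreeAdjustedRanks()].
#' @param seeds character vector of seed genes.
#' @param cutoffK number of top-ranked non-seed genes to add (>= 0).
#' @return a [NetworkNeighborhood-class] object.
#' @export
buildNeighborhood <- function(x, ranked, seeds, cutoffK) {
  stopifnot(is(x, "WeightedInteractome"), is(ranked, "RankedGeneList"),
            cutoffK >= 0L)
  seeds <- intersect(unique(.canonSymbols(seeds)), nodes(x))
  e <- ranked@entries
  top <- e$gene[e$rank <= cutoffK]
  cand <- union(seeds, top)
  sub <- igraph::induced_subgraph(x@graph, cand)
  cl <- igraph::components(sub)
  comps <- split(igraph::V(sub)$name, cl$membership)
  has_seed <- vapply(comps, function(cc) any(cc %in% seeds), logical(1))
  seeded <- unname(comps[has_seed])
  seeded <- lapply(seeded, function(cc) sort(cc))
  seedless <- unname(comps[!has_seed])
  NetworkNeighborhood(seeded, seeds, cutoffK = cutoffK,
                      seedless = seedless)
}

#' @rdname members
#' @export
setMethod("members", "NetworkNeighborhood", function(x) x@neighborhood)

setMethod("show", "NetworkNeighborhood", function(object) {
  cat("NetworkNeighborhood:", length(object@neighborhood), "genes in",
      length(object@components), "seed-containing component(s)\n")
  cat("  component sizes:",
      paste(lengths(object@components), collapse = ", "), "\n")
  cat("  seeds:", length(object@seeds), "; cutoff k =", object@cutoffK,
      "\n")
  if (length(object@seedless))
    cat("  plus", length(object@seedless), "seedless component(s) (",
        sum(lengths(object@seedless)), "genes ) excluded\n")
})

#' Significance of the largest connected component of a gene set
#'
#' Compares the size of the largest connected component (LCC) induced by
#' `genes` against the LCC sizes of `nRand` equally sized node sets
#' placed uniformly at random in the interactome. Reports the Z-score
#' and the add-one empirical p-value `(1 + #{null >= observed}) /
#' (1 + nRand)`.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param genes character vector of gene symbols (must map to the
#'   network, non-empty).
#' @param nRand number of random placements (>= 100; default 10000).
#' @param seed integer RNG seed for reproducibility (optional).
#' @param degreeBinned if `TRUE`, random sets are sampled within degree
#'   bins (log2-spaced) matching the observed set instead of uniformly.
#' @return list of class `netmod_lcc` with `lcc_size`, `null_mean`,
#'   `null_sd`, `z`, `empirical_p`, `n_rand`, `seed`.
#' @export
lccSignificance <- function(x, genes, nRand = 10000L, seed = NULL,
                            degreeBinned = FALSE) {
  stopifnot(is(x, "WeightedInteractome"), nRand >= 100L)
  genes <- unique(.canonSymbols(genes))
  if (!length(genes)) stop("empty gene set")
  unmapped <- setdiff(genes, nodes(x))
  if (length(unmapped))
    stop("genes not in the network: ", paste(unmapped, collapse = ", "))
  g <- x@graph
  idx <- match(genes, igraph::V(g)$name)
  lcc <- function(vids) {
    max(igraph::components(igraph::induced_subgraph(g, vids))$csize)
  }
  observed <- lcc(idx)
  n <- igraph::gorder(g)
  k <- length(idx)
  sampler <- if (degreeBinned) {
    deg <- igraph::degree(g)
    bins <- pmax(0L, floor(log2(pmax(deg, 1L))))
    byBin <- split(seq_len(n), bins)
    need <- table(bins[idx])
    function() unlist(lapply(names(need), function(b)
      sample(byBin[[b]], need[[b]])), use.names = FALSE)
  } else {
    function() sample.int(n, k)
  }
  null <- .withSeed(seed,
    vapply(seq_len(nRand), function(i) lcc(sampler()), numeric(1)))
  out <- list(lcc_size = observed, null_mean = mean(null),
              null_sd = stats::sd(null),
              z = .zscore(observed, mean(null), stats::sd(null)),
              empirical_p = .empiricalP(null, observed, "ge"),
              n_rand = nRand, seed = seed)
  class(out) <- "netmod_lcc"
  out
}

#' @export
print.netmod_lcc <- function(x, ...) {
  cat(sprintf(
    "LCC size %d vs null %.2f +/- %.2f (n_rand = %d): z = %.2f, p = %.4g\n",
    x$lcc_size, x$null_mean, x$null_sd, x$n_rand, x$z, x$empirical_p))
  invisible(x)
}
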