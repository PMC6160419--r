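#' Construct a WeightedInteractome from an edge table
#'
#' Canonicalizes an edge table into a [WeightedInteractome-class]: gene
#' symbols are uppercased and whitespace-stripped, self-loops are dropped
#' (with a message reporting the count), and duplicate edges are collapsed
#' keeping the maximum confidence.
#'
#' @param edges `data.frame` whose first two columns are gene symbols and
#'   whose optional third column is the edge confidence in \[0, 1\]
#'   (missing column defaults to 1, which yields an unweighted network).
#' @return a [WeightedInteractome-class] object.
#' @examples
#' g <- WeightedInteractome(data.frame(a = c("a", "b"), b = c("b", "c"),
#'                                     w = c(0.5, 0.9)))
#' nodes(g)
#' @export
WeightedInteractome <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  from <- toupper(trimws(as.character(edges[[1L]])))
  to <- toupper(trimws(as.character(edges[[2L]])))
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  if (anyNA(w)) stop("non-numeric confidence value")
  if (any(w < 0 | w > 1))
    stop("confidence outside [0, 1] at row(s) ",
         paste(utils::head(which(w < 0 | w > 1), 5L), collapse = ", "))
  loops <- from == to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
  }
  zero <- w == 0
  if (any(zero)) {
    # zero confidence = infinite path length = absent edge
    message("dropped ", sum(zero), " zero-confidence edge(s)")
    from <- from[!zero]; to <- to[!zero]; w <- w[!zero]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  if (length(a)) {
    key <- paste(a, b, sep = "\x01")
    w <- vapply(split(w, key), max, numeric(1))
    ab <- strsplit(names(w), "\x01", fixed = TRUE)
    a <- vapply(ab, `[`, character(1), 1L)
    b <- vapply(ab, `[`, character(1), 2L)
  }
  o <- order(a, b, method = "radix")
  df <- data.frame(from = a[o], to = b[o], weight = as.numeric(w[o]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  new("WeightedInteractome", graph = g)
}

#' Read a confidence-weighted edge list
#'
#' Reads a tab-separated edge list (`geneA geneB confidence`) into a
#' canonical [WeightedInteractome-class]. The confidence column is
#' optional and defaults to 1. Symbols are uppercased, duplicate edges
#' keep the maximum confidence, and self-loops are dropped.
#'
#' @param path path to the TSV file.
#' @param header logical; skip one header line (default `FALSE`).
#' @param defaultConfidence confidence assigned when the third column is
#'   absent (default 1).
#' @return a [WeightedInteractome-class] object.
#' @export
readEdgeList <- function(path, header = FALSE, defaultConfidence = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new("WeightedInteractome",
               graph = igraph::make_empty_graph(0, directed = FALSE)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed row (fewer than 2 columns) at line ",
         which(nf < 2L)[1L] + as.integer(header))
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, `[`, character(1), 2L)
  conf <- vapply(parts, function(p)
    if (length(p) >= 3L) p[[3L]] else NA_character_, character(1))
  w <- suppressWarnings(as.numeric(conf))
  if (any(bad <- !is.na(conf) & is.na(w)))
    stop("non-numeric confidence at line ",
         which(bad)[1L] + as.integer(header))
  w[is.na(conf)] <- defaultConfidence
  if (any(bad <- w < 0 | w > 1))
    stop("confidence outside [0, 1] at line ",
         which(bad)[1L] + as.integer(header))
  WeightedInteractome(data.frame(from, to, w, stringsAsFactors = FALSE))
}

#' Write an interactome as a canonical edge list
#'
#' @param x a [WeightedInteractome-class] object.
#' @param path output TSV path (columns `from`, `to`, `weight`, no
#'   header).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  et <- edgeTable(x)
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene set from a plain-text file
#'
#' One symbol per line; `#` starts a comment; blank lines ignored;
#' symbols uppercased and deduplicated.
#'
#' @param path path to the file.
#' @return character vector of gene symbols.
#' @export
readGeneSet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  unique(.canonSymbols(lines))
}

#' Write a gene set to a plain-text file
#'
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(unique(.canonSymbols(genes)), path)
  invisible(path)
}

#' @rdname nodes
#' @export
setMethod("nodes", "WeightedInteractome", function(x) {
  if (igraph::gorder(x@graph) == 0L) character(0) else igraph::V(x@graph)$name
})

#' @rdname numNodes
#' @export
setMethod("numNodes", "WeightedInteractome",
          function(x) igraph::gorder(x@graph))

#' @rdname numNodes
#' @export
setMethod("numEdges", "WeightedInteractome",
          function(x) igraph::gsize(x@graph))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "WeightedInteractome", function(x) {
  if (igraph::gsize(x@graph) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  el <- igraph::as_edgelist(x@graph)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  o <- order(a, b, method = "radix")
  data.frame(from = a[o], to = b[o],
             weight = igraph::E(x@graph)$weight[o],
             stringsAsFactors = FALSE)
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "WeightedInteractome", function(x) x@graph)

setMethod("show", "WeightedInteractome", function(object) {
  cat("WeightedInteractome with", numNodes(object), "genes and",
      numEdges(object), "interactions\n")
  if (numEdges(object) > 0L) {
    w <- igraph::E(object@graph)$weight
    cat(sprintf("  confidence range: [%.3f, %.3f]\n", min(w), max(w)))
  }
})

#' Summarize a weighted interactome
#'
#' Global network statistics: node and edge counts, mean degree
#' `2M/N`, the average local clustering coefficient (nodes of degree < 2
#' contribute 0), and the upper tail of the degree distribution at the
#' requested thresholds.
#'
#' @param x a [WeightedInteractome-class] object; must be non-empty.
#' @param degreeThresholds integer vector of degree thresholds `t`; for
#'   each, the count and fraction of nodes with degree `>= t` is
#'   reported.
#' @return a list of class `netmod_summary` with elements `n_nodes`,
#'   `n_edges`, `mean_degree`, `clustering_coefficient`, and
#'   `degree_tail` (a `data.frame` with columns `threshold`, `count`,
#'   `fraction`).
#' @examples
#' tri <- WeightedInteractome(data.frame(c("A", "B", "C"),
#'                                       c("B", "C", "A"), 1))
#' networkSummary(tri)
#' @export
networkSummary <- function(x, degreeThresholds = integer(0)) {
  stopifnot(is(x, "WeightedInteractome"))
  g <- x@graph
  n <- igraph::gorder(g)
  if (n == 0L) stop("cannot summarize an empty graph")
  m <- igraph::gsize(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  tail <- data.frame(threshold = as.integer(degreeThresholds),
                     count = vapply(degreeThresholds,
                                    function(t) sum(deg >= t), numeric(1)))
  tail$fraction <- tail$count / n
  out <- list(n_nodes = n, n_edges = m, mean_degree = 2 * m / n,
              clustering_coefficient = mean(cc), degree_tail = tail)
  class(out) <- "netmod_summary"
  out
}

#' @export
print.netmod_summary <- function(x, ...) {
  cat(sprintf("Interactome: N = %d genes, M = %d links\n", x$n_nodes,
              x$n_edges))
  cat(sprintf("  mean degree <k> = %.2f, clustering <C> = %.3f\n",
              x$mean_degree, x$clustering_coefficient))
  if (nrow(x$degree_tail))
    for (i in seq_len(nrow(x$degree_tail)))
      cat(sprintf("  P(k >= %d) = %.2f (%d genes)\n",
                  x$degree_tail$threshold[i], x$degree_tail$fraction[i],
                  x$degree_tail$count[i]))
  invisible(x)
}
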