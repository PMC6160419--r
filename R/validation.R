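#' Read a differential-expression table
#'
#' Reads a limma-style TSV with (case-insensitive) columns for the gene
#' symbol, log fold change, raw p-value and adjusted p-value. Accepted
#' aliases: `gene` / `gene.symbol` / `symbol`; `logFC`; `P.Value` /
#' `pvalue` / `p`; `adj.P.Val` / `adj.p.value` / `padj` / `fdr`.
#' Symbols are uppercased; duplicate genes are collapsed keeping the row
#' with the smallest raw p-value.
#'
#' @param path path to the TSV file (with header).
#' @param dataset label for the dataset (default: file name).
#' @return `data.frame` with columns `gene`, `logFC`, `P.Value`,
#'   `adj.P.Val` and attribute `dataset`.
#' @export
readDETable <- function(path, dataset = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  findCol <- function(aliases, what) {
    hit <- which(tolower(names(raw)) %in% aliases)
    if (!length(hit)) stop("missing required column: ", what)
    hit[1L]
  }
  gi <- findCol(c("gene", "gene.symbol", "symbol", "gene_symbol"), "gene")
  fi <- findCol(c("logfc", "log_fc"), "logFC")
  pi <- findCol(c("p.value", "pvalue", "p_value", "p"), "P.Value")
  ai <- findCol(c("adj.p.val", "adj.p.value", "adj_p", "adj_p_val",
                  "padj", "fdr"), "adj.P.Val")
  out <- data.frame(gene = toupper(trimws(raw[[gi]])),
                    logFC = as.numeric(raw[[fi]]),
                    P.Value = as.numeric(raw[[pi]]),
                    adj.P.Val = as.numeric(raw[[ai]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$P.Value), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset") <- dataset
  out
}

#' Fold-change comparison of module versus background DE genes
#'
#' Among genes differentially expressed at raw `p < pThresh`, compares
#' the absolute log fold changes of module genes against all other DE
#' genes with a two-sided rank-sum test (exact below 20 observations per
#' group, normal approximation above).
#'
#' @param module character vector of module genes.
#' @param table a DE table from [readDETable()] (or any `data.frame`
#'   with those columns).
#' @param pThresh raw p-value filter defining "differentially
#'   expressed" (default 0.05).
#' @return list of class `netmod_validation`: `dataset`, `n_module_de`,
#'   `n_background_de`, `median_absfc_module`,
#'   `median_absfc_background`, `u_stat`, `p_value`, `direction`.
#' @export
foldchangeComparison <- function(module, table, pThresh = 0.05) {
  module <- unique(.canonSymbols(module))
  if (!any(module %in% table$gene))
    stop("no module gene is present in the DE table")
  de <- table[table$P.Value < pThresh, , drop = FALSE]
  inMod <- de$gene %in% module
  a <- abs(de$logFC[inMod]); b <- abs(de$logFC[!inMod])
  if (length(a) < 3L || length(b) < 3L)
    stop("too few DE genes after filtering: ", length(a), " module vs ",
         length(b), " background")
  exact <- length(a) < 20L && length(b) < 20L
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact)
  out <- list(dataset = attr(table, "dataset"),
              n_module_de = length(a), n_background_de = length(b),
              median_absfc_module = stats::median(a),
              median_absfc_background = stats::median(b),
              u_stat = unname(wt$statistic), p_value = wt$p.value,
              direction = if (stats::median(a) >= stats::median(b))
                "module_higher" else "module_lower")
  class(out) <- "netmod_validation"
  out
}

#' @export
print.netmod_validation <- function(x, ...) {
  cat(sprintf(
    "%s: %d module DE vs %d background DE genes; median |logFC| %.3f vs %.3f (%s), p = %.4g\n",
    if (is.null(x$dataset)) "DE table" else x$dataset, x$n_module_de,
    x$n_background_de, x$median_absfc_module, x$median_absfc_background,
    x$direction, x$p_value))
  invisible(x)
}

#' Hypergeometric enrichment of a gene set among DE genes
#'
#' One-sided hypergeometric tail probability `P(X >= overlap)` of
#' drawing at least the observed overlap when `|set|` genes are drawn
#' from a universe containing `|de|` DE genes, plus the fold enrichment
#' `(overlap/set) / (de/universe)`.
#'
#' @param set character vector (e.g. module genes).
#' @param deGenes character vector of DE genes.
#' @param universe size of the gene universe (must be at least
#'   `|set U de|`).
#' @return list with `overlap`, `set_size`, `de_size`, `universe`,
#'   `fold`, `p_value`.
#' @export
enrichmentTest <- function(set, deGenes, universe) {
  set <- unique(.canonSymbols(set))
  deGenes <- unique(.canonSymbols(deGenes))
  if (universe < length(union(set, deGenes)))
    stop("universe smaller than the union of the two sets")
  ov <- length(intersect(set, deGenes))
  k <- length(set); m <- length(deGenes)
  p <- stats::phyper(ov - 1L, m, universe - m, k, lower.tail = FALSE)
  fold <- if (k > 0 && m > 0) (ov / k) / (m / universe) else NA_real_
  list(overlap = ov, set_size = k, de_size = m, universe = universe,
       fold = fold, p_value = p)
}

#' Overlap of a module with an annotation signature
#'
#' Same hypergeometric test as [enrichmentTest()], reported with the
#' percentages used for annotation overlaps: the module overlap as a
#' percentage of the module size (nearest integer) and the background
#' rate `|signature| / universe`.
#'
#' @param module character vector of module genes.
#' @param signature character vector of signature genes (e.g. an
#'   inflammasome gene list).
#' @param universe size of the gene universe.
#' @return list with the [enrichmentTest()] fields plus
#'   `module_percent` and `background_percent`.
#' @export
overlapTest <- function(module, signature, universe) {
  et <- enrichmentTest(module, signature, universe)
  et$module_percent <- round(100 * et$overlap / et$set_size)
  et$background_percent <- round(100 * et$de_size / et$universe)
  et
}

#' Draw a connected random gene subset
#'
#' Iteratively grows a connected set inside `pool`: the first gene is
#' picked at random, each subsequent gene at random among pool members
#' adjacent to the current set. On a dead end the growth restarts from a
#' fresh first gene, up to `maxAttempts` times.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param pool character vector of eligible genes (mapped to the
#'   network).
#' @param size target subset size (>= 1).
#' @param seed optional integer RNG seed.
#' @param maxAttempts restart budget (default 100).
#' @return character vector of `size` genes, connected in the induced
#'   subgraph.
#' @export
connectedRandomSubset <- function(x, pool, size, seed = NULL,
                                  maxAttempts = 100L) {
  stopifnot(is(x, "WeightedInteractome"), size >= 1L)
  pool <- intersect(unique(.canonSymbols(pool)), nodes(x))
  if (length(pool) < size)
    stop("pool smaller than the requested subset size")
  g <- x@graph
  adj <- igraph::adjacent_vertices(g, pool)
  adj <- lapply(adj, function(v) igraph::V(g)$name[as.integer(v)])
  names(adj) <- pool
  .withSeed(seed, {
    for (att in seq_len(maxAttempts)) {
      cur <- sample(pool, 1L)
      frontier <- intersect(adj[[cur]], pool)
      while (length(cur) < size) {
        elig <- setdiff(frontier, cur)
        if (!length(elig)) break
        nxt <- if (length(elig) == 1L) elig else sample(elig, 1L)
        cur <- c(cur, nxt)
        frontier <- union(frontier, intersect(adj[[nxt]], pool))
      }
      if (length(cur) == size) return(cur)
    }
    stop("could not draw a connected subset of size ", size, " from a ",
         "pool of ", length(pool), " genes in ", maxAttempts,
         " attempts; the pool may be too disconnected")
  })
}

#' Connectivity-corrected fold-change comparison
#'
#' Draws `nDraws` connected subsets of `size` genes from the
#' differentially expressed module genes and from all differentially
#' expressed genes (both filtered at raw `p < pThresh`), computes each
#' subset's mean absolute log fold change, and compares the two
#' distributions with a two-sided rank-sum test. This corrects for
#' connectivity as a selection bias: randomly chosen DE genes tend not
#' to be connected to other DE genes.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param module character vector of module genes.
#' @param table DE table (see [readDETable()]).
#' @param size subset size (default 10).
#' @param nDraws draws per side (default 1000).
#' @param seed optional integer RNG seed.
#' @param pThresh DE filter on the raw p-value (default 0.05).
#' @return list with `module_means`, `de_means`, `p_value` (`NA` when
#'   `nDraws == 1`), and summary quantiles of both distributions.
#' @export
moduleVsConnectedRandom <- function(x, module, table, size = 10L,
                                    nDraws = 1000L, seed = NULL,
                                    pThresh = 0.05) {
  module <- unique(.canonSymbols(module))
  fc <- stats::setNames(abs(table$logFC), table$gene)
  de <- table$gene[table$P.Value < pThresh]
  modPool <- intersect(intersect(module, de), nodes(x))
  dePool <- intersect(de, nodes(x))
  .withSeed(seed, {
    mMeans <- vapply(seq_len(nDraws), function(i)
      mean(fc[connectedRandomSubset(x, modPool, size)]), numeric(1))
    dMeans <- vapply(seq_len(nDraws), function(i)
      mean(fc[connectedRandomSubset(x, dePool, size)]), numeric(1))
    p <- if (nDraws > 1L)
      stats::wilcox.test(mMeans, dMeans, exact = FALSE)$p.value
    else NA_real_
    list(module_means = mMeans, de_means = dMeans, p_value = p,
         module_quantiles = stats::quantile(mMeans, c(.25, .5, .75)),
         de_quantiles = stats::quantile(dMeans, c(.25, .5, .75)))
  })
}
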