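#' Synthetic study configuration
#'
#' Parameters of the synthetic-data generator, which emulates every
#' input class of the pipeline: a scale-free confidence-weighted
#' interactome, a planted dense module with seeds inside it, gene-level
#' association p-values enriched in the module, a pull-down candidate
#' set partially proximal to the module, and differential-expression
#' tables with inflated fold changes for module genes.
#'
#' @param nNodes number of genes (>= 20; default 400).
#' @param attachmentEdges edges added per new node in the
#'   preferential-attachment backbone (default 3).
#' @param weightShape `c(alpha, beta)` of the Beta law for edge
#'   confidences (default `c(2, 2)`, spreading weights over (0, 1)).
#' @param moduleSize planted module size (default 30).
#' @param moduleDensity target edge density of the planted module
#'   (default 0.35).
#' @param nSeeds number of seed genes inside the module (default 5).
#' @param pvalEnrichment Beta(`a`, 1) shape for module gene p-values;
#'   `a < 1` concentrates them near 0, `a = 1` is the uniform null
#'   (default 0.2).
#' @param nPartners number of pull-down candidate genes (default 96).
#' @param fracProximal fraction of partners wired close to the module
#'   (default `9 / 96`).
#' @param fcEffect absolute mean log fold change of module genes in the
#'   synthetic DE tables (default 2; background is standard normal).
#' @param rngSeed integer seed driving every generator (default 1).
#' @return list of class `simConfig`.
#' @export
simConfig <- function(nNodes = 400L, attachmentEdges = 3L,
                      weightShape = c(2, 2), moduleSize = 30L,
                      nSeeds = 5L, moduleDensity = 0.35,
                      pvalEnrichment = 0.2, nPartners = 96L,
                      fracProximal = 9 / 96, fcEffect = 2,
                      rngSeed = 1L) {
  cfg <- list(nNodes = as.integer(nNodes),
              attachmentEdges = as.integer(attachmentEdges),
              weightShape = as.numeric(weightShape),
              moduleSize = as.integer(moduleSize),
              nSeeds = as.integer(nSeeds),
              moduleDensity = as.numeric(moduleDensity),
              pvalEnrichment = as.numeric(pvalEnrichment),
              nPartners = as.integer(nPartners),
              fracProximal = as.numeric(fracProximal),
              fcEffect = as.numeric(fcEffect),
              rngSeed = as.integer(rngSeed))
  stopifnot(cfg$nNodes >= 20L, cfg$moduleSize < cfg$nNodes,
            cfg$nSeeds <= cfg$moduleSize,
            cfg$fracProximal >= 0, cfg$fracProximal <= 1,
            cfg$moduleDensity > 0, cfg$moduleDensity <= 1,
            length(cfg$weightShape) == 2L)
  class(cfg) <- "simConfig"
  cfg
}

# stage-specific sub-seeds so each generator is independently
# reproducible; offsets keep every derived seed well below 2^31
.stageSeed <- function(cfg, stage) cfg$rngSeed * 101L + stage

#' Generate a scale-free confidence-weighted interactome
#'
#' Preferential-attachment backbone (`attachmentEdges` per new node)
#' with i.i.d. Beta-distributed confidences truncated away from 0.
#' Deterministic given `cfg$rngSeed`.
#'
#' @param cfg a [simConfig()] list.
#' @return a [WeightedInteractome-class] object with genes named
#'   `G0001`, `G0002`, ...
#' @export
generateInteractome <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  .withSeed(.stageSeed(cfg, 1L), {
    g <- igraph::sample_pa(cfg$nNodes, m = cfg$attachmentEdges,
                           directed = FALSE)
    w <- stats::rbeta(igraph::gsize(g), cfg$weightShape[1L],
                      cfg$weightShape[2L])
    w <- pmax(w, 0.01)
    el <- igraph::as_edgelist(g)
    nm <- sprintf("G%04d", seq_len(cfg$nNodes))
    WeightedInteractome(data.frame(from = nm[el[, 1L]], to = nm[el[, 2L]],
                                   weight = w, stringsAsFactors = FALSE))
  })
}

#' Plant a dense module with seed genes
#'
#' Chooses `moduleSize` genes and adds high-confidence edges (drawn
#' uniformly from \[0.8, 1\]) among them until the induced density
#' reaches `moduleDensity`; `nSeeds` members are designated seed genes.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param cfg a [simConfig()] list.
#' @return list with `interactome` (the augmented network), `module`
#'   (character vector) and `seeds` (subset of `module`).
#' @export
plantModule <- function(x, cfg) {
  stopifnot(is(x, "WeightedInteractome"), inherits(cfg, "simConfig"))
  .withSeed(.stageSeed(cfg, 2L), {
    mod <- sort(sample(nodes(x), cfg$moduleSize))
    et <- edgeTable(x)
    pairs <- t(utils::combn(mod, 2L))
    key <- paste(pairs[, 1L], pairs[, 2L], sep = "\x01")
    have <- key %in% paste(et$from, et$to, sep = "\x01")
    needed <- ceiling(cfg$moduleDensity * nrow(pairs)) - sum(have)
    if (needed > 0L) {
      pick <- sample(which(!have), needed)
      add <- data.frame(from = pairs[pick, 1L], to = pairs[pick, 2L],
                        weight = stats::runif(needed, 0.8, 1),
                        stringsAsFactors = FALSE)
      et <- rbind(et, add)
    }
    seeds <- sort(sample(mod, cfg$nSeeds))
    list(interactome = WeightedInteractome(et), module = mod,
         seeds = seeds)
  })
}

#' Generate gene-level association p-values
#'
#' Module genes draw `p ~ Beta(pvalEnrichment, 1)` (stochastically small
#' when the shape is below 1); all other genes draw `p ~ Uniform(0, 1)`.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param module character vector of planted module genes.
#' @param cfg a [simConfig()] list.
#' @return named numeric vector of p-values in (0, 1\] over all genes.
#' @export
generateGenePvalues <- function(x, module, cfg) {
  stopifnot(is(x, "WeightedInteractome"), inherits(cfg, "simConfig"))
  .withSeed(.stageSeed(cfg, 3L), {
    nm <- nodes(x)
    p <- stats::setNames(stats::runif(length(nm)), nm)
    p[module] <- stats::rbeta(length(module), cfg$pvalEnrichment, 1)
    pmax(pmin(p, 1), 1e-300)
  })
}

#' Generate a pull-down candidate gene set
#'
#' Picks `nPartners` genes outside the module;
#' `round(fracProximal * nPartners)` of them are wired adjacent to at
#' least 3 module genes with confidences in \[0.8, 1\] (the planted
#' proximal partners), the rest are sampled uniformly from genes at hop
#' distance >= 2 from the module.
#'
#' @param x a [WeightedInteractome-class] object (module already
#'   planted).
#' @param module character vector of module genes.
#' @param cfg a [simConfig()] list.
#' @return list with `interactome` (augmented network), `partners`
#'   (all candidates) and `proximal` (the planted-proximal subset).
#' @export
generatePulldown <- function(x, module, cfg) {
  stopifnot(is(x, "WeightedInteractome"), inherits(cfg, "simConfig"))
  .withSeed(.stageSeed(cfg, 4L), {
    nProx <- round(cfg$fracProximal * cfg$nPartners)
    nonMod <- setdiff(nodes(x), module)
    hop <- suppressWarnings(
      igraph::distances(x@graph, v = module, to = nonMod, weights = NA))
    minHop <- apply(hop, 2L, min)
    distant <- nonMod[minHop >= 2]
    prox <- sort(sample(nonMod, nProx))
    pool <- setdiff(distant, prox)
    nRest <- cfg$nPartners - nProx
    if (length(pool) < nRest) {
      # small networks may not have enough genes 2+ hops from the
      # module; top up from the remaining non-module genes
      message("only ", length(pool), " distant genes; topping up")
      pool <- union(pool, setdiff(nonMod, prox))
    }
    rest <- sort(sample(pool, nRest))
    et <- edgeTable(x)
    if (nProx > 0L) {
      add <- do.call(rbind, lapply(prox, function(g) {
        tgt <- sample(module, 3L)
        data.frame(from = g, to = tgt,
                   weight = stats::runif(3L, 0.8, 1),
                   stringsAsFactors = FALSE)
      }))
      et <- rbind(et, add)
    }
    list(interactome = WeightedInteractome(et),
         partners = sort(c(prox, rest)), proximal = prox)
  })
}

#' Generate a synthetic differential-expression table
#'
#' Background genes draw `logFC ~ N(0, 1)`; module genes draw
#' `logFC ~ N(+/- fcEffect, 1)` (random sign per gene). The raw p-value
#' is the two-sided tail of the drawn value under the standard normal,
#' and the adjusted p-value is Benjamini-Hochberg over the table.
#'
#' @param x a [WeightedInteractome-class] object.
#' @param module character vector of module genes.
#' @param cfg a [simConfig()] list.
#' @param dataset label for the table (default "synthetic").
#' @param stageOffset integer added to the derived stage seed so that
#'   several independent tables can be produced from one config.
#' @return DE `data.frame` as returned by [readDETable()].
#' @export
generateDETable <- function(x, module, cfg, dataset = "synthetic",
                            stageOffset = 0L) {
  stopifnot(is(x, "WeightedInteractome"), inherits(cfg, "simConfig"))
  .withSeed(.stageSeed(cfg, 5L) + stageOffset, {
    nm <- nodes(x)
    lfc <- stats::rnorm(length(nm))
    inMod <- nm %in% module
    sgn <- sample(c(-1, 1), sum(inMod), replace = TRUE)
    lfc[inMod] <- stats::rnorm(sum(inMod), mean = sgn * cfg$fcEffect)
    p <- 2 * stats::pnorm(-abs(lfc))
    out <- data.frame(gene = nm, logFC = lfc, P.Value = p,
                      adj.P.Val = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    attr(out, "dataset") <- dataset
    out
  })
}

#' Write a complete synthetic fixture set
#'
#' Runs every generator in sequence and writes the pipeline's input
#' files to `outdir`: `edges.tsv`, `seeds.txt`, `gwas.tsv`,
#' `partners.txt`, `de_1.tsv` .. `de_<nDatasets>.tsv`, and `truth.json`
#' (planted module, seeds and proximal partners, for tests).
#'
#' @param cfg a [simConfig()] list.
#' @param outdir output directory (created if needed).
#' @param nDatasets number of DE tables to write (default 2).
#' @return invisibly, a list with the generated objects (`interactome`,
#'   `module`, `seeds`, `partners`, `proximal`, `pvals`, `deTables`).
#' @export
writeFixtures <- function(cfg, outdir, nDatasets = 2L) {
  stopifnot(inherits(cfg, "simConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g0 <- generateInteractome(cfg)
  pm <- plantModule(g0, cfg)
  pd <- generatePulldown(pm$interactome, pm$module, cfg)
  g <- pd$interactome
  pv <- generateGenePvalues(g, pm$module, cfg)
  deTables <- lapply(seq_len(nDatasets), function(i)
    generateDETable(g, pm$module, cfg, dataset = paste0("synthetic_", i),
                    stageOffset = i))
  writeEdgeList(g, file.path(outdir, "edges.tsv"))
  writeGeneSet(pm$seeds, file.path(outdir, "seeds.txt"))
  utils::write.table(
    data.frame(gene = names(pv), p = as.numeric(pv)),
    file.path(outdir, "gwas.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeGeneSet(pd$partners, file.path(outdir, "partners.txt"))
  for (i in seq_len(nDatasets))
    utils::write.table(deTables[[i]],
                       file.path(outdir, sprintf("de_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(module = pm$module, seeds = pm$seeds, partners = pd$partners,
         proximal = pd$proximal),
    file.path(outdir, "truth.json"))
  invisible(list(interactome = g, module = pm$module, seeds = pm$seeds,
                 partners = pd$partners, proximal = pd$proximal,
                 pvals = pv, deTables = deTables))
}

#' Read a gene-level p-value table
#'
#' Two-column TSV `gene p` (with header) as produced by gene-based
#' association tools.
#'
#' @param path path to the TSV.
#' @return named numeric vector of p-values.
#' @export
readGenePvalues <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected columns: gene, p")
  stats::setNames(as.numeric(df[[2L]]), toupper(trimws(df[[1L]])))
}
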