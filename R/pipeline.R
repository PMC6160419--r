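#' Run the full disease-module pipeline
#'
#' Orchestrates the complete workflow on file inputs: read the weighted
#' interactome, rank genes around the seeds with the degree-adjusted
#' random walk, choose the neighborhood boundary from gene-level
#' association p-values (or a forced `k`), extract the seed-containing
#' neighborhood and test its largest connected component, score the
#' candidate genes with the confidence-weighted closeness Z-score,
#' assemble the disease module with the greedy Steiner strategy, and
#' validate it against each differential-expression table. Every
#' stochastic stage derives its seed from the single `rngSeed` (seed
#' plus stage index), so reruns are reproducible stage by stage.
#'
#' @param config either a path to a YAML file or a named list with
#'   entries: `network`, `seeds`, `gwas` (optional when `force_k` is
#'   given), `candidates`, `de` (character vector of DE table paths,
#'   may be empty), `signature` + `universe` (optional overlap test),
#'   `restart` (default 0.75), `window` (25), `alpha` (0.05),
#'   `force_k` (optional), `p_grid` (exponents, default
#'   `c(0, 1, 2, 10)`), `report_p` (exponent, default 1), `n_rand`
#'   (default 10000), `z_threshold` (-1.6), `lcc_n_rand` (default
#'   `n_rand`), `steiner_hops` (FALSE), `drop_seeds` (FALSE: exclude
#'   seeds from the module before expression validation), `rng_seed`
#'   (1), `outdir` (optional: write artifacts).
#' @return a run report (list of class `netmod_report`) with the stage
#'   outputs and the headline counts; written as `report.json` when
#'   `outdir` is set, together with `ranked.tsv`, `neighborhood.txt`,
#'   `cab.tsv`, `module.txt`, `module_edges.tsv` and `provenance.tsv`.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  def <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  seed <- as.integer(def("rng_seed", 1L))
  for (f in c("network", "seeds", "candidates"))
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'")
  net <- readEdgeList(cfg$network, header = isTRUE(cfg$header))
  seeds <- readGeneSet(cfg$seeds)
  candidates <- readGeneSet(cfg$candidates)

  restart <- def("restart", 0.75)
  ranked <- degreeAdjustedRanks(net, seeds, restart = restart,
                                weighted = !isTRUE(cfg$unweighted_walk))
  forceK <- cfg$force_k
  cutoffK <- if (!is.null(forceK)) as.integer(forceK) else {
    if (is.null(cfg$gwas)) stop("config needs 'gwas' or 'force_k'")
    plateauCutoff(ranked, readGenePvalues(cfg$gwas),
                  window = as.integer(def("window", 25L)),
                  alpha = def("alpha", 0.05))
  }
  nbhd <- buildNeighborhood(net, ranked, seeds, cutoffK)

  lccN <- as.integer(def("lcc_n_rand", def("n_rand", 10000L)))
  lcc <- if (length(nbhd@components))
    lccSignificance(net, nbhd@components[[1L]], nRand = lccN,
                    seed = seed + 1L)
  else NULL

  params <- cabParams(pGrid = exp(def("p_grid", c(0, 1, 2, 10))),
                      reportP = exp(def("report_p", 1)),
                      nRand = as.integer(def("n_rand", 10000L)),
                      zThreshold = def("z_threshold", -1.6),
                      rngSeed = seed + 2L)
  cab <- scoreCandidates(net, candidates, members(nbhd), params)

  module <- assembleModule(nbhd, cab$significant, net,
                           p = params@reportP,
                           hops = isTRUE(cfg$steiner_hops))

  testSet <- members(module)
  if (isTRUE(cfg$drop_seeds)) testSet <- setdiff(testSet, nbhd@seeds)
  validation <- list()
  dePaths <- def("de", character(0))
  for (i in seq_along(dePaths)) {
    tab <- readDETable(dePaths[[i]])
    fc <- tryCatch(foldchangeComparison(testSet, tab),
                   error = function(e) list(error = conditionMessage(e)))
    enr <- enrichmentTest(testSet, tab$gene[tab$P.Value < 0.05],
                          universe = nrow(tab))
    validation[[attr(tab, "dataset")]] <-
      list(foldchange = fc, enrichment = enr)
  }
  overlap <- NULL
  if (!is.null(cfg$signature)) {
    uni <- as.integer(def("universe", numNodes(net)))
    overlap <- overlapTest(testSet, readGeneSet(cfg$signature), uni)
  }

  counts <- list(
    n_nodes = numNodes(net), n_edges = numEdges(net),
    n_seeds_mapped = length(nbhd@seeds), cutoff_k = cutoffK,
    neighborhood_size = length(members(nbhd)),
    n_components = length(nbhd@components),
    lcc_size = if (is.null(lcc)) NA_integer_ else lcc$lcc_size,
    lcc_z = if (is.null(lcc)) NA_real_ else lcc$z,
    n_candidates = length(candidates),
    n_candidates_unmapped = length(cab$unmapped),
    n_significant = length(cab$significant),
    n_linkers = length(linkers(module)),
    module_size = length(members(module)),
    n_overlap_terminals = length(intersect(members(nbhd),
                                           cab$significant)))
  report <- list(config = cfg, rng_seed = seed, counts = counts,
                 force_k = forceK,
                 ranked = ranked, neighborhood = nbhd, lcc = lcc,
                 cab = cab, module = module, validation = validation,
                 overlap = overlap)
  class(report) <- "netmod_report"

  if (!is.null(cfg$outdir)) .writeArtifacts(report, cfg$outdir)
  report
}

# Stage artifacts: all tabular outputs as TSV, report as JSON.
.writeArtifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(ranking(report$ranked), "ranked.tsv")
  writeGeneSet(members(report$neighborhood),
               file.path(outdir, "neighborhood.txt"))
  w(report$cab$results, "cab.tsv")
  writeGeneSet(members(report$module), file.path(outdir, "module.txt"))
  w(report$module@moduleEdges, "module_edges.tsv")
  w(report$module@provenance, "provenance.tsv")
  json <- list(rng_seed = report$rng_seed, counts = report$counts,
               lcc = report$lcc[c("lcc_size", "null_mean", "null_sd",
                                  "z", "empirical_p")],
               significant = report$cab$significant,
               linkers = linkers(report$module),
               validation = lapply(report$validation, function(v) list(
                 foldchange_p = v$foldchange$p_value,
                 n_module_de = v$foldchange$n_module_de,
                 enrichment_p = v$enrichment$p_value,
                 enrichment_fold = v$enrichment$fold)),
               overlap = report$overlap)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.netmod_report <- function(x, ...) {
  cc <- x$counts
  cat("netmod pipeline report (rng_seed =", x$rng_seed, ")\n")
  cat(sprintf("  interactome: %d genes / %d edges\n", cc$n_nodes,
              cc$n_edges))
  cat(sprintf("  neighborhood: %d genes in %d component(s) (k = %d, %d seeds)\n",
              cc$neighborhood_size, cc$n_components, cc$cutoff_k,
              cc$n_seeds_mapped))
  if (!is.na(cc$lcc_z))
    cat(sprintf("  LCC: %d genes, z = %.2f\n", cc$lcc_size, cc$lcc_z))
  cat(sprintf("  candidates: %d significant of %d (%d unmapped)\n",
              cc$n_significant, cc$n_candidates, cc$n_candidates_unmapped))
  cat(sprintf("  module: %d genes (+%d linkers)\n", cc$module_size,
              cc$n_linkers))
  for (nm in names(x$validation)) {
    v <- x$validation[[nm]]
    if (!is.null(v$foldchange$p_value))
      cat(sprintf("  %s: fold-change p = %.4g, enrichment p = %.4g\n",
                  nm, v$foldchange$p_value, v$enrichment$p_value))
  }
  invisible(x)
}
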