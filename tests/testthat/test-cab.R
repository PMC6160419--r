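test_that("edge lengths follow ln(p/w)", {
  expect_equal(edgeLength(1, 1), 0)
  expect_equal(edgeLength(0.5, exp(1)), 1 + log(2))
  expect_equal(edgeLength(1, exp(10)), 10)
  expect_error(edgeLength(0, 1), "zero-confidence")
})

test_that("minimum weighted distances trade hops for confidence as p varies", {
  g <- wi(c("A", "A", "C"), c("B", "C", "B"), c(0.1, 0.9, 0.9))
  # p = 1: confidence dominates, two strong hops beat one weak edge
  r <- minWeightedDistance(g, "A", "B", p = 1)
  expect_equal(r$length, 2 * log(1 / 0.9), tolerance = 1e-9)
  expect_equal(r$path, c("A", "C", "B"))
  expect_equal(r$hops, 2L)
  # p = e^10: hop count dominates, direct edge wins
  r <- minWeightedDistance(g, "A", "B", p = exp(10))
  expect_equal(r$length, 10 + log(10), tolerance = 1e-9)
  expect_equal(r$hops, 1L)
  # identity and errors
  r <- minWeightedDistance(g, "A", "A")
  expect_equal(r$length, 0)
  expect_equal(r$hops, 0L)
  expect_error(minWeightedDistance(g, "A", "ZZ"), "unknown gene")
  # unreachable pair
  g2 <- wi(c("A", "P"), c("B", "Q"))
  r <- minWeightedDistance(g2, "A", "P")
  expect_equal(r$length, Inf)
  expect_length(r$path, 0)
})

test_that("weighted shortest paths agree with exhaustive enumeration", {
  set.seed(31)
  for (i in 1:20) {
    g <- randomConnectedGraph(sample(4:7, 1))
    nm <- nodes(g)
    pair <- sample(nm, 2)
    for (p in exp(c(0, 1, 2, 10))) {
      got <- minWeightedDistance(g, pair[1], pair[2], p = p)$length
      expect_equal(got, enumMinDist(g, pair[1], pair[2], p),
                   tolerance = 1e-9)
    }
  }
})

test_that("p = 1 reduces to -ln of the path confidence product; large p counts hops", {
  set.seed(33)
  for (i in 1:10) {
    g <- randomConnectedGraph(6)
    nm <- nodes(g)
    r <- minWeightedDistance(g, nm[1], nm[4], p = 1)
    et <- edgeTable(g)
    wts <- vapply(seq_len(r$hops), function(j) {
      a <- min(r$path[j], r$path[j + 1]); b <- max(r$path[j], r$path[j + 1])
      et$weight[et$from == a & et$to == b]
    }, numeric(1))
    expect_equal(r$length, -log(prod(wts)), tolerance = 1e-9)
  }
  # all confidences 1: length is exactly 10 x unweighted hop distance
  path5 <- wi(sprintf("N%d", 1:4), sprintf("N%d", 2:5), 1)
  for (tgt in sprintf("N%d", 2:5)) {
    r <- minWeightedDistance(path5, "N1", tgt, p = exp(10))
    hops <- as.numeric(igraph::distances(asIgraph(path5), "N1", tgt,
                                         weights = NA))
    expect_identical(r$length, 10 * hops)
  }
})

test_that("distances never increase when an edge is added or a confidence is raised", {
  set.seed(35)
  for (i in 1:6) {
    g <- randomConnectedGraph(6)
    et <- edgeTable(g)
    nm <- nodes(g)
    p <- exp(1)
    dist0 <- igraph::distances(asIgraph(g), weights = log(p / et$weight))
    # raise one confidence
    j <- sample(nrow(et), 1)
    et2 <- et; et2$weight[j] <- min(1, et2$weight[j] + 0.3)
    g2 <- WeightedInteractome(et2)
    d2 <- igraph::distances(asIgraph(g2),
                            weights = log(p / edgeTable(g2)$weight))
    expect_true(all(d2[nm, nm] <= dist0[nm, nm] + 1e-12))
    # add one new edge
    pairs <- t(combn(nm, 2))
    have <- paste(et$from, et$to)
    newp <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% have), , drop = FALSE]
    if (nrow(newp)) {
      et3 <- rbind(et, data.frame(from = newp[1, 1], to = newp[1, 2],
                                  weight = 0.8))
      g3 <- WeightedInteractome(et3)
      d3 <- igraph::distances(asIgraph(g3),
                              weights = log(p / edgeTable(g3)$weight))
      expect_true(all(d3[nm, nm] <= dist0[nm, nm] + 1e-12))
    }
  }
})

test_that("set distance averages reachable targets and excludes the source", {
  star <- wi(rep("C", 3), c("L1", "L2", "L3"), 1)
  expect_equal(setDistance(star, "C", c("L1", "L2", "L3"))$mean_length, 1)
  path3 <- wi(c("A", "B"), c("B", "C"), 1)
  expect_equal(setDistance(path3, "A", c("B", "C"))$mean_length, 1.5)
  # source inside the target set is excluded
  r <- setDistance(wi("A", "B", 1), "A", c("A", "B"))
  expect_equal(r$mean_length, 1)
  expect_equal(r$n_reachable, 1L)
  # sum aggregation restores the literal set distance
  expect_equal(setDistance(path3, "A", c("B", "C"),
                           aggregate = "sum")$mean_length, 3)
  # unreachable targets are counted, fully unreachable is an error
  g2 <- wi(c("A", "P"), c("B", "Q"), 1)
  expect_error(setDistance(g2, "A", c("P", "Q")), "reachable")
  r <- setDistance(g2, "A", c("B", "P"))
  expect_equal(r$n_unreachable, 1L)
})

test_that("planted-adjacent candidates get significant closeness calls", {
  study <- makeStudy(rngSeed = 2L, nNodes = 300L, moduleDensity = 1)
  params <- cabParams(nRand = 1000L, rngSeed = 5L)
  # a candidate wired to every module gene is called significant
  et <- edgeTable(study$interactome)
  et <- rbind(et, data.frame(from = "NEWC", to = study$module, weight = 1))
  g <- WeightedInteractome(et)
  r <- closenessZscore(g, "NEWC", study$module, params)
  at <- r[abs(r$log_p - 1) < 1e-9, ]
  expect_lt(at$z, -1.6)
  expect_true(at$significant)
  # candidate inside the module is refused
  expect_error(closenessZscore(g, study$module[1], study$module, params),
               "module member")
})

test_that("null candidates are calibrated and degenerate nulls are caught", {
  study <- makeStudy(rngSeed = 3L, nNodes = 300L)
  g <- study$interactome
  pool <- setdiff(nodes(g), study$module)
  set.seed(77)
  cands <- sample(pool, 200)
  sc <- scoreCandidates(g, cands, study$module,
                        cabParams(nRand = 1000L, rngSeed = 13L))
  at <- sc$results[abs(sc$results$log_p - 1) < 1e-9, ]
  expect_gt(mean(at$z), -0.3)
  expect_lt(mean(at$z), 0.3)
  # degenerate null: every non-module node of a star is exactly one
  # hop from the module, so the null has zero variance
  sym <- wi(rep("C", 4), c("A", "B", "X", "Y"), 1)
  expect_error(
    closenessZscore(sym, "X", "C",
                    cabParams(pGrid = exp(1), reportP = exp(1),
                              nRand = 100L, rngSeed = 1L)),
    "degenerate")
})

test_that("candidate scoring reports unmapped genes and handles empty input", {
  g <- wi(c("A", "B", "C"), c("B", "C", "D"), 0.9)
  params <- cabParams(pGrid = exp(1), reportP = exp(1), nRand = 100L,
                      rngSeed = 1L)
  sc <- scoreCandidates(g, c("D", "GHOST"), c("A", "B"), params)
  expect_equal(sc$unmapped, "GHOST")
  expect_setequal(sc$results$candidate, "D")
  sc <- scoreCandidates(g, character(0), c("A", "B"), params)
  expect_equal(nrow(sc$results), 0L)
  expect_length(sc$significant, 0)
})

test_that("closeness z-scores are invariant under node relabelling", {
  # exhaustive null (nRand >= pool) makes the z computation deterministic
  set.seed(41)
  g <- randomConnectedGraph(12, pe = 0.3)
  module <- nodes(g)[1:4]
  cand <- nodes(g)[8]
  params <- cabParams(nRand = 1000L, rngSeed = 1L)
  z1 <- closenessZscore(g, cand, module, params)$z
  # permute labels
  perm <- setNames(sprintf("Q%02d", sample(12)), nodes(g))
  et <- edgeTable(g)
  g2 <- WeightedInteractome(data.frame(from = perm[et$from],
                                       to = perm[et$to],
                                       w = et$weight))
  z2 <- closenessZscore(g2, perm[cand], perm[module], params)$z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("set cohesion detects planted cliques and handles single pairs", {
  # two adjacent genes at confidence 1, p = e: observed distance exactly 1
  g <- wi(c("A", "B", "C"), c("B", "C", "D"), 1)
  params <- cabParams(nRand = 100L, rngSeed = 2L)
  r <- cohesionZscore(g, c("A", "B"), params)
  expect_equal(r$observed_mean_pairwise, 1)
  expect_error(cohesionZscore(g, "A", params), "at least 2")

  # a planted 5-clique in a sparse 200-node graph is strongly cohesive
  study <- makeStudy(rngSeed = 6L, nNodes = 200L, moduleSize = 5L,
                     moduleDensity = 1, nSeeds = 2L, nPartners = 10L,
                     fracProximal = 0)
  r <- cohesionZscore(study$interactome, study$module,
                      cabParams(nRand = 1000L, rngSeed = 3L))
  expect_lt(r$z, -2)
  expect_lt(r$empirical_p, 0.05)
})

test_that("cohesion is calibrated on uniformly random gene sets", {
  study <- makeStudy(rngSeed = 14L, nNodes = 150L, nPartners = 10L,
                     fracProximal = 0)
  g <- study$interactome
  set.seed(91)
  zs <- vapply(1:200, function(i)
    cohesionZscore(g, sample(nodes(g), 8),
                   cabParams(nRand = 150L, rngSeed = 500 + i))$z,
    numeric(1))
  expect_gt(mean(zs), -0.3)
  expect_lt(mean(zs), 0.3)
})
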