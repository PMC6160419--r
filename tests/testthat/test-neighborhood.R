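test_that("restart walk solves the two-state fixed point", {
  g <- wi("A", "B")
  s <- randomWalkRestart(g, "A", restart = 0.5)
  expect_equal(unname(s[c("A", "B")]), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(sum(s), 1, tolerance = 1e-9)
})

test_that("restart walk matches a dense linear solve on random graphs", {
  set.seed(3)
  for (i in 1:8) {
    n <- sample(5:20, 1)
    g <- randomConnectedGraph(n, pe = 0.3)
    seeds <- sample(nodes(g), sample(1:3, 1))
    for (r in c(0.3, 0.75)) {
      got <- randomWalkRestart(g, seeds, restart = r)
      want <- denseRWR(g, seeds, r)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("restart limits: near-1 restart concentrates on seeds, symmetry gives uniformity", {
  g <- wi(c("A", "B", "C", "D"), c("B", "C", "D", "A"))  # 4-cycle
  s <- randomWalkRestart(g, c("A", "C"), restart = 0.999)
  expect_true(all(s[c("A", "C")] > 0.49))
  expect_true(all(s[c("B", "D")] < 0.01))
  # regular graph with all nodes seeded: exact uniformity
  s <- randomWalkRestart(g, nodes(g), restart = 0.6)
  expect_equal(unname(s), rep(0.25, 4), tolerance = 1e-9)
  expect_error(randomWalkRestart(g, "ZZZ"), "no seed maps")
})

test_that("total seed mass increases with the restart probability", {
  set.seed(5)
  g <- randomConnectedGraph(12, pe = 0.3)
  seeds <- nodes(g)[1:2]
  mass <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r)
    sum(randomWalkRestart(g, seeds, restart = r)[seeds]), numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("degree adjustment demotes the hub relative to an equal-share leaf", {
  # seed S has two neighbors: H (a hub serving 5 further leaves) and L
  # (a leaf). Both receive the same one-step share from S, and H even
  # collects backflow from its leaves, so its raw score is the largest;
  # after division by the strength-proportional reference the ordering
  # of the two is reversed.
  hub_leaves <- sprintf("X%d", 1:5)
  g <- wi(c("S", "S", rep("H", 5)), c("H", "L", hub_leaves))
  rk <- ranking(degreeAdjustedRanks(g, "S", restart = 0.75))
  expect_gte(rk$raw[match("H", rk$gene)], rk$raw[match("L", rk$gene)])
  expect_lt(rk$adjusted[match("H", rk$gene)],
            rk$adjusted[match("L", rk$gene)])
  # the adjustment shrinks the hub's advantage by the degree ratio
  rawRatio <- rk$raw[match("L", rk$gene)] / rk$raw[match("H", rk$gene)]
  adjRatio <- rk$adjusted[match("L", rk$gene)] /
    rk$adjusted[match("H", rk$gene)]
  expect_gt(adjRatio, rawRatio)
})

test_that("regular graphs rank by raw score; off-component genes rank last with zero scores", {
  ring <- wi(sprintf("N%d", 1:6), sprintf("N%d", c(2:6, 1)))
  rk <- ranking(degreeAdjustedRanks(ring, "N1"))
  expect_equal(order(-rk$raw, rk$gene), seq_len(nrow(rk)))
  # disconnected second component scores 0 and ranks last
  two <- wi(c("A", "B", "P", "Q"), c("B", "C", "Q", "R"))
  rk <- ranking(degreeAdjustedRanks(two, "A"))
  far <- rk[rk$gene %in% c("P", "Q", "R"), ]
  expect_true(all(far$raw == 0 & far$adjusted == 0))
  expect_setequal(far$rank, 3:5)
})

test_that("plateau boundary finds an enriched prefix and returns 0 under the null", {
  mkRanked <- function(n) {
    genes <- sprintf("G%03d", seq_len(n))
    new("RankedGeneList",
        entries = data.frame(gene = genes,
                             raw = seq(1, 0.01, length.out = n),
                             adjusted = seq(1, 0.01, length.out = n),
                             rank = seq_len(n)),
        seeds = character(0), restart = 0.75)
  }
  rl <- mkRanked(400)
  # pure-null p-values: no boundary
  set.seed(2)
  pnull <- setNames(runif(400), ranking(rl)$gene)
  expect_equal(plateauCutoff(rl, pnull), 0L)
  # the override bypasses detection entirely
  expect_equal(plateauCutoff(rl, pnull, forceK = 150L), 150L)
  # enriched prefix of 50 genes: boundary lands in [40, 75] in >= 90%
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    pv <- setNames(c(rbeta(50, 0.2, 1), runif(350)), ranking(rl)$gene)
    k <- plateauCutoff(rl, pv)
    if (k >= 40 && k <= 75) hits <- hits + 1
  }
  expect_gte(hits, 90)
  # preconditions
  expect_error(plateauCutoff(mkRanked(20), pnull), "fewer ranked genes")
  expect_error(plateauCutoff(rl, pnull[1:100]), "cover")
})

test_that("neighborhood keeps seed components and reports seedless genes", {
  # path S-a-b, cutoff 2: single chain component
  g <- wi(c("S", "A"), c("A", "B"))
  rk <- degreeAdjustedRanks(g, "S")
  nb <- buildNeighborhood(g, rk, "S", 2L)
  expect_equal(length(nb@components), 1L)
  expect_setequal(members(nb), c("S", "A", "B"))

  # two seeded triangles plus an isolated top-ranked gene
  g <- wi(c("S1", "A1", "B1", "S2", "A2", "B2", "Z", "W"),
          c("A1", "B1", "S1", "A2", "B2", "S2", "W", "V"))
  entries <- data.frame(
    gene = c("A1", "B1", "A2", "B2", "Z", "V", "W"),
    raw = 7:1, adjusted = 7:1, rank = 1:7)
  rk <- new("RankedGeneList", entries = entries, seeds = c("S1", "S2"),
            restart = 0.75)
  nb <- buildNeighborhood(g, rk, c("S1", "S2"), 5L)
  expect_equal(length(nb@components), 2L)
  expect_equal(length(members(nb)), 6L)
  expect_false("Z" %in% members(nb))
  expect_true("Z" %in% unlist(nb@seedless))
  # components partition the neighborhood and each contains a seed
  expect_equal(sort(unlist(nb@components)), sort(members(nb)))
  expect_true(all(vapply(nb@components,
                         function(cc) any(cc %in% c("S1", "S2")),
                         logical(1))))
})

test_that("LCC significance flags planted cliques and is calibrated on random sets", {
  study <- makeStudy(rngSeed = 8L, nNodes = 200L, moduleSize = 15L,
                     moduleDensity = 1)
  g <- study$interactome
  r <- lccSignificance(g, study$module, nRand = 1000L, seed = 4L)
  expect_gt(r$z, 3)
  expect_lt(r$empirical_p, 0.01)

  # degenerate null: the whole node set always has LCC = N
  whole <- lccSignificance(g, nodes(g), nRand = 200L, seed = 1L)
  expect_equal(whole$z, 0)
  expect_equal(whole$empirical_p, 1)

  # calibration: mean z of uniformly random sets is near 0
  set.seed(21)
  zs <- vapply(1:200, function(i) {
    lccSignificance(g, sample(nodes(g), 15), nRand = 150L,
                    seed = 100 + i)$z
  }, numeric(1))
  expect_gt(mean(zs), -0.3)
  expect_lt(mean(zs), 0.3)
  expect_error(lccSignificance(g, character(0)), "empty")
})

test_that("LCC empirical p is reproducible by seed and stable across draws", {
  study <- makeStudy(rngSeed = 9L, nNodes = 150L, nPartners = 20L,
                     fracProximal = 0.2)
  g <- study$interactome
  genes <- study$module[1:20]
  a <- lccSignificance(g, genes, nRand = 10000L, seed = 1L)
  b <- lccSignificance(g, genes, nRand = 10000L, seed = 1L)
  expect_identical(a$empirical_p, b$empirical_p)
  c <- lccSignificance(g, genes, nRand = 10000L, seed = 2L)
  expect_lt(abs(a$empirical_p - c$empirical_p), 0.02)
})
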