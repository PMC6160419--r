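writeDE <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                     .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("DE tables are parsed, aliased, and deduplicated", {
  f <- writeDE(data.frame(Gene.symbol = c("il32", "MMP12", "IL32"),
                          logFC = c(-3.77, 2.39, 0.5),
                          P.Value = c(1.35e-6, 6e-4, 0.2),
                          adj.P.Val = c(0.0014, 0.0423, 0.6)))
  tab <- readDETable(f, dataset = "toy")
  expect_equal(nrow(tab), 2L)
  # duplicate IL32 keeps the smaller-p row
  expect_equal(tab$logFC[tab$gene == "IL32"], -3.77)
  expect_equal(attr(tab, "dataset"), "toy")

  # missing adjusted-p column is an error naming the column
  f2 <- writeDE(data.frame(gene = "A", logFC = 1, P.Value = 0.1))
  expect_error(readDETable(f2), "adj.P.Val")
})

test_that("fold-change comparison reproduces the exact rank-sum p under separation", {
  tab <- data.frame(
    gene = c(sprintf("M%d", 1:3), sprintf("B%d", 1:3)),
    logFC = c(2, -3, 4, 0.1, -0.2, 0.3),
    P.Value = rep(0.01, 6), adj.P.Val = rep(0.05, 6))
  r <- foldchangeComparison(sprintf("M%d", 1:3), tab)
  # complete separation, n = 3 vs 3: two-sided exact p = 2/20
  expect_equal(r$p_value, 0.1)
  expect_equal(r$direction, "module_higher")
  expect_equal(r$n_module_de, 3L)
  # |logFC| contract: flipping signs changes nothing
  tab2 <- tab; tab2$logFC <- -tab2$logFC
  expect_equal(foldchangeComparison(sprintf("M%d", 1:3), tab2)$p_value,
               r$p_value)
  # module absent from the table
  expect_error(foldchangeComparison("GHOST", tab), "no module gene")
  # too few DE genes after filtering
  tab3 <- tab; tab3$P.Value[4:6] <- 0.9
  expect_error(foldchangeComparison(sprintf("M%d", 1:3), tab3),
               "too few")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # closed-form check by summing the density over the tail
  chooseTail <- function(ov, k, m, N)
    sum(sapply(ov:min(k, m), function(x)
      choose(m, x) * choose(N - m, k - x) / choose(N, k)))
  r <- enrichmentTest(sprintf("A%d", 1:10),
                      c(sprintf("A%d", 1:5), sprintf("B%d", 1:5)), 100)
  expect_equal(r$overlap, 5L)
  expect_equal(r$p_value, chooseTail(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(r$fold, (5 / 10) / (10 / 100))
  # exhaustive agreement on every overlap for a small universe
  for (ov in 0:4) {
    set <- sprintf("S%d", 1:6)
    de <- c(sprintf("S%d", seq_len(ov)), sprintf("D%d", seq_len(4 - ov)))
    r <- enrichmentTest(set, de, 20)
    expect_equal(r$p_value, chooseTail(ov, 6, 4, 20), tolerance = 1e-12)
  }
  # certain event: module inside DE genes spanning the whole universe
  r <- enrichmentTest(sprintf("A%d", 1:5), sprintf("A%d", 1:8), 8)
  expect_equal(r$p_value, 1)
  expect_error(enrichmentTest(sprintf("A%d", 1:5), sprintf("B%d", 1:5), 8),
               "universe")
})

test_that("overlap test reports module and background percentages", {
  # toy: module 10, signature 20, universe 100, overlap 4
  mod <- sprintf("M%d", 1:10)
  sig <- c(mod[1:4], sprintf("S%d", 1:16))
  r <- overlapTest(mod, sig, 100)
  expect_equal(r$module_percent, 40)
  expect_equal(r$background_percent, 20)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # published-scale arithmetic: 37 of 163 genes is 23%
  mod <- sprintf("G%03d", 1:163)
  sig <- c(mod[1:37], sprintf("X%04d", 1:2294))
  r <- overlapTest(mod, sig, 14280)
  expect_equal(r$module_percent, 23)
})

test_that("connected random subsets are connected and respect forced structures", {
  # a 10-path forces the whole path
  path10 <- wi(sprintf("P%02d", 1:9), sprintf("P%02d", 2:10), 1)
  s <- connectedRandomSubset(path10, nodes(path10), 10L, seed = 1L)
  expect_setequal(s, nodes(path10))
  # isolated nodes cannot form a pair
  iso <- wi(c("A", "C"), c("B", "D"), 1)
  expect_error(connectedRandomSubset(iso, c("A", "C"), 2L, seed = 1L,
                                     maxAttempts = 5L), "attempts")
  # triangle plus isolated extras: every size-3 draw is the triangle
  g <- wi(c("T1", "T2", "T3", "X1", "X3"), c("T2", "T3", "T1", "X2", "X4"), 1)
  pool <- c("T1", "T2", "T3", "X1", "X2", "X3", "X4")
  for (i in 1:50)
    expect_setequal(connectedRandomSubset(g, pool, 3L, seed = i),
                    c("T1", "T2", "T3"))
  # general invariant: draws from a synthetic study are always connected
  study <- makeStudy(rngSeed = 4L, nNodes = 150L, nPartners = 10L,
                     fracProximal = 0)
  for (i in 1:25) {
    s <- connectedRandomSubset(study$interactome, nodes(study$interactome),
                               8L, seed = 100 + i)
    sub <- igraph::induced_subgraph(asIgraph(study$interactome), s)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("connectivity-corrected comparison draws valid distributions reproducibly", {
  study <- makeStudy(rngSeed = 12L)
  tab <- generateDETable(study$interactome, study$module, study$cfg)
  r <- moduleVsConnectedRandom(study$interactome, study$module, tab,
                               size = 10L, nDraws = 200L, seed = 19L)
  expect_length(r$module_means, 200L)
  expect_length(r$de_means, 200L)
  # subset means live in the DE-censored |logFC| range
  expect_true(all(r$module_means > 1) && all(r$de_means > 1))
  expect_true(is.finite(r$p_value))
  # reproducible under the same seed
  r2 <- moduleVsConnectedRandom(study$interactome, study$module, tab,
                                size = 10L, nDraws = 200L, seed = 19L)
  expect_identical(r$module_means, r2$module_means)
  # degenerate draw count: summary only
  r1 <- moduleVsConnectedRandom(study$interactome, study$module, tab,
                                size = 5L, nDraws = 1L, seed = 3L)
  expect_true(is.na(r1$p_value))
})
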