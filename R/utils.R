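# Internal helpers shared across modules.

# Canonicalize gene symbols: strip whitespace, uppercase, drop empties.
.canonSymbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL / NA leaves the
# stream alone.
.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Z-score with a guard for a degenerate (zero-variance) null.
.zscore <- function(observed, nullMean, nullSd) {
  if (nullSd > 0) return((observed - nullMean) / nullSd)
  if (isTRUE(all.equal(observed, nullMean))) 0 else sign(observed - nullMean) * Inf
}

# Add-one empirical p-value: P(null at least as extreme as observed).
.empiricalP <- function(nullVals, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  b <- if (tail == "ge") sum(nullVals >= observed) else sum(nullVals <= observed)
  (1 + b) / (1 + length(nullVals))
}

# Lexicographically smallest of a list of name sequences (used for
# deterministic shortest-path tie-breaks). "\x01" sorts below every
# character that occurs in a gene symbol.
.lexMinPath <- function(paths) {
  keys <- vapply(paths, paste, character(1), collapse = "\x01")
  paths[[order(keys, method = "radix")[1L]]]
}

# Edge length ln(p / w) for a vector of confidences.
.edgeCosts <- function(g, p, hops = FALSE) {
  if (hops) return(rep(1, igraph::gsize(g)))
  w <- igraph::E(g)$weight
  log(p / w)
}
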