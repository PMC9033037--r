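test_that("half-up rounding follows the reporting convention", {
  expect_identical(roundHalfUp(0.125, 2), 0.13) # round() would give 0.12
  expect_identical(roundHalfUp(0.375, 2), 0.38)
  expect_identical(roundHalfUp(14.957264, 2), 14.96)
  expect_identical(roundHalfUp(2.7, 2), 2.7)
})

# Each (called, total, expected) pair exercises the percentage arithmetic
# of the chromosome summary against an externally supplied denominator.
test_that("chromosome summary reproduces count/denominator percentages", {
  cases <- list(
    list(k = 35L, total = 234, expected = 14.96),
    list(k = 10L, total = 270, expected = 3.70),
    list(k = 21L, total = 677, expected = 3.10),
    list(k = 30L, total = 1034, expected = 2.90)
  )
  for (case in cases) {
    universe <- sprintf("g%03d", seq_len(40L))
    ann <- data.frame(gene_id = universe, chromosome = "21")
    calls <- new("CallSet", stratum = "brain", threshold = 1.96,
                 overexpressed = universe[seq_len(case$k)],
                 underexpressed = character())
    out <- summarizeByChromosome(calls, ann, universe,
                                 chromosomeTotals = c("21" = case$total))
    expect_identical(out$overexpressed, case$k)
    expect_identical(out$total_genes, case$total)
    expect_identical(out$percentage, case$expected)
  }
})

test_that("chromosome summary falls back to universe denominators", {
  universe <- c("a", "b", "c", "d", "e")
  ann <- data.frame(
    gene_id = c("a", "b", "c", "d"), # e unannotated
    chromosome = c("21", "21", "2", "2")
  )
  calls <- new("CallSet", stratum = "brain", threshold = 1.96,
               overexpressed = c("a", "c", "e"), underexpressed = character())
  out <- summarizeByChromosome(calls, ann, universe)
  expect_identical(out$chromosome, c("2", "21"))
  expect_identical(out$total_genes, c(2, 2))
  expect_identical(out$overexpressed, c(1L, 1L)) # e excluded: no annotation
  expect_identical(out$percentage, c(50, 50))
  expect_lte(sum(out$overexpressed), 3L)
  expect_error(summarizeByChromosome(calls, ann, character()), "empty")
})

test_that("zero calls give all-zero percentages", {
  universe <- sprintf("g%d", 1:10)
  ann <- data.frame(gene_id = universe, chromosome = rep(c("1", "21"), 5))
  calls <- new("CallSet", stratum = "brain", threshold = 1.96,
               overexpressed = character(), underexpressed = character())
  out <- summarizeByChromosome(calls, ann, universe)
  expect_true(all(out$percentage == 0))
  expect_true(all(out$overexpressed == 0L))
})

test_that("structure summary percentages match the universe convention", {
  mkCalls <- function(n, stratum) {
    new("CallSet", stratum = stratum, threshold = 1.96,
        overexpressed = if (n) sprintf("%s_g%d", stratum, seq_len(n))
                        else character(),
        underexpressed = character())
  }
  out <- summarizeByStructure(
    list(brain = mkCalls(486L, "brain"), DFC = mkCalls(601L, "DFC"),
         HIP = mkCalls(426L, "HIP"), CBC = mkCalls(477L, "CBC"),
         empty = mkCalls(0L, "empty")),
    universeSize = 17537
  )
  expect_identical(out$stratum, c("brain", "DFC", "HIP", "CBC", "empty"))
  expect_identical(out$overexpressed, c(486L, 601L, 426L, 477L, 0L))
  expect_identical(out$percentage, c(2.77, 3.43, 2.43, 2.72, 0))
})

test_that("squared correlation matches construction and textbook oracle", {
  a <- zrv(c(1, -1, 0), ids = c("x", "y", "z"))
  expect_equal(zratioCorrelation(a, a), 1.0, tolerance = 1e-12)
  # zero covariance by construction
  expect_equal(zratioCorrelation(c(1, -1, 0), c(1, 1, -2)), 0,
               tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(5000)
    y <- rnorm(5000)
    expect_lt(abs(zratioCorrelation(x, y) - pearsonR2Oracle(x, y)), 1e-12)
    expect_lt(zratioCorrelation(x, y), 0.01) # independent nulls decorrelate
  }
})

test_that("correlation joins on shared genes and rejects degenerate input", {
  a <- zrv(c(1, 2, 3, 4), ids = c("a", "b", "c", "d"))
  b <- zrv(c(8, 6, 4), ids = c("c", "b", "a")) # reversed order, no "d"
  # after the inner join the pairing is exact: r^2 = 1 for a linear map
  expect_equal(zratioCorrelation(a, b), 1.0, tolerance = 1e-12)

  short <- zrv(c(1, 2), ids = c("a", "b"))
  expect_error(zratioCorrelation(a, short), "3 shared genes")
  flat <- zrv(c(1, 1, 1), ids = c("a", "b", "c"))
  expect_error(zratioCorrelation(a, flat), "zero variance")
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(22)
  x <- rnorm(200)
  y <- x + rnorm(200, sd = 0.5)
  base <- zratioCorrelation(x, y)
  expect_equal(zratioCorrelation(2.7 * x + 1, y), base, tolerance = 1e-12)
  expect_equal(zratioCorrelation(x, 0.3 * y - 5), base, tolerance = 1e-12)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(23)
  ids <- sprintf("g%d", 1:50)
  vs <- list(
    A = zrv(rnorm(50), ids = ids, stratum = "A"),
    B = zrv(rnorm(50), ids = ids, stratum = "B"),
    C = zrv(rnorm(50), ids = ids, stratum = "C")
  )
  m <- correlationMatrix(vs)
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(m, t(m))
  expect_lt(max(abs(diag(m) - 1)), 1e-9)
  expect_true(all(m >= 0 & m <= 1))

  twin <- correlationMatrix(list(A = vs$A, A2 = vs$A))
  expect_equal(twin["A", "A2"], 1.0, tolerance = 1e-12)

  disjoint <- list(
    A = vs$A,
    D = zrv(rnorm(50), ids = sprintf("h%d", 1:50), stratum = "D")
  )
  expect_error(correlationMatrix(disjoint), "shared genes")
  expect_error(correlationMatrix(vs["A"]), "two strata")
})

test_that("signed-rank p-values match exact enumeration on small samples", {
  set.seed(24)
  x <- rnorm(6, 0.8)
  y <- rnorm(6)
  out <- pairedTests(x, y)
  w <- out[out$test_name == "wilcoxon_signed_rank", ]
  expect_lt(abs(w$p_value - wilcoxonExactOracle(x, y)), 1e-9)
  expect_identical(w$n, 6L)
  expect_identical(out$alpha, c(0.05, 0.05))

  for (n in 5:10) {
    x <- rnorm(n)
    y <- rnorm(n)
    got <- pairedTests(x, y)
    wp <- got$p_value[got$test_name == "wilcoxon_signed_rank"]
    expect_lt(abs(wp - wilcoxonExactOracle(x, y)), 1e-9)
  }
})

test_that("paired tests detect forced separation and reject degeneracy", {
  set.seed(25)
  x <- rnorm(12)
  y <- x + 10 + rnorm(12, sd = 1e-3)
  out <- pairedTests(x, y)
  expect_true(all(out$p_value < 0.05))
  expect_error(pairedTests(x, x), "degenerate")
  expect_error(pairedTests(x, y[1:5]), "equal length")
  expect_error(pairedTests(1:3, 3:1), "at least 5")
  # zero-difference pairs are dropped before ranking
  x2 <- c(x, 5)
  y2 <- c(y, 5)
  expect_identical(
    pairedTests(x2, y2)$n[1],
    12L
  )
})
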