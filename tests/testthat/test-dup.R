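test_that("mode tabulation counts, proportions, and unclassified genes", {
  cat6 <- data.frame(gene_id = paste0("g", 1:6),
                     mode = c("WGD", "TD", "PD", "RD", "DSD", "ND"))
  tb <- tabulateModeDistribution(paste0("g", 1:6), cat6)
  expect_true(all(tb$proportions == 1 / 6))
  expect_equal(sum(tb$proportions), 1, tolerance = 1e-9)
  tb2 <- tabulateModeDistribution(c(paste0("g", 1:6), "x1", "x2"), cat6)
  expect_equal(tb2$nUnclassified, 2)
  expect_setequal(tb2$unclassified, c("x1", "x2"))
  expect_equal(sum(tb2$proportions), 1, tolerance = 1e-9)
  expect_error(tabulateModeDistribution(c("z1", "z2"), cat6), "empty intersection")
})

test_that("the printed study percentages round-trip to integer DEG counts", {
  degPct <- c(WGD = 3.96, TD = 14.58, PD = 5.21, RD = 27.71,
              DSD = 37.08, ND = 11.46)
  expect_identical(unname(round(480 * degPct / 100)),
                   c(19, 70, 25, 133, 178, 55))
})

test_that("goodness-of-fit statistic and calibration behave as defined", {
  g <- testGlobalDistribution(c(10, 0), c(0.5, 0.5))
  expect_equal(g$statistic, 10)
  expect_equal(g$df, 1L)
  bg <- c(0.1, 0.2, 0.3, 0.4)
  exact <- testGlobalDistribution(100 * bg, bg)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p, 1)
  expect_error(testGlobalDistribution(c(5, 5, 0), c(0.5, 0.5, 0)), "pool")
})

test_that("Fisher exact p matches enumeration and handles edge tables", {
  r <- testModeEnrichment(5, 10, 5, 10)
  expect_equal(r$p, 1)
  expect_equal(r$oddsRatio, 1)
  r2 <- testModeEnrichment(3, 3, 0, 3)   # table (3,0;0,3)
  expect_equal(r2$p, 0.1, tolerance = 1e-12)
  expect_error(testModeEnrichment(-1, 3, 1, 3), "non-negative")
  # Haldane correction engages on zero cells
  expect_true(is.finite(testModeEnrichment(3, 3, 0, 3)$oddsRatio))
  # spot-check against the enumeration oracle and fisher.test
  set.seed(61)
  for (i in 1:50) {
    m <- sample(1:25, 1); n <- sample(1:25, 1); k <- sample(1:(m + n), 1)
    a <- sample(max(0, k - n):min(k, m), 1)
    ours <- noduleTx:::fisherExact2x2_(a, m - a, k - a, n - (k - a))
    expect_equal(ours, fisherEnumOracle(a, m - a, k - a, n - (k - a)),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(a, m - a, k - a, n - (k - a)), 2, byrow = TRUE))
    expect_equal(ours, ft$p.value, tolerance = 1e-7)
  }
})

test_that("null cutoff is deterministic, type-7, and monotone in level", {
  set.seed(62)
  mat <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  nc1 <- nullCorrelationCutoff(mat, nPairs = 2000, seed = 99)
  nc2 <- nullCorrelationCutoff(mat, nPairs = 2000, seed = 99)
  expect_identical(nc1$cutoff, nc2$cutoff)
  expect_equal(nc1$cutoff,
               unname(quantile(nc1$samples, 0.95, type = 7)))
  nc90 <- nullCorrelationCutoff(mat, nPairs = 2000, level = 0.90, seed = 99)
  nc99 <- nullCorrelationCutoff(mat, nPairs = 2000, level = 0.99, seed = 99)
  expect_lte(nc90$cutoff, nc1$cutoff)
  expect_lte(nc1$cutoff, nc99$cutoff)
  expect_true(nc1$cutoff >= min(nc1$samples) && nc1$cutoff <= max(nc1$samples))
})

test_that("shared-profile matrices give cutoff 1; tiny matrices fall back to all pairs", {
  prof <- matrix(rep(seq_len(8), each = 5), 5, 8, byrow = FALSE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  expect_warning(nc <- nullCorrelationCutoff(prof, nPairs = 100, seed = 1),
                 "all of them")
  expect_equal(nc$cutoff, 1)
  expect_length(nc$samples, choose(5, 2))
})

test_that("constant-profile genes are skipped with a logged count", {
  set.seed(63)
  mat <- rbind(matrix(rnorm(40 * 12), 40, 12), matrix(3, 5, 12))
  rownames(mat) <- paste0("g", 1:45); colnames(mat) <- paste0("s", 1:12)
  nc <- suppressWarnings(nullCorrelationCutoff(mat, nPairs = 300, seed = 2))
  expect_equal(nc$nSkippedConstant, 5)
})

test_that("pair divergence classification follows the cutoff and DE restriction", {
  set.seed(64)
  base <- rnorm(12)
  expr <- rbind(a = base, b = base, c = rnorm(12), d = rep(1, 12), e = rnorm(12))
  colnames(expr) <- paste0("s", 1:12)
  pairs <- data.frame(gene1 = c("a", "a", "d", "zz"),
                      gene2 = c("b", "c", "e", "a"),
                      mode = c("TD", "TD", "RD", "RD"))
  expect_warning(pd <- classifyPairDivergence(pairs, expr, cutoff = 0.5),
                 "skipped")
  expect_identical(pd$pairs$divergence, c("conserved", "diverged", "undefined"))
  expect_equal(pd$divergedFractionByMode[["TD"]], 0.5)
  expect_true(is.na(pd$divergedFractionByMode[["RD"]]))
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   status = c("de_up", rep("not_de", 4)))
  pd2 <- classifyPairDivergence(pairs[1:3, ], expr, 0.5, deResults = de)
  expect_identical(pd2$pairs$divergence, c("conserved", "diverged", "not_assessed"))
})

test_that("planted divergence is recovered against a matched null cutoff", {
  acc <- vapply(1:5, function(seed) {
    cons <- simulateLatentProfiles(50, 2, 24, noiseSd = 0.1, seed = seed)
    set.seed(seed + 1000)
    div <- matrix(rnorm(100 * 24), 100, 24)
    rownames(div) <- paste0("d", 1:100); colnames(div) <- colnames(cons$mat)
    expr <- rbind(cons$mat, div)
    null <- matrix(rnorm(300 * 24), 300, 24,
                   dimnames = list(paste0("n", 1:300), colnames(expr)))
    nc <- nullCorrelationCutoff(null, nPairs = 5000, seed = seed)
    pairs <- data.frame(
      gene1 = c(rownames(cons$mat)[seq(1, 99, 2)], paste0("d", seq(1, 99, 2))),
      gene2 = c(rownames(cons$mat)[seq(2, 100, 2)], paste0("d", seq(2, 100, 2))))
    truthState <- rep(c("conserved", "diverged"), each = 50)
    pd <- classifyPairDivergence(pairs, expr, nc)
    mean(pd$pairs$divergence == truthState)
  }, numeric(1))
  expect_gte(mean(acc), 0.9)
})

test_that("mode enrichment report combines tabulation and tests coherently", {
  b <- smallBundle(seed = 17, deFraction = 0.1, tandemDeEnrichment = 6)
  de <- names(b$truth$deGenes)
  me <- modeEnrichment(de, rownames(b$experiment), b$catalog)
  expect_equal(sum(me$table$deg_pct), 100, tolerance = 1e-9)
  expect_equal(sum(me$table$bg_pct), 100, tolerance = 1e-9)
  expect_equal(me$global$df, 5L)
  expect_true(all(me$table$p >= 0 & me$table$p <= 1))
  me2 <- modeEnrichment(de, rownames(b$experiment), b$catalog,
                        excludeDegFromBackground = TRUE)
  expect_equal(me2$background$nClassified,
               me$background$nClassified - me$deg$nClassified)
})
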