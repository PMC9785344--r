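test_that("transform-and-filter keeps genes by the boundary-inclusive rule", {
  y <- rbind(zero = rep(0L, 6),
             boundary = c(1100L, 1100L, 1100L, 0L, 0L, 0L),
             high = rep(5000L, 6),
             low = rep(10L, 6))
  colnames(y) <- paste0("s", 1:6)
  tf <- transformAndFilter(y, sf = rep(1, 6))
  expect_true(all(c("boundary", "high") %in% rownames(tf)))
  expect_false(any(c("zero", "low") %in% rownames(tf)))
  # oracle re-application of the rule on a synthetic bundle
  b <- simulateCounts(generatorConfig(nGenes = 2000, seed = 71))
  nex <- computeSizeFactors(b$experiment)
  tf2 <- transformAndFilter(nex, threshold = 6, minSamples = 3)
  lm2 <- log2(sweep(counts(nex), 2, sizeFactors(nex), "/") + 1)
  keep <- rownames(lm2)[rowSums(lm2 >= 6) >= 3]
  expect_setequal(rownames(tf2), keep)
  expect_error(transformAndFilter(y, sf = rep(1, 6), threshold = 100), "filter")
})

test_that("signed-hybrid adjacency zeroes negative correlations and powers positives", {
  s <- seq_len(8)
  mat <- rbind(up1 = s, up2 = s, down = -s)
  mat <- mat + 0  # numeric
  colnames(mat) <- paste0("s", 1:8)
  a <- adjacencySignedHybrid(mat, beta = 6)
  expect_equal(a["up1", "up2"], 1)
  expect_equal(a["up1", "down"], 0)
  set.seed(72)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, 0, sqrt(0.75))
  m2 <- rbind(a = x, b = y); colnames(m2) <- paste0("s", 1:20)
  a2 <- adjacencySignedHybrid(m2, beta = 6)
  r <- cor(x, y)
  expect_equal(a2["a", "b"], if (r > 0) r^6 else 0)
  expect_equal(unname(adjacencySignedHybrid(
    rbind(a = c(0.5, 1, 0.25), b = c(1, 0.5, 0.25), c = c(1, 2, 3)) * 0 +
      rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)), beta = 6)["a", "b"]), 1)
})

test_that("constant profiles get zero adjacency with a warning", {
  mat <- rbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(4, 3, 2, 1))
  colnames(mat) <- paste0("s", 1:4)
  expect_warning(a <- adjacencySignedHybrid(mat), "constant")
  expect_equal(unname(a["b", c("a", "c")]), c(0, 0))
  expect_equal(a["b", "b"], 1)
})

test_that("TOM matches the brute-force triple loop and edge cases", {
  # two genes adjacent only to each other with a = 1 -> TOM = 1
  a <- diag(3); a[1, 2] <- a[2, 1] <- 1
  tom <- topologicalOverlap(a)
  expect_equal(tom[1, 2], 1)
  expect_equal(unname(tom[3, 1:2]), c(0, 0))  # isolated gene
  set.seed(73)
  for (G in c(20, 50)) {
    r <- matrix(runif(G * G), G)
    adj <- (r + t(r)) / 2; diag(adj) <- 1
    expect_equal(topologicalOverlap(adj), bruteTom(adj), tolerance = 1e-10)
  }
})

test_that("module detection recovers planted blocks and obeys size/merge rules", {
  sim <- simulateLatentProfiles(2, 30, 20, noiseSd = 0.1, seed = 74)
  tom <- topologicalOverlap(adjacencySignedHybrid(sim$mat))
  asg <- detectModules(tom, sim$mat)
  mods <- setdiff(unique(asg), "grey")
  expect_length(mods, 2)
  expect_gte(adjustedRand(asg, sim$blocks), 0.95)
  # fewer genes than the size floor -> all grey
  tiny <- simulateLatentProfiles(1, 10, 12, noiseSd = 0.1, seed = 75)
  tomT <- topologicalOverlap(adjacencySignedHybrid(tiny$mat))
  expect_true(all(detectModules(tomT, tiny$mat, minModuleSize = 20) == "grey"))
  # merge disabled keeps the statically cut modules apart
  asg0 <- detectModules(tom, sim$mat, mergeCutHeight = 0)
  expect_gte(length(setdiff(unique(asg0), "grey")), 2)
})

test_that("degenerate TOM collapses to a single module with a warning", {
  tomEq <- matrix(0.5, 25, 25); diag(tomEq) <- 1
  mat <- matrix(rnorm(25 * 8), 25, 8,
                dimnames = list(paste0("g", 1:25), paste0("s", 1:8)))
  expect_warning(asg <- detectModules(tomEq, mat, minModuleSize = 5),
                 "degenerate")
  expect_length(setdiff(unique(asg), "grey"), 1)
})

test_that("eigengenes summarize modules with the documented orientation", {
  prof <- rnorm(10)
  mat <- rbind(g1 = 2 * prof + 3, g2 = -1 + 0.5 * prof, g3 = prof)
  colnames(mat) <- paste0("s", 1:10)
  asg <- structure(rep("turquoise", 3), names = rownames(mat))
  me <- moduleEigengenes(mat, asg)
  expect_equal(me$varianceExplained[["turquoise"]], 1, tolerance = 1e-12)
  expect_gt(cor(me$eigengenes["turquoise", ], prof), 0.999)
  expect_equal(sum(me$eigengenes["turquoise", ]^2), 1, tolerance = 1e-12)
  # flipping all module genes flips the eigengene
  meF <- moduleEigengenes(-mat, asg)
  expect_equal(unname(meF$eigengenes["turquoise", ]),
               unname(-me$eigengenes["turquoise", ]), tolerance = 1e-9)
  badAsg <- structure(rep("blue", 2), names = c("c1", "c2"))
  constMat <- matrix(1, 2, 10, dimnames = list(c("c1", "c2"), colnames(mat)))
  expect_error(moduleEigengenes(constMat, badAsg), "blue")
})

test_that("planted latent factors are tracked by module eigengenes", {
  sim <- simulateLatentProfiles(2, 30, 24, noiseSd = 0.1, seed = 76)
  tom <- topologicalOverlap(adjacencySignedHybrid(sim$mat))
  asg <- detectModules(tom, sim$mat)
  me <- moduleEigengenes(sim$mat, asg)
  best <- apply(me$eigengenes, 1, function(v) {
    max(abs(apply(sim$factors, 1, cor, y = v)))
  })
  expect_true(all(best >= 0.95))
})

test_that("module-trait correlations flag at the documented threshold", {
  sim <- simulateLatentProfiles(1, 25, 16, noiseSd = 0.1, seed = 77)
  asg <- structure(rep("turquoise", 25), names = rownames(sim$mat))
  me <- moduleEigengenes(sim$mat, asg)
  traits <- cbind(same = me$eigengenes["turquoise", ],
                  anti = -me$eigengenes["turquoise", ],
                  const = rep(1, 16))
  rownames(traits) <- colnames(sim$mat)
  mt <- moduleTraitCorrelation(me$eigengenes, traits)
  expect_equal(mt$r[mt$trait == "same"], 1, tolerance = 1e-9)
  expect_equal(mt$r[mt$trait == "anti"], -1, tolerance = 1e-9)
  expect_true(is.na(mt$r[mt$trait == "const"]))
  expect_true(mt$significant[mt$trait == "same"])
})

test_that("independent traits are flagged at about the nominal rate", {
  set.seed(78)
  sim <- simulateLatentProfiles(3, 25, 20, noiseSd = 0.2, seed = 78)
  tom <- topologicalOverlap(adjacencySignedHybrid(sim$mat))
  asg <- detectModules(tom, sim$mat)
  me <- moduleEigengenes(sim$mat, asg)
  flags <- replicate(300, {
    tr <- cbind(perm = rnorm(ncol(sim$mat)))
    rownames(tr) <- colnames(sim$mat)
    mt <- moduleTraitCorrelation(me$eigengenes, tr)
    mean(mt$significant)
  })
  expect_lt(abs(mean(flags) - 0.01), 0.015)
})

test_that("hypergeometric enrichment equals the closed-form tail", {
  universe <- paste0("g", 1:1000)
  term <- paste0("g", 1:10)
  ann <- data.frame(gene_id = term, term_id = "T1")
  res <- hypergeometricEnrichment(term, ann, universe)
  expect_equal(res$p, phyper(9, 10, 990, 10, lower.tail = FALSE),
               tolerance = 1e-15)
  expect_equal(res$p, 1 / choose(1000, 10), tolerance = 1e-12)
  # k = 0 gives p = 1 by the upper-tail convention
  res0 <- hypergeometricEnrichment(paste0("g", 500:520), ann, universe)
  expect_equal(res0$p, 1)
  expect_error(hypergeometricEnrichment("not_in_universe", ann, universe),
               "subset")
  expect_warning(
    hypergeometricEnrichment(term, rbind(ann, data.frame(gene_id = "zz",
                                                         term_id = "T2")),
                             universe), "skipped")
})

test_that("enrichment p matches exhaustive enumeration on small universes", {
  set.seed(79)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(2:min(30, N), 1)
    n <- sample(2:min(40, N), 1)
    term <- sample(uni, K)
    mod <- sample(uni, n)
    ann <- data.frame(gene_id = term, term_id = "T")
    k <- length(intersect(term, mod))
    res <- hypergeometricEnrichment(mod, ann, uni)
    # enumeration oracle: sum over j >= k of C(K,j)C(N-K,n-j)/C(N,n)
    pj <- sapply(k:min(K, n), function(j) {
      exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
    })
    expect_equal(res$p, if (k == 0) 1 else sum(pj), tolerance = 1e-10)
  }
})

test_that("planted enriched terms are detected at FDR < 0.05", {
  b <- smallBundle(seed = 23, nGenes = 800, latentGeneFraction = 0.3)
  nex <- computeSizeFactors(b$experiment)
  universe <- rownames(nex)
  for (tm in names(b$truth$plantedTerms)) {
    f <- b$truth$plantedTerms[[tm]]
    fg <- names(b$truth$trueModules)[b$truth$trueModules == f]
    res <- hypergeometricEnrichment(fg, b$annotation, universe)
    expect_true(res$enriched[res$term_id == tm])
  }
})

test_that("edge-list export respects the adjacency threshold", {
  a <- matrix(c(1, 0.8, 0.05, 0.8, 1, 0.2, 0.05, 0.2, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  el <- adjacencyEdgeList(a, threshold = 0.1)
  expect_identical(nrow(el), 2L)
  expect_identical(nrow(adjacencyEdgeList(a, threshold = 2)), 0L)
})
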