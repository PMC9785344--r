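test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generatorConfig(deFraction = 1.5), "deFraction")
  expect_error(generatorConfig(dupModeProportions = c(WGD = 0.5, TD = 0.5,
                                                      PD = 0, RD = 0, DSD = 0,
                                                      ND = 0.1)), "sum to 1")
  expect_error(generatorConfig(tandemDeEnrichment = 0.5), "tandemDeEnrichment")
  expect_error(generatorConfig(nGenes = 0), "nGenes")
})

test_that("planted DE gene count follows the floor rule and zero fraction plants nothing", {
  b0 <- simulateCounts(generatorConfig(nGenes = 400, deFraction = 0, seed = 1))
  expect_length(b0$truth$deGenes, 0)
  b <- simulateCounts(generatorConfig(nGenes = 1000, deFraction = 0.05, seed = 1))
  expect_length(b$truth$deGenes, 50)
  expect_true(all(abs(b$truth$deGenes) >= 1.2 & abs(b$truth$deGenes) <= 3))
  expect_true(all(names(b$truth$deGenes) %in% rownames(b$experiment)))
})

test_that("equal seeds give byte-identical written bundles", {
  cfg <- generatorConfig(nGenes = 300, ncrCount = 4, decoyCount = 8, seed = 42)
  d1 <- file.path(tempdir(), "bundleA"); d2 <- file.path(tempdir(), "bundleB")
  writeBundle(simulateBundle(cfg), d1)
  writeBundle(simulateBundle(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("with no planted effects the group log-ratios are centered at zero", {
  b <- simulateCounts(generatorConfig(nGenes = 3000, deFraction = 0,
                                      nDupPairs = 0, nLatentFactors = 0,
                                      seed = 3))
  nex <- computeSizeFactors(b$experiment)
  z <- normalizedCounts(counts(nex), sizeFactors(nex))
  grp <- SummarizedExperiment::colData(nex)$bnf_class
  lr <- log2(rowMeans(z[, grp == "high"]) + 0.5) -
    log2(rowMeans(z[, grp == "low"]) + 0.5)
  se <- sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr)), 3 * se)
})

test_that("conserved pairs built from shared latent profiles correlate strongly", {
  rs <- unlist(lapply(1:20, function(seed) {
    sim <- simulateLatentProfiles(nBlocks = 10, genesPerBlock = 2,
                                  nSamples = 24, noiseSd = 0.1, seed = seed)
    vapply(seq_len(10), function(b) {
      idx <- which(sim$blocks == b)
      cor(sim$mat[idx[1], ], sim$mat[idx[2], ])
    }, numeric(1))
  }))
  expect_gt(mean(rs), 0.9)
})

test_that("pair truth covers the emitted pair list and divergence labels", {
  b <- smallBundle(seed = 9)
  expect_identical(b$pairs$gene1, b$truth$pairs$gene1)
  expect_true(all(b$pairs$divergence %in% c("conserved", "diverged")))
  expect_true(all(b$pairs$mode %in% setdiff(noduleTx:::DUP_MODES, "ND")))
  expect_true(all(c(b$pairs$gene1, b$pairs$gene2) %in% rownames(b$experiment)))
  b0 <- simulateBundle(generatorConfig(nGenes = 600, divergedPairFraction = 0,
                                       seed = 2))
  expect_true(all(b0$pairs$divergence == "conserved"))
})

test_that("without enrichment the tandem rate is equal among DE and non-DE genes", {
  pv <- vapply(1:40, function(seed) {
    cfg <- generatorConfig(nGenes = 4000, deFraction = 0.1,
                           tandemDeEnrichment = 1, nDupPairs = 0, seed = seed)
    b <- simulateCounts(cfg)
    dup <- simulateDuplicationCatalog(cfg, b$truth)
    de <- names(b$truth$deGenes)
    isTd <- dup$catalog$mode == "TD"
    isDe <- dup$catalog$gene_id %in% de
    suppressWarnings(chisq.test(table(isTd, isDe))$p.value)
  }, numeric(1))
  # null case: rejections stay near the nominal rate, no pile-up of small p
  expect_lte(mean(pv < 0.05), 0.2)
  expect_gt(mean(pv), 0.3)
})

test_that("generated proteins encode the planted structure and decoy violations", {
  cfg <- generatorConfig(nGenes = 500, ncrCount = 6, decoyCount = 12, seed = 4)
  b <- simulateCounts(cfg)
  pr <- simulateProteins(cfg, b$truth)
  expect_length(pr$ncrIds, 6)
  expect_length(pr$decoyReasons, 12)
  w <- Biostrings::width(pr$proteins)
  names(w) <- names(pr$proteins)
  expect_true(all(w[pr$ncrIds] < 150))
  expect_true(all(w[names(pr$decoyReasons)[pr$decoyReasons == "length"]] >= 150))
  pr0 <- simulateProteins(generatorConfig(nGenes = 500, ncrCount = 0,
                                          decoyCount = 5, seed = 4), b$truth)
  expect_length(pr0$ncrIds, 0)
})

test_that("Ct tables are seed-deterministic and encode expression doublings", {
  cfg <- generatorConfig(nGenes = 500, seed = 6)
  b <- simulateCounts(cfg)
  ct1 <- simulateCtTable(cfg, b$truth)
  ct2 <- simulateCtTable(cfg, b$truth)
  expect_identical(ct1$ct, ct2$ct)
  # reference gene: constant expected expression, so Ct flat up to noise
  refCt <- ct1$ct[ct1$ct$gene == b$truth$referenceGene, ]
  expect_lt(diff(range(tapply(refCt$ct, refCt$sample, mean))), 0.5)
  expect_error(simulateCtTable(cfg, list(geneIds = "g1")), "reference gene")
})

test_that("recomputed ddCt fold changes recover the planted fold changes", {
  cfg <- generatorConfig(nGenes = 800, deFraction = 0.05,
                         deLog2fcRange = c(2, 2), nDupPairs = 0,
                         nLatentFactors = 0, genotypeEffectSd = 0.05, seed = 8)
  b <- simulateCounts(cfg)
  ctb <- simulateCtTable(cfg, b$truth)
  res <- relativeExpressionDDCt(ctb$ct, ctb$referenceGene,
                                calibratorSample = colnames(b$experiment)[1])
  meta <- as.data.frame(SummarizedExperiment::colData(b$experiment))
  deTargets <- intersect(ctb$targets, names(b$truth$deGenes))
  for (g in deTargets) {
    sub <- res[res$gene == g, ]
    hi <- mean(sub$fold[meta$bnf_class[match(sub$sample, meta$sample_id)] == "high"])
    lo <- mean(sub$fold[meta$bnf_class[match(sub$sample, meta$sample_id)] == "low"])
    planted <- 2^b$truth$deGenes[[g]]
    expect_equal(log2(hi / lo), log2(planted), tolerance = 0.15)
  }
})

test_that("traits carry the planted group difference and mass-ethylene link", {
  b <- simulateCounts(generatorConfig(nGenes = 200, seed = 10))
  meta <- as.data.frame(SummarizedExperiment::colData(b$experiment))
  g <- meta[!duplicated(meta$genotype), ]
  expect_gt(mean(g$ethylene[g$bnf_class == "high"]),
            mean(g$ethylene[g$bnf_class == "low"]))
  expect_gt(cor(g$fresh_mass, g$ethylene), 0.3)
})
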