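#' @importFrom stats rlnorm rnbinom rnorm runif rgamma rbinom
NULL

#' Derive a stage seed from the top-level seed
#'
#' All generator and pipeline randomness flows from one integer seed;
#' per-stage seeds are derived by hashing the stage name so that any stage
#' can be re-run in isolation with the same stream.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return integer below 2^31.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

geneIds_ <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate a nodule RNA-seq experiment with planted ground truth
#'
#' Draws a negative-binomial count matrix for 2 BNF groups x
#' \code{nGenotypesPerGroup} genotypes x \code{nReplicates} replicates.
#' Planted structure, all recorded in the returned ground truth:
#' \itemize{
#'   \item DE genes (a \code{deFraction} of genes, |log2FC| in
#'     \code{deLog2fcRange}, \code{deUpFraction} up-regulated in high-BNF);
#'   \item genotype-level log-normal random effects (so replicate QC
#'     clustering has structure to find);
#'   \item latent sample factors loading co-expression-module genes;
#'   \item duplicate pairs: conserved pairs share a latent per-sample
#'     profile (plus \code{pairNoiseSd} log2 noise), diverged pairs get
#'     independent profiles; the first pair member is drawn from the DE
#'     genes when possible so that pair divergence is assessable downstream;
#'   \item a constant reference (housekeeping) gene for qPCR;
#'   \item sample traits: ethylene from group-shifted gamma distributions
#'     and fresh mass as an affine function of ethylene with a steeper slope
#'     for tetraploids.
#' }
#' Library sizes are log-uniform over \code{librarySizeRange}; dispersion
#' follows the mild trend \code{nbDispersion + 2/baseMean}. Equal seeds give
#' identical bundles.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list: \code{experiment} (\linkS4class{NoduleExperiment} with true
#'   traits in colData), \code{truth} (list: \code{deGenes} named true-lfc
#'   vector, \code{pairs} data.frame with divergence states,
#'   \code{trueModules} gene -> factor id, \code{referenceGene},
#'   \code{sizeFactors}, \code{geneIds}, \code{log2Mu} expected log2
#'   normalized means).
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  set.seed(deriveSeed(config@seed, "counts"))
  G <- config@nGenes
  npg <- config@nGenotypesPerGroup
  nrep <- config@nReplicates
  nGeno <- 2L * npg
  n <- nGeno * nrep
  genes <- geneIds_(G)

  group <- rep(c("low", "high"), each = npg)
  genoIds <- paste0(rep(c("L", "H"), each = npg), rep(seq_len(npg), 2))
  ploidy <- rep(rep(c("2n", "4n"), length.out = npg), 2)
  sampleGeno <- rep(seq_len(nGeno), each = nrep)
  sampleIds <- paste0(genoIds[sampleGeno], "_r", rep(seq_len(nrep), nGeno))
  x <- as.numeric(group[sampleGeno] == "high")

  baseMean <- rlnorm(G, log(150), 1.2)
  logMu2 <- matrix(log2(baseMean), G, n, dimnames = list(genes, sampleIds))

  # planted DE
  nDe <- floor(config@deFraction * G)
  deGenes <- if (nDe > 0) sort(sample(genes, nDe)) else character(0)
  trueLfc <- structure(numeric(nDe), names = deGenes)
  if (nDe > 0) {
    mag <- runif(nDe, config@deLog2fcRange[1], config@deLog2fcRange[2])
    nUp <- round(nDe * config@deUpFraction)
    sgn <- rep(c(1, -1), c(nUp, nDe - nUp))[sample.int(nDe)]
    trueLfc[] <- mag * sgn
    logMu2[deGenes, ] <- logMu2[deGenes, , drop = FALSE] + outer(trueLfc, x)
  }

  # duplicate pairs: gene1 from DE genes when available, gene2 from the rest
  pool <- setdiff(genes, deGenes)
  nPair <- min(config@nDupPairs, floor((G - nDe) / 2), G %/% 2)
  pairs <- NULL
  if (nPair > 0) {
    n1de <- min(nDe %/% 2, nPair)  # only part of the DE set joins pairs
    g1 <- c(if (n1de > 0) sample(deGenes, n1de),
            if (nPair > n1de) sample(pool, nPair - n1de))
    pool <- setdiff(pool, g1)
    g2 <- sample(pool, nPair)
    pool <- setdiff(pool, g2)
    nDiv <- round(config@divergedPairFraction * nPair)
    state <- rep(c("diverged", "conserved"), c(nDiv, nPair - nDiv))
    lat1 <- matrix(rnorm(nPair * n), nPair, n)
    lat2 <- matrix(rnorm(nPair * n), nPair, n)
    for (k in seq_len(nPair)) {
      if (state[k] == "conserved") {
        logMu2[g1[k], ] <- logMu2[g1[k], ] + lat1[k, ] +
          rnorm(n, 0, config@pairNoiseSd)
        logMu2[g2[k], ] <- logMu2[g2[k], ] + lat1[k, ] +
          rnorm(n, 0, config@pairNoiseSd)
      } else {
        logMu2[g1[k], ] <- logMu2[g1[k], ] + lat1[k, ]
        logMu2[g2[k], ] <- logMu2[g2[k], ] + lat2[k, ]
      }
    }
    pairs <- data.frame(gene1 = g1, gene2 = g2, divergence = state,
                        stringsAsFactors = FALSE)
  }

  # latent co-expression factors
  trueModules <- structure(integer(0), names = character(0))
  nLat <- min(floor(config@latentGeneFraction * G), length(pool))
  if (config@nLatentFactors > 0 && nLat >= config@nLatentFactors) {
    latGenes <- sample(pool, nLat)
    pool <- setdiff(pool, latGenes)
    fac <- rep(seq_len(config@nLatentFactors), length.out = nLat)
    scores <- matrix(rnorm(config@nLatentFactors * n),
                     config@nLatentFactors, n)
    load <- runif(nLat, 0.6, 1.0)
    logMu2[latGenes, ] <- logMu2[latGenes, , drop = FALSE] +
      load * scores[fac, , drop = FALSE]
    trueModules <- structure(fac, names = latGenes)
  }

  # genotype random effects (log2 scale), skipping the reference gene below
  genoEff <- matrix(rnorm(G * nGeno, 0, config@genotypeEffectSd), G, nGeno)
  referenceGene <- if (length(pool)) sample(pool, 1) else genes[1]
  genoEff[match(referenceGene, genes), ] <- 0
  baseMean[match(referenceGene, genes)] <- 500
  logMu2[referenceGene, ] <- log2(500)
  logMu2 <- logMu2 + genoEff[, sampleGeno]

  lib <- exp(runif(n, log(config@librarySizeRange[1]),
                   log(config@librarySizeRange[2])))
  sfTrue <- lib / exp(mean(log(lib)))
  alpha <- config@nbDispersion + 2 / baseMean
  mu <- sweep(2^logMu2, 2, sfTrue, "*")
  cts <- matrix(rnbinom(G * n, mu = mu, size = rep(1 / alpha, n)), G, n,
                dimnames = list(genes, sampleIds))

  # genotype-level traits
  ethyGeno <- ifelse(group == "high",
                     rgamma(nGeno, shape = 6, scale = 0.35),
                     rgamma(nGeno, shape = 3, scale = 0.20))
  slope <- ifelse(ploidy == "4n", 120, 60)
  massGeno <- 50 + slope * ethyGeno + rnorm(nGeno, 0, 15)
  meta <- data.frame(sample_id = sampleIds,
                     genotype = genoIds[sampleGeno],
                     replicate = rep(seq_len(nrep), nGeno),
                     bnf_class = group[sampleGeno],
                     ploidy = ploidy[sampleGeno],
                     fresh_mass = round(massGeno[sampleGeno], 2),
                     ethylene = round(ethyGeno[sampleGeno], 4),
                     stringsAsFactors = FALSE)
  nex <- NoduleExperiment(cts, meta)
  truth <- list(deGenes = trueLfc, pairs = pairs, trueModules = trueModules,
                referenceGene = referenceGene, sizeFactors = sfTrue,
                geneIds = genes, log2Mu = logMu2, seed = config@seed)
  list(experiment = nex, truth = truth)
}

#' Simulate a duplication catalog and duplicate-pair list
#'
#' Assigns every gene a duplication mode drawn from
#' \code{dupModeProportions}; planted DE genes are re-drawn from
#' proportions whose tandem (TD) and dispersed (DSD) odds are multiplied by
#' \code{tandemDeEnrichment}, planting the over-representation the
#' enrichment stage should recover. Planted duplicate pairs get a shared
#' (non-ND) mode for both members.
#'
#' @param config \code{\link{generatorConfig}}.
#' @param truth ground truth from \code{\link{simulateCounts}}.
#' @return list: \code{catalog} (data.frame gene_id, mode), \code{pairs}
#'   (data.frame gene1, gene2, mode, divergence).
#' @export
simulateDuplicationCatalog <- function(config, truth) {
  stopifnot(is(config, "GeneratorConfig"))
  if (is.null(truth$geneIds)) stop("consistency error: truth lacks geneIds")
  set.seed(deriveSeed(config@seed, "dup_catalog"))
  genes <- truth$geneIds
  p <- config@dupModeProportions
  mode <- sample(DUP_MODES, length(genes), replace = TRUE, prob = p)
  names(mode) <- genes
  de <- names(truth$deGenes)
  if (!all(de %in% genes)) stop("consistency error: DE genes not in matrix")
  if (length(de)) {
    pDe <- p
    pDe[c("TD", "DSD")] <- pDe[c("TD", "DSD")] * config@tandemDeEnrichment
    pDe <- pDe / sum(pDe)
    mode[de] <- sample(DUP_MODES, length(de), replace = TRUE, prob = pDe)
  }
  pairs <- truth$pairs
  if (!is.null(pairs) && nrow(pairs)) {
    pNoND <- p[DUP_MODES != "ND"] / sum(p[DUP_MODES != "ND"])
    pmode <- sample(setdiff(DUP_MODES, "ND"), nrow(pairs),
                    replace = TRUE, prob = pNoND)
    mode[pairs$gene1] <- pmode
    mode[pairs$gene2] <- pmode
    pairs <- data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                        mode = pmode, divergence = pairs$divergence,
                        stringsAsFactors = FALSE)
  }
  list(catalog = data.frame(gene_id = genes, mode = unname(mode),
                            stringsAsFactors = FALSE),
       pairs = pairs)
}

AA_FILLER <- c("K", "E", "N", "Q", "D", "R", "P", "Y", "W", "H", "M", "F")
AA_POLAR <- c("K", "E", "N", "Q", "D", "R")

buildMature_ <- function(gaps, lead, trail, filler) {
  body <- character(0)
  for (i in seq_along(gaps)) {
    body <- c(body, "C", sample(filler, gaps[i], replace = TRUE))
  }
  body <- c(sample(filler, lead, replace = TRUE), body, "C",
            sample(filler, trail, replace = TRUE))
  paste(body, collapse = "")
}

signalPrefix_ <- function() {
  paste0("M", paste(sample(c("L", "V", "I", "F"), 13, replace = TRUE),
                    collapse = ""), "A")
}

drawGaps_ <- function(bounds) {
  as.integer(round(runif(nrow(bounds), bounds[, 1], bounds[, 2])))
}

#' Simulate NCR-like peptides and single-violation decoys
#'
#' Planted NCR records have an N-terminal hydrophobic signal stretch with a
#' cleavage site at residue 15, a mature region with exactly 4 or 6
#' cysteines at spacings inside the default grammar, and total length below
#' 150 residues. Each decoy violates exactly one criterion (length >= 150,
#' wrong cysteine count, spacing out of bounds, or no signal stretch); the
#' violated criterion is recorded. Sequence ids are gene ids from the count
#' matrix (half the NCRs are planted on DE genes when available) so that
#' candidates can be adjudicated against DE results.
#'
#' @param config \code{\link{generatorConfig}}.
#' @param truth ground truth from \code{\link{simulateCounts}}; optional
#'   (ids fall back to a fresh id sequence).
#' @param pattern the \code{\link{cysteinePattern}} grammar to plant within.
#' @return list: \code{proteins} (\code{Biostrings::AAStringSet}),
#'   \code{ncrIds}, \code{decoyReasons} (named by decoy id).
#' @export
simulateProteins <- function(config, truth = NULL, pattern = cysteinePattern()) {
  stopifnot(is(config, "GeneratorConfig"))
  set.seed(deriveSeed(config@seed, "proteins"))
  nNcr <- config@ncrCount; nDec <- config@decoyCount
  if (!is.null(truth)) {
    de <- names(truth$deGenes)
    nFromDe <- min(length(de), nNcr %/% 2)
    ids <- c(if (nFromDe) sample(de, nFromDe),
             sample(setdiff(truth$geneIds, de), nNcr + nDec - nFromDe))
  } else {
    ids <- sprintf("seq%04d", seq_len(nNcr + nDec))
  }
  ncrIds <- if (nNcr) ids[seq_len(nNcr)] else character(0)
  decIds <- if (nDec) ids[nNcr + seq_len(nDec)] else character(0)

  makeNcr <- function() {
    if (runif(1) < 0.5) {
      paste0(signalPrefix_(),
             buildMature_(drawGaps_(pattern@spacing4), sample(2:6, 1),
                          sample(2:15, 1), AA_FILLER))
    } else {
      paste0(signalPrefix_(),
             buildMature_(drawGaps_(pattern@spacing6), sample(2:6, 1),
                          sample(2:10, 1), AA_FILLER))
    }
  }
  reasons <- c("length", "cysteine count", "spacing", "signal peptide")
  makeDecoy <- function(reason) {
    switch(reason,
      "length" = {
        s <- makeNcr()
        paste0(s, paste(sample(AA_FILLER, 155 - nchar(s), replace = TRUE),
                        collapse = ""))
      },
      "cysteine count" = {
        g <- sample(c(3L, 5L, 7L), 1)
        paste0(signalPrefix_(),
               buildMature_(rep(5L, g - 1L), 3, 8, AA_FILLER))
      },
      "spacing" = {
        gaps <- drawGaps_(pattern@spacing4)
        bad <- sample(3, 1)
        gaps[bad] <- if (runif(1) < 0.5) pattern@spacing4[bad, 1] - 1L
                     else pattern@spacing4[bad, 2] + 3L
        gaps <- pmax(gaps, 0L)
        paste0(signalPrefix_(), buildMature_(gaps, 3, 8, AA_FILLER))
      },
      "signal peptide" = {
        paste0("M", paste(sample(AA_POLAR, 8, replace = TRUE), collapse = ""),
               buildMature_(drawGaps_(pattern@spacing4), 3, 8, AA_POLAR))
      })
  }
  seqs <- character(0)
  if (nNcr) seqs <- vapply(seq_len(nNcr), function(i) makeNcr(), character(1))
  decoyReasons <- character(0)
  if (nDec) {
    decoyReasons <- rep(reasons, length.out = nDec)
    seqs <- c(seqs, vapply(decoyReasons, makeDecoy, character(1)))
    names(decoyReasons) <- decIds
  }
  names(seqs) <- ids
  proteins <- Biostrings::AAStringSet(seqs)
  list(proteins = proteins, ncrIds = ncrIds, decoyReasons = decoyReasons)
}

#' Simulate a qPCR Ct table consistent with the planted expression
#'
#' For the reference (housekeeping) gene and a panel of target genes, Ct
#' values are generated as \code{ctIntercept - log2(q)} plus measurement
#' noise, where q is the planted expected normalized expression -- so Ct
#' drops by one cycle per doubling of expression and 2^-ddCt fold changes
#' recomputed from the table recover the planted fold changes within noise.
#'
#' @param config \code{\link{generatorConfig}}.
#' @param truth ground truth from \code{\link{simulateCounts}}.
#' @param nTargets number of target genes (planted DE genes first).
#' @param ctNoiseSd technical noise sd in cycles (default 0.05).
#' @param nTechReps technical replicates per (sample, gene) (default 3).
#' @return list: \code{ct} (data.frame sample, gene, ct), \code{targets},
#'   \code{referenceGene}.
#' @export
simulateCtTable <- function(config, truth, nTargets = 8, ctNoiseSd = 0.05,
                            nTechReps = 3) {
  stopifnot(is(config, "GeneratorConfig"))
  if (is.null(truth$referenceGene) || is.null(truth$log2Mu)) {
    stop("input error: truth lacks the designated reference gene")
  }
  set.seed(deriveSeed(config@seed, "ct"))
  de <- names(truth$deGenes)
  pool <- setdiff(truth$geneIds, c(de, truth$referenceGene))
  nFromDe <- min(length(de), nTargets %/% 2)
  targets <- c(if (nFromDe) sample(de, nFromDe),
               sample(pool, nTargets - nFromDe))
  genes <- c(truth$referenceGene, targets)
  lm2 <- truth$log2Mu[genes, , drop = FALSE]
  rows <- expand.grid(rep = seq_len(nTechReps),
                      sample = colnames(lm2), gene = genes,
                      stringsAsFactors = FALSE)
  base <- 30 - lm2[cbind(rows$gene, rows$sample)]
  rows$ct <- round(base + rnorm(nrow(rows), 0, ctNoiseSd), 3)
  list(ct = rows[, c("sample", "gene", "ct")], targets = targets,
       referenceGene = truth$referenceGene)
}

#' Simulate a gene-to-term annotation table with planted enrichment
#'
#' Background terms are assigned gene-wise at \code{termBackgroundRate};
#' additionally each latent co-expression factor gets one planted term
#' covering \code{plantedTermRate} of its genes, so module-wise
#' hypergeometric enrichment has a known answer.
#'
#' @param config \code{\link{generatorConfig}}.
#' @param truth ground truth from \code{\link{simulateCounts}}.
#' @return list: \code{annotation} (data.frame gene_id, term_id),
#'   \code{plantedTerms} (named vector term -> factor id).
#' @export
simulateAnnotation <- function(config, truth) {
  stopifnot(is(config, "GeneratorConfig"))
  set.seed(deriveSeed(config@seed, "annotation"))
  genes <- truth$geneIds
  rows <- list()
  for (t in seq_len(config@nBackgroundTerms)) {
    hit <- genes[runif(length(genes)) < config@termBackgroundRate]
    if (length(hit)) {
      rows[[length(rows) + 1]] <- data.frame(gene_id = hit,
                                             term_id = sprintf("TERMB%02d", t),
                                             stringsAsFactors = FALSE)
    }
  }
  plantedTerms <- structure(integer(0), names = character(0))
  if (length(truth$trueModules)) {
    for (f in sort(unique(truth$trueModules))) {
      fg <- names(truth$trueModules)[truth$trueModules == f]
      hit <- fg[runif(length(fg)) < config@plantedTermRate]
      tm <- sprintf("TERMF%02d", f)
      bgHit <- setdiff(genes, fg)[runif(length(setdiff(genes, fg))) <
                                    config@termBackgroundRate]
      rows[[length(rows) + 1]] <- data.frame(gene_id = c(hit, bgHit),
                                             term_id = tm,
                                             stringsAsFactors = FALSE)
      plantedTerms[tm] <- f
    }
  }
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$gene_id, ann$term_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotation = ann, plantedTerms = plantedTerms)
}

#' Simulate a complete experiment bundle
#'
#' Runs every generator stage (counts, duplication catalog, proteins, Ct
#' table, annotation) from one config and merges the ground truth. When
#' \code{outdir} is given the bundle is also written as plain-text files via
#' \code{\link{writeBundle}}.
#'
#' @param config \code{\link{generatorConfig}}.
#' @param outdir optional output directory.
#' @return list: \code{experiment}, \code{catalog}, \code{pairs},
#'   \code{proteins}, \code{ct}, \code{annotation}, \code{truth}.
#' @export
simulateBundle <- function(config, outdir = NULL) {
  cb <- simulateCounts(config)
  truth <- cb$truth
  dup <- simulateDuplicationCatalog(config, truth)
  prot <- simulateProteins(config, truth)
  ctb <- simulateCtTable(config, truth)
  annb <- simulateAnnotation(config, truth)
  truth$pairs <- dup$pairs
  truth$ncrIds <- prot$ncrIds
  truth$decoyReasons <- prot$decoyReasons
  truth$ctTargets <- ctb$targets
  truth$plantedTerms <- annb$plantedTerms
  bundle <- list(experiment = cb$experiment, catalog = dup$catalog,
                 pairs = dup$pairs, proteins = prot$proteins,
                 ct = ctb$ct, annotation = annb$annotation, truth = truth)
  if (!is.null(outdir)) writeBundle(bundle, outdir)
  bundle
}

#' Simulate block-structured expression profiles
#'
#' Profile-level (already transformed) matrix for clustering and divergence
#' tests: each block of genes follows one latent standard-normal sample
#' factor plus independent Gaussian noise.
#'
#' @param nBlocks number of latent blocks.
#' @param genesPerBlock genes per block.
#' @param nSamples samples.
#' @param noiseSd noise sd around the latent factor (default 0.1).
#' @param nNoiseGenes extra pure-noise genes appended (default 0).
#' @param seed integer seed.
#' @return list: \code{mat} (matrix), \code{blocks} (gene -> block id, 0 for
#'   noise genes), \code{factors} (block x sample latent scores).
#' @export
simulateLatentProfiles <- function(nBlocks, genesPerBlock, nSamples,
                                   noiseSd = 0.1, nNoiseGenes = 0, seed = 1) {
  set.seed(seed)
  fac <- matrix(rnorm(nBlocks * nSamples), nBlocks, nSamples)
  G <- nBlocks * genesPerBlock + nNoiseGenes
  blocks <- c(rep(seq_len(nBlocks), each = genesPerBlock),
              rep(0L, nNoiseGenes))
  mat <- matrix(rnorm(G * nSamples, 0, noiseSd), G, nSamples)
  mat[blocks > 0, ] <- mat[blocks > 0, , drop = FALSE] +
    fac[blocks[blocks > 0], , drop = FALSE]
  if (nNoiseGenes > 0) {
    mat[blocks == 0, ] <- matrix(rnorm(nNoiseGenes * nSamples), nNoiseGenes)
  }
  rownames(mat) <- sprintf("g%05d", seq_len(G))
  colnames(mat) <- sprintf("s%02d", seq_len(nSamples))
  names(blocks) <- rownames(mat)
  list(mat = mat, blocks = blocks, factors = fac)
}
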