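#' @importFrom methods new validObject is setClass setValidity setMethod show slot
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

DUP_MODES <- c("WGD", "TD", "PD", "RD", "DSD", "ND")

#' Configuration for the synthetic nodule-experiment generator
#'
#' Holds every knob of the seeded simulator: experiment layout (genotypes per
#' BNF group, replicates), the negative-binomial count model, planted
#' differential expression, duplication-mode label proportions, duplicate-pair
#' divergence structure, latent co-expression factors, and NCR/decoy protein
#' counts. Defaults emulate the study design the package targets: 2 BNF groups
#' x 4 genotypes x 3 replicates (24 nodule samples), duplication-mode
#' background proportions matching genome-wide expectations for a legume, and
#' a 3:1 up/down split of planted DE genes.
#'
#' @slot nGenes number of genes.
#' @slot nGenotypesPerGroup genotypes per BNF class (half diploid, half
#'   tetraploid when even).
#' @slot nReplicates biological replicates per genotype.
#' @slot deFraction fraction of genes with a planted group effect.
#' @slot deLog2fcRange range of planted |log2 fold change|.
#' @slot deUpFraction fraction of planted DE genes that are up-regulated in
#'   the high-BNF group.
#' @slot nbDispersion baseline NB dispersion; a mild 2/mu trend is added.
#' @slot librarySizeRange range (reads) for log-uniform library sizes.
#' @slot dupModeProportions named 6-vector over WGD/TD/PD/RD/DSD/ND, sums to 1.
#' @slot tandemDeEnrichment odds multiplier pushing DE genes toward TD and DSD.
#' @slot divergedPairFraction fraction of duplicate pairs planted as diverged.
#' @slot nDupPairs number of duplicate pairs to plant.
#' @slot pairNoiseSd log2-scale noise sd around the shared latent profile of
#'   conserved pairs.
#' @slot nLatentFactors number of latent sample factors driving co-expression
#'   modules.
#' @slot latentGeneFraction fraction of genes loaded on latent factors.
#' @slot genotypeEffectSd sd (log2) of genotype-level random effects.
#' @slot ncrCount planted NCR peptides.
#' @slot decoyCount decoy peptides, each violating exactly one criterion.
#' @slot nBackgroundTerms background annotation terms.
#' @slot termBackgroundRate per-gene probability of carrying a background term.
#' @slot plantedTermRate fraction of a latent factor's genes carrying its
#'   planted term.
#' @slot seed integer seed; equal seeds give byte-identical bundles.
#' @export
setClass("GeneratorConfig",
  representation(
    nGenes = "integer", nGenotypesPerGroup = "integer", nReplicates = "integer",
    deFraction = "numeric", deLog2fcRange = "numeric", deUpFraction = "numeric",
    nbDispersion = "numeric", librarySizeRange = "numeric",
    dupModeProportions = "numeric", tandemDeEnrichment = "numeric",
    divergedPairFraction = "numeric", nDupPairs = "integer",
    pairNoiseSd = "numeric", nLatentFactors = "integer",
    latentGeneFraction = "numeric", genotypeEffectSd = "numeric",
    ncrCount = "integer", decoyCount = "integer",
    nBackgroundTerms = "integer", termBackgroundRate = "numeric",
    plantedTermRate = "numeric", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  chkProp <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      msg <<- c(msg, sprintf("%s must be a single proportion in [0,1]", nm))
    }
  }
  chkCount <- function(x, nm, min = 1L) {
    if (length(x) != 1 || is.na(x) || x < min) {
      msg <<- c(msg, sprintf("%s must be a count >= %d", nm, min))
    }
  }
  chkCount(object@nGenes, "nGenes")
  chkCount(object@nGenotypesPerGroup, "nGenotypesPerGroup")
  chkCount(object@nReplicates, "nReplicates")
  chkCount(object@ncrCount, "ncrCount", 0L)
  chkCount(object@decoyCount, "decoyCount", 0L)
  chkCount(object@nDupPairs, "nDupPairs", 0L)
  chkCount(object@nLatentFactors, "nLatentFactors", 0L)
  chkProp(object@deFraction, "deFraction")
  chkProp(object@deUpFraction, "deUpFraction")
  chkProp(object@divergedPairFraction, "divergedPairFraction")
  chkProp(object@latentGeneFraction, "latentGeneFraction")
  chkProp(object@termBackgroundRate, "termBackgroundRate")
  chkProp(object@plantedTermRate, "plantedTermRate")
  p <- object@dupModeProportions
  if (length(p) != 6 || !identical(names(p), DUP_MODES)) {
    msg <- c(msg, "dupModeProportions must be a named 6-vector over WGD,TD,PD,RD,DSD,ND")
  } else {
    if (any(p < 0 | p > 1)) msg <- c(msg, "dupModeProportions entries must lie in [0,1]")
    if (abs(sum(p) - 1) > 1e-12) msg <- c(msg, "dupModeProportions must sum to 1 within 1e-12")
  }
  if (length(object@deLog2fcRange) != 2 || diff(object@deLog2fcRange) < 0 ||
      any(object@deLog2fcRange <= 0)) {
    msg <- c(msg, "deLog2fcRange must be an increasing positive interval")
  }
  if (length(object@librarySizeRange) != 2 || any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0) {
    msg <- c(msg, "librarySizeRange must be an increasing positive interval")
  }
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@tandemDeEnrichment < 1) msg <- c(msg, "tandemDeEnrichment must be >= 1")
  if (object@genotypeEffectSd < 0) msg <- c(msg, "genotypeEffectSd must be non-negative")
  if (length(object@seed) != 1 || is.na(object@seed)) msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneratorConfig-class Constructor with study-condition defaults.
#' @param nGenes,nGenotypesPerGroup,nReplicates,deFraction,deLog2fcRange,deUpFraction,nbDispersion,librarySizeRange,dupModeProportions,tandemDeEnrichment,divergedPairFraction,nDupPairs,pairNoiseSd,nLatentFactors,latentGeneFraction,genotypeEffectSd,ncrCount,decoyCount,nBackgroundTerms,termBackgroundRate,plantedTermRate,seed see slot documentation.
#' @return A validated \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nGenes = 5000, nGenotypesPerGroup = 4, nReplicates = 3,
                            deFraction = 0.02,
                            deLog2fcRange = c(1.2, 3),
                            deUpFraction = 0.75,
                            nbDispersion = 0.05,
                            librarySizeRange = c(5e5, 2e6),
                            dupModeProportions = c(WGD = 0.0403, TD = 0.0991,
                                                   PD = 0.0534, RD = 0.3089,
                                                   DSD = 0.3275, ND = 0.1708),
                            tandemDeEnrichment = 3,
                            divergedPairFraction = 0.5,
                            nDupPairs = 200,
                            pairNoiseSd = 0.1,
                            nLatentFactors = 4,
                            latentGeneFraction = 0.2,
                            genotypeEffectSd = 0.15,
                            ncrCount = 10, decoyCount = 40,
                            nBackgroundTerms = 20,
                            termBackgroundRate = 0.05,
                            plantedTermRate = 0.8,
                            seed = 1) {
  obj <- new("GeneratorConfig",
    nGenes = as.integer(nGenes),
    nGenotypesPerGroup = as.integer(nGenotypesPerGroup),
    nReplicates = as.integer(nReplicates),
    deFraction = deFraction, deLog2fcRange = deLog2fcRange,
    deUpFraction = deUpFraction, nbDispersion = nbDispersion,
    librarySizeRange = librarySizeRange,
    dupModeProportions = dupModeProportions,
    tandemDeEnrichment = tandemDeEnrichment,
    divergedPairFraction = divergedPairFraction,
    nDupPairs = as.integer(nDupPairs), pairNoiseSd = pairNoiseSd,
    nLatentFactors = as.integer(nLatentFactors),
    latentGeneFraction = latentGeneFraction,
    genotypeEffectSd = genotypeEffectSd,
    ncrCount = as.integer(ncrCount), decoyCount = as.integer(decoyCount),
    nBackgroundTerms = as.integer(nBackgroundTerms),
    termBackgroundRate = termBackgroundRate,
    plantedTermRate = plantedTermRate,
    seed = as.integer(seed)
  )
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) stop("invalid generator configuration: ", paste(ok, collapse = "; "))
  obj
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  %d genes; 2 BNF groups x %d genotypes x %d replicates (%d samples)\n",
              object@nGenes, object@nGenotypesPerGroup, object@nReplicates,
              2L * object@nGenotypesPerGroup * object@nReplicates))
  cat(sprintf("  planted DE: %.1f%% of genes, |log2FC| in [%.2f, %.2f], %.0f%% up\n",
              100 * object@deFraction, object@deLog2fcRange[1],
              object@deLog2fcRange[2], 100 * object@deUpFraction))
  cat(sprintf("  %d duplicate pairs (%.0f%% diverged); %d latent factors; seed %d\n",
              object@nDupPairs, 100 * object@divergedPairFraction,
              object@nLatentFactors, object@seed))
})

#' Container for a nodule RNA-seq experiment
#'
#' A thin extension of \linkS4class{SummarizedExperiment}: the \code{"counts"}
#' assay holds non-negative integer read counts (genes x samples) and
#' \code{colData} carries the sample sheet (genotype, replicate, BNF class,
#' ploidy, fresh mass, ethylene concentration from the acetylene reduction
#' assay). Size factors, once estimated, live in \code{colData$sizeFactor}.
#'
#' @export
setClass("NoduleExperiment", contains = "SummarizedExperiment")

setValidity("NoduleExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts))) {
    msg <- c(msg, "counts must be finite non-negative integers")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (!"bnf_class" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain bnf_class")
  } else if (anyNA(SummarizedExperiment::colData(object)$bnf_class)) {
    msg <- c(msg, "bnf_class must be non-missing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NoduleExperiment-class Construct from a count matrix and a
#'   sample table (rows matched to count columns by \code{sample_id}).
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param sampleData data.frame with a \code{sample_id} column covering every
#'   count column, plus at least \code{bnf_class}.
#' @return A \code{NoduleExperiment}.
#' @export
NoduleExperiment <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  sampleData <- as.data.frame(sampleData)
  if (!"sample_id" %in% colnames(sampleData)) stop("sampleData needs a sample_id column")
  if (!all(colnames(counts) %in% sampleData$sample_id)) {
    stop("every count column must appear in sampleData$sample_id")
  }
  sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), , drop = FALSE]
  rownames(sampleData) <- sampleData$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleData)
  )
  obj <- new("NoduleExperiment", se)
  validObject(obj)
  obj
}

setMethod("show", "NoduleExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("NoduleExperiment: %d genes x %d samples\n", nrow(object), ncol(object)))
  if ("bnf_class" %in% colnames(cd)) {
    tb <- table(cd$bnf_class)
    cat("  BNF classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat("  size factors:",
      if ("sizeFactor" %in% colnames(cd)) "estimated" else "not estimated", "\n")
})

#' Cysteine-spacing grammar for NCR-like peptides
#'
#' NCR (nodule-specific cysteine-rich) peptides carry 4 or 6 conserved
#' cysteines in the mature peptide with characteristic spacings. The grammar
#' stores, for each cysteine count, the allowed (min, max) residue gaps
#' between consecutive cysteines. The default is the package's documented
#' stand-in grammar: 4C = C-X(4..12)-C-X(8..30)-C-X(3..12)-C and 6C inserts
#' two further cysteines at X(1..12) gaps:
#' C-X(4..12)-C-X(1..12)-C-X(8..30)-C-X(1..12)-C-X(3..12)-C.
#'
#' @slot spacing4 3 x 2 matrix of (min, max) gaps for the 4-cysteine form.
#' @slot spacing6 5 x 2 matrix of (min, max) gaps for the 6-cysteine form.
#' @export
setClass("CysteinePattern",
         representation(spacing4 = "matrix", spacing6 = "matrix"))

setValidity("CysteinePattern", function(object) {
  msg <- character()
  chk <- function(m, n, nm) {
    if (!is.numeric(m) || ncol(m) != 2 || nrow(m) != n) {
      msg <<- c(msg, sprintf("%s must be a %d x 2 numeric matrix", nm, n))
    } else if (any(m <= 0) || any(m[, 1] > m[, 2])) {
      msg <<- c(msg, sprintf("%s bounds must be positive with min <= max", nm))
    }
  }
  chk(object@spacing4, 3L, "spacing4")
  chk(object@spacing6, 5L, "spacing6")
  if (length(msg)) msg else TRUE
})

#' @describeIn CysteinePattern-class Constructor; defaults give the package's
#'   documented default grammar.
#' @param spacing4,spacing6 gap-bound matrices, see slots.
#' @return A validated \code{CysteinePattern}.
#' @export
cysteinePattern <- function(spacing4 = cbind(c(4, 8, 3), c(12, 30, 12)),
                            spacing6 = cbind(c(4, 1, 8, 1, 3), c(12, 12, 30, 12, 12))) {
  obj <- new("CysteinePattern", spacing4 = spacing4, spacing6 = spacing6)
  validObject(obj)
  obj
}

setMethod("show", "CysteinePattern", function(object) {
  fmt <- function(m) paste0("C", paste(sprintf("-X(%d..%d)-C", m[, 1], m[, 2]), collapse = ""))
  cat("CysteinePattern\n  4C:", fmt(object@spacing4), "\n  6C:", fmt(object@spacing6), "\n")
})
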