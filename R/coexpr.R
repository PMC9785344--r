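#' @importFrom stats cutree cor.test phyper
NULL

# WGCNA-style module color sequence (largest module first)
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue", "darkred",
                   "darkgreen", "darkturquoise", "darkgrey", "orange",
                   "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Transform counts and filter genes for network construction
#'
#' Applies the package's log-based stabilizing transform
#' \code{log2(count / sizeFactor + 1)} and keeps genes whose transformed
#' value reaches \code{threshold} in at least \code{minSamples} samples.
#'
#' @param object \code{NoduleExperiment} or count matrix.
#' @param sf size factors (estimated when omitted).
#' @param threshold transformed-value threshold (default 10).
#' @param minSamples minimum number of samples at or above it (default 3,
#'   boundary inclusive).
#' @return transformed, filtered matrix (genes x samples).
#' @export
transformAndFilter <- function(object, sf = NULL, threshold = 10, minSamples = 3) {
  if (is(object, "NoduleExperiment")) {
    if (is.null(sf)) {
      if (is.null(sizeFactors(object))) object <- computeSizeFactors(object)
      sf <- sizeFactors(object)
    }
    object <- counts(object)
  }
  tm <- logNormalizedCounts(object, sf)
  keep <- rowSums(tm >= threshold) >= minSamples
  if (!any(keep)) stop("no gene passes the expression filter")
  tm[keep, , drop = FALSE]
}

#' Signed-hybrid adjacency
#'
#' a_ij = cor(i, j)^beta when the correlation is positive, 0 otherwise
#' (negative co-expression carries no edge weight); the diagonal is 1.
#' Constant gene profiles get zero adjacency to every other gene, with a
#' warning.
#'
#' @param mat expression matrix (genes x samples), >= 3 samples.
#' @param beta soft-threshold power (default 6).
#' @return symmetric adjacency matrix in [0, 1].
#' @export
adjacencySignedHybrid <- function(mat, beta = 6) {
  if (ncol(mat) < 3) stop("need at least 3 samples")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene profile(s); adjacency set to 0")
  }
  r <- suppressWarnings(cor(t(mat)))
  r[!is.finite(r)] <- 0
  a <- ifelse(r > 0, r^beta, 0)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i = sum_{u != i} a_iu, applied to a non-negative adjacency; the
#' diagonal is set to 1. The corresponding dissimilarity is 1 - TOM.
#'
#' @param adjacency symmetric matrix in [0, 1] with unit diagonal.
#' @return TOM matrix.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  tom[!is.finite(tom)] <- 0
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of genes on the TOM dissimilarity
#' 1 - TOM, followed by: a static tree cut at the \code{cutQuantile}
#' quantile of merge heights, a size floor sending clusters smaller than
#' \code{minModuleSize} to the unassigned "grey" module, and iterative
#' merging of modules whose eigengene dissimilarity 1 - cor(ME_a, ME_b)
#' falls below \code{mergeCutHeight} (0 disables merging). Modules are
#' labeled by decreasing size with the conventional color sequence.
#'
#' @param tom TOM matrix from \code{\link{topologicalOverlap}}.
#' @param exprMat the transformed expression matrix (needed for eigengene
#'   merging), same gene order as \code{tom}.
#' @param minModuleSize minimum module size (default 20).
#' @param mergeCutHeight eigengene-dissimilarity merge threshold
#'   (default 0.45).
#' @param cutQuantile static-cut quantile of merge heights (default 0.99).
#' @return named character vector gene -> module color ("grey" = unassigned).
#' @export
detectModules <- function(tom, exprMat, minModuleSize = 20,
                          mergeCutHeight = 0.45, cutQuantile = 0.99) {
  stopifnot(nrow(tom) == nrow(exprMat))
  genes <- rownames(exprMat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(exprMat)))
  d <- 1 - tom
  if (max(d) - min(d[upper.tri(d)]) < 1e-12) {
    warning("degenerate TOM (all dissimilarities equal); single module")
    labels <- rep(1L, nrow(tom))
  } else {
    hc <- hclust(as.dist(d), method = "average")
    h <- unname(quantile(hc$height, cutQuantile, type = 7))
    labels <- cutree(hc, h = h)
  }
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < minModuleSize])
  labels[labels %in% small] <- 0L
  if (all(labels == 0L)) {
    out <- rep("grey", length(labels)); names(out) <- genes
    return(out)
  }
  # iterative eigengene merging
  if (mergeCutHeight > 0) {
    repeat {
      ids <- sort(unique(labels[labels != 0L]))
      if (length(ids) < 2) break
      asg <- structure(paste0("m", labels), names = genes)
      asg[labels == 0L] <- "grey"
      me <- moduleEigengenes(exprMat, asg)$eigengenes
      me <- me[paste0("m", ids), , drop = FALSE]
      cm <- cor(t(me))
      diss <- 1 - cm
      diag(diss) <- Inf
      if (min(diss) >= mergeCutHeight) break
      ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
      keep <- ids[min(ij)]; drop <- ids[max(ij)]
      labels[labels == drop] <- keep
    }
  }
  ids <- sort(unique(labels[labels != 0L]))
  ord <- ids[order(-vapply(ids, function(i) sum(labels == i), numeric(1)))]
  colorOf <- function(k) {
    if (k <= length(MODULE_COLORS)) MODULE_COLORS[k] else paste0("module", k)
  }
  out <- rep("grey", length(labels))
  for (k in seq_along(ord)) out[labels == ord[k]] <- colorOf(k)
  names(out) <- genes
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' gene-standardized module submatrix: a unit-norm per-sample profile
#' summarizing the module. Its sign is oriented so it correlates positively
#' with the module's mean standardized expression profile. The fraction of
#' variance explained by the first component is reported per module.
#'
#' @param exprMat transformed expression matrix (genes x samples).
#' @param assignment named gene -> module vector; "grey" is skipped.
#' @return list: \code{eigengenes} (module x sample matrix, unit rows),
#'   \code{varianceExplained} (named vector).
#' @export
moduleEigengenes <- function(exprMat, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  if (!length(mods)) stop("no non-grey module")
  eg <- matrix(NA_real_, length(mods), ncol(exprMat),
               dimnames = list(mods, colnames(exprMat)))
  ve <- structure(numeric(length(mods)), names = mods)
  for (m in mods) {
    sub <- exprMat[names(assignment)[assignment == m], , drop = FALSE]
    if (nrow(sub) < 2) stop("module '", m, "' has fewer than 2 genes")
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) stop("module '", m, "' consists of constant genes")
    sub <- sub[sds > 0, , drop = FALSE]
    z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (cor(v, colMeans(z)) < 0) v <- -v
    eg[m, ] <- v
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, varianceExplained = ve)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation and two-sided p-value per module x trait; binary
#' traits must be coded 0/1 beforehand (see \code{\link{traitMatrix}}).
#' Constant traits yield missing correlations.
#'
#' @param eigengenes module x sample matrix.
#' @param traits sample x trait numeric data.frame/matrix (rows matched to
#'   eigengene columns by name when available).
#' @param flagAlpha significance threshold (default 0.01).
#' @return data.frame: \code{module}, \code{trait}, \code{r}, \code{p},
#'   \code{significant}.
#' @export
moduleTraitCorrelation <- function(eigengenes, traits, flagAlpha = 0.01) {
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) && !is.null(colnames(eigengenes))) {
    traits <- traits[colnames(eigengenes), , drop = FALSE]
  }
  if (ncol(eigengenes) < 3) stop("need at least 3 samples")
  rows <- list()
  for (m in rownames(eigengenes)) {
    for (tr in colnames(traits)) {
      x <- eigengenes[m, ]; y <- traits[, tr]
      if (stats::sd(y) == 0 || stats::sd(x) == 0) {
        rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                               r = NA_real_, p = NA_real_,
                                               significant = NA)
        next
      }
      ct <- cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                             r = unname(ct$estimate),
                                             p = ct$p.value,
                                             significant = ct$p.value < flagAlpha)
    }
  }
  do.call(rbind, rows)
}

#' Numeric trait matrix from sample metadata
#'
#' Codes the study traits for module-trait correlation: \code{bnf} (high =
#' 1, low = 0), \code{ploidy} (4n = 1, 2n = 0), \code{ethylene},
#' \code{fresh_mass}, plus one-hot genotype indicators.
#'
#' @param sampleData data.frame with the metadata columns.
#' @return numeric matrix, samples x traits.
#' @export
traitMatrix <- function(sampleData) {
  sd <- as.data.frame(sampleData)
  out <- data.frame(row.names = sd$sample_id)
  if ("bnf_class" %in% colnames(sd)) out$bnf <- as.numeric(sd$bnf_class == "high")
  if ("ploidy" %in% colnames(sd)) out$ploidy <- as.numeric(sd$ploidy == "4n")
  if ("ethylene" %in% colnames(sd)) out$ethylene <- sd$ethylene
  if ("fresh_mass" %in% colnames(sd)) out$fresh_mass <- sd$fresh_mass
  if ("genotype" %in% colnames(sd)) {
    for (g in unique(sd$genotype)) {
      out[[paste0("genotype_", g)]] <- as.numeric(sd$genotype == g)
    }
  }
  as.matrix(out)
}

#' Hypergeometric term enrichment per module
#'
#' For each annotation term with at least one universe gene: k = term genes
#' in the module, K = term genes in the universe, n = module size, N =
#' universe size; upper-tail hypergeometric p = P[X >= k]; BH adjustment
#' across terms within the module; enriched when FDR < \code{fdrThreshold}.
#' Terms with no gene in the universe are skipped with a warning.
#'
#' @param moduleGenes character vector (subset of \code{universe}).
#' @param annotation data.frame \code{gene_id}, \code{term_id}.
#' @param universe character vector of all tested genes.
#' @param fdrThreshold enrichment FDR threshold (default 0.05).
#' @return data.frame: \code{term_id}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p}, \code{fdr}, \code{enriched}, sorted by p.
#' @export
hypergeometricEnrichment <- function(moduleGenes, annotation, universe,
                                     fdrThreshold = 0.05) {
  if (!all(moduleGenes %in% universe)) stop("moduleGenes must be a subset of universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  dropped <- setdiff(unique(annotation$term_id), unique(ann$term_id))
  if (length(dropped)) {
    warning(length(dropped), " term(s) with no universe gene skipped")
  }
  if (!nrow(ann)) return(data.frame(term_id = character(0), k = integer(0),
                                    K = integer(0), n = integer(0),
                                    N = integer(0), p = numeric(0),
                                    fdr = numeric(0), enriched = logical(0)))
  N <- length(unique(universe))
  n <- length(unique(moduleGenes))
  byTerm <- split(ann$gene_id, ann$term_id)
  rows <- lapply(names(byTerm), function(tm) {
    termGenes <- unique(byTerm[[tm]])
    K <- length(termGenes)
    k <- length(intersect(termGenes, moduleGenes))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr < fdrThreshold
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Export the co-expression network edge list
#'
#' Writes gene pairs whose adjacency reaches \code{threshold} (a free
#' parameter: note that adjacency values live in [0, 1], so thresholds above
#' 1 select nothing).
#'
#' @param adjacency adjacency matrix.
#' @param threshold minimum adjacency for an edge (default 0.1).
#' @return data.frame \code{gene1}, \code{gene2}, \code{adjacency}.
#' @export
adjacencyEdgeList <- function(adjacency, threshold = 0.1) {
  idx <- which(upper.tri(adjacency) & adjacency >= threshold, arr.ind = TRUE)
  g <- rownames(adjacency)
  if (is.null(g)) g <- paste0("g", seq_len(nrow(adjacency)))
  data.frame(gene1 = g[idx[, 1]], gene2 = g[idx[, 2]],
             adjacency = adjacency[idx], stringsAsFactors = FALSE)
}
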