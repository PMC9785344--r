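#' @importFrom BiocGenerics counts sizeFactors sizeFactors<-
#' @importFrom stats median prcomp cor hclust as.dist var
NULL

#' @describeIn NoduleExperiment-class Raw count matrix accessor.
#' @param object a \code{NoduleExperiment}.
#' @export
setMethod("counts", "NoduleExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @describeIn NoduleExperiment-class Per-sample size factors (or NULL).
#' @export
setMethod("sizeFactors", "NoduleExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"sizeFactor" %in% colnames(cd)) return(NULL)
  structure(cd$sizeFactor, names = colnames(object))
})

#' @describeIn NoduleExperiment-class Set size factors.
#' @param value positive numeric vector, one per sample.
#' @export
setMethod("sizeFactors<-", "NoduleExperiment", function(object, value) {
  stopifnot(length(value) == ncol(object), all(value > 0))
  SummarizedExperiment::colData(object)$sizeFactor <- as.numeric(value)
  object
})

#' Median-of-ratios size factors
#'
#' Sequencing-depth normalization: for each sample j the size factor is the
#' median over reference genes of \code{count[i,j] / geomean_i}, where
#' \code{geomean_i} is the geometric mean of gene i across samples and the
#' reference set is the genes whose geometric mean is positive (i.e. genes
#' with no zero count). Factors are rescaled to unit geometric mean so that
#' normalized totals stay on the scale of the input library sizes.
#'
#' @param object a count matrix (genes x samples) or a
#'   \code{\linkS4class{NoduleExperiment}}.
#' @return For a matrix, a named positive vector of size factors with unit
#'   geometric mean; for a \code{NoduleExperiment}, the object with
#'   \code{sizeFactors(object)} filled in.
#' @examples
#' m <- cbind(A = c(10L, 20L, 30L), B = c(20L, 40L, 60L))
#' rownames(m) <- paste0("g", 1:3)
#' computeSizeFactors(m) # B twice A
#' @export
setGeneric("computeSizeFactors", function(object) standardGeneric("computeSizeFactors"))

#' @rdname computeSizeFactors
#' @export
setMethod("computeSizeFactors", "matrix", function(object) {
  if (any(object < 0)) stop("counts must be non-negative")
  logGeo <- rowMeans(log(object))
  use <- is.finite(logGeo)
  if (!any(use)) {
    stop("degenerate input: no gene has all-positive counts; ",
         "consider a pseudo-reference fallback (e.g. adding a pseudocount ",
         "or restricting to positive genes) before normalization")
  }
  lr <- log(object[use, , drop = FALSE]) - logGeo[use]
  sf <- exp(apply(lr, 2, median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(object)
  sf
})

#' @rdname computeSizeFactors
#' @export
setMethod("computeSizeFactors", "NoduleExperiment", function(object) {
  sf <- computeSizeFactors(counts(object))
  sizeFactors(object) <- sf
  object
})

#' Normalized and log-normalized counts
#'
#' \code{normalizedCounts} divides each sample column by its size factor;
#' \code{logNormalizedCounts} returns \code{log2(normalized + 1)}, the
#' transform used for replicate QC and expression-profile correlations.
#'
#' @param counts count matrix or \code{NoduleExperiment}.
#' @param sf size factors; taken from the object when omitted.
#' @return numeric matrix of the same shape.
#' @export
normalizedCounts <- function(counts, sf = NULL) {
  if (is(counts, "NoduleExperiment")) {
    if (is.null(sf)) sf <- sizeFactors(counts)
    counts <- BiocGenerics::counts(counts)
  }
  if (is.null(sf)) sf <- computeSizeFactors(counts)
  sweep(counts, 2, sf, "/")
}

#' @rdname normalizedCounts
#' @export
logNormalizedCounts <- function(counts, sf = NULL) {
  log2(normalizedCounts(counts, sf) + 1)
}

#' Replicate quality control
#'
#' Computes the pairwise Pearson correlation matrix of samples on
#' \code{log2(normalized + 1)} counts, hierarchical clustering with distance
#' \code{d = 1 - r} under complete linkage, and a PCA of the samples on the
#' centered, gene-standardized matrix. Constant sample columns yield missing
#' (NA) correlations for their pairs, reported with a warning rather than
#' silently coerced; such samples are dropped from the dendrogram.
#'
#' @param object \code{NoduleExperiment} (size factors estimated if missing)
#'   or a raw count matrix.
#' @param sf optional size factors when \code{object} is a matrix.
#' @return A list of class \code{"QCReport"}: \code{correlation} (r matrix),
#'   \code{dendrogram} (an \code{hclust} object on d = 1 - r, complete
#'   linkage), \code{pca} (data.frame of PC1/PC2 sample coordinates) and
#'   \code{pcaVarianceExplained}.
#' @export
replicateQC <- function(object, sf = NULL) {
  if (is(object, "NoduleExperiment")) {
    if (is.null(sizeFactors(object))) object <- computeSizeFactors(object)
    lm2 <- logNormalizedCounts(counts(object), sizeFactors(object))
  } else {
    lm2 <- logNormalizedCounts(object, sf)
  }
  if (ncol(lm2) < 3) stop("replicate QC needs at least 3 samples")
  sds <- apply(lm2, 2, stats::sd)
  r <- suppressWarnings(cor(lm2))
  diag(r) <- 1
  if (any(sds == 0)) {
    warning("constant sample column(s): ",
            paste(colnames(lm2)[sds == 0], collapse = ", "),
            "; correlations reported as missing")
  }
  ok <- sds > 0
  hc <- NULL
  if (sum(ok) >= 2) {
    d <- as.dist(1 - r[ok, ok, drop = FALSE])
    hc <- hclust(d, method = "complete")
  }
  geneSd <- apply(lm2, 1, stats::sd)
  zz <- lm2[geneSd > 0, , drop = FALSE]
  zz <- (zz - rowMeans(zz)) / apply(zz, 1, stats::sd)
  pc <- prcomp(t(zz), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(sample_id = colnames(lm2),
                       PC1 = pc$x[, 1],
                       PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                       row.names = NULL)
  structure(list(correlation = r, dendrogram = hc, pca = coords,
                 pcaVarianceExplained = ve[seq_len(min(2, length(ve)))]),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d samples; min pairwise r = %.3f\n",
              ncol(x$correlation), min(x$correlation, na.rm = TRUE)))
  cat(sprintf("  PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
              100 * x$pcaVarianceExplained[1],
              100 * ifelse(length(x$pcaVarianceExplained) > 1,
                           x$pcaVarianceExplained[2], 0)))
  invisible(x)
}
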