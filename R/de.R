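#' @importFrom stats pt pnorm p.adjust lm.fit quantile
NULL

# Method-of-moments NB dispersion per gene, shrunk 50% toward a parametric
# a0 + a1/mu trend fitted by least squares across genes. Pooled within-group
# variance of normalized counts estimates s^2 ~ xi*mu + alpha*mu^2 with
# xi = mean(1/sf) accounting for the shot-noise term after normalization.
estimateDispersions_ <- function(y, sf, group) {
  z <- sweep(y, 2, sf, "/")
  lv <- levels(group)
  idx0 <- group == lv[1]; idx1 <- group == lv[2]
  n0 <- sum(idx0); n1 <- sum(idx1)
  m0 <- rowMeans(z[, idx0, drop = FALSE]); m1 <- rowMeans(z[, idx1, drop = FALSE])
  v0 <- rowVars_(z[, idx0, drop = FALSE]); v1 <- rowVars_(z[, idx1, drop = FALSE])
  s2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  xi <- mean(1 / sf)
  mgrp <- (m0 + m1) / 2
  aMom <- pmin(pmax((s2 - xi * mgrp) / mgrp^2, 1e-8), 10)
  mu <- rowMeans(z)
  ok <- mu > 0 & is.finite(aMom)
  co <- tryCatch(lm.fit(cbind(1, 1 / mu[ok]), aMom[ok])$coefficients,
                 error = function(e) c(mean(aMom[ok]), 0))
  a0 <- max(co[1], 1e-8); a1 <- max(co[2], 0)
  aTrend <- a0 + a1 / mu
  pmin(pmax(0.5 * aMom + 0.5 * aTrend, 1e-8), 10)
}

rowVars_ <- function(m) {
  nc <- ncol(m)
  if (nc < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (nc - 1)
}

# Vectorized IRLS for the per-gene NB GLM log mu = b0 + b1*x + log sf with
# known dispersion. The design is shared across genes, so each update solves
# the same 2x2 normal equations from row sums.
nbGlmFit_ <- function(y, sf, x, alpha, maxit = 50, tol = 1e-10) {
  G <- nrow(y); n <- ncol(y)
  ls <- matrix(log(sf), G, n, byrow = TRUE)
  i1 <- x == 1
  eps <- 0.5 / max(sf)
  z <- sweep(y, 2, sf, "/")
  m0 <- rowMeans(z[, !i1, drop = FALSE]); m1 <- rowMeans(z[, i1, drop = FALSE])
  b0 <- log(pmax(m0, eps)); b1 <- log(pmax(m1, eps)) - b0
  Sw <- S1 <- NULL
  for (it in seq_len(maxit)) {
    eta <- b0 + outer(b1, as.numeric(i1)) + ls
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    wz <- w * ((eta - ls) + (y - mu) / mu)
    Sw <- rowSums(w); S1 <- rowSums(w[, i1, drop = FALSE]); S0 <- Sw - S1
    bb1 <- rowSums(wz); bb2 <- rowSums(wz[, i1, drop = FALSE])
    nb0 <- (bb1 - bb2) / S0
    nb1 <- (Sw * bb2 - S1 * bb1) / (S1 * S0)
    delta <- max(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    if (!is.finite(delta) || delta < tol) break
  }
  se <- sqrt(Sw / (S1 * (Sw - S1)))
  list(b0 = b0, b1 = b1, se = se)
}

#' Differential expression between BNF classes (NB Wald test)
#'
#' Tests each gene for differential expression between the high- and low-BNF
#' sample groups with a negative-binomial Wald test: per-gene dispersion is
#' estimated by method of moments and shrunk 50\% toward a parametric
#' a0 + a1/mu mean-dispersion trend; group log fold change and its standard
#' error come from an IRLS fit of the NB GLM with size-factor offsets; the
#' Wald statistic is referred to a t distribution with n - 2 degrees of
#' freedom to account for the estimated dispersion at small sample sizes.
#' The low-BNF class is the reference, so positive log2 fold changes mean
#' higher expression in high-BNF samples.
#'
#' Genes whose raw mean count across all samples is below
#' \code{lowCountMean} are not tested (status \code{"low_count"}, p absent)
#' and are excluded from the Benjamini-Hochberg adjustment. A gene is called
#' differentially expressed (\code{"de_up"} / \code{"de_down"}) when
#' \code{|log2fc| > lfcThreshold} and \code{padj < alpha}.
#'
#' @param object \code{\linkS4class{NoduleExperiment}} with a two-level
#'   \code{bnf_class}; size factors are estimated when absent.
#' @param lfcThreshold log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lowCountMean raw-mean threshold below which genes are flagged
#'   \code{low_count} (default 2).
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{base_mean} (mean normalized count), \code{log2fc}, \code{se},
#'   \code{p}, \code{padj}, \code{status}.
#' @export
testDifferentialExpression <- function(object, lfcThreshold = 1, alpha = 0.05,
                                       lowCountMean = 2) {
  stopifnot(is(object, "NoduleExperiment"))
  if (is.null(sizeFactors(object))) object <- computeSizeFactors(object)
  y <- counts(object)
  sf <- sizeFactors(object)
  grp <- as.character(SummarizedExperiment::colData(object)$bnf_class)
  if (!all(grp %in% c("high", "low"))) stop("bnf_class must be 'high'/'low'")
  group <- factor(grp, levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2 || any(table(group) < 2)) {
    stop("design error: both bnf_class levels must be present with >= 2 samples")
  }
  baseMean <- rowMeans(sweep(y, 2, sf, "/"))
  rawMean <- rowMeans(y)
  low <- rawMean < lowCountMean
  res <- data.frame(gene_id = rownames(y), base_mean = baseMean,
                    log2fc = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, status = "low_count",
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!low)) {
    yt <- y[!low, , drop = FALSE]
    disp <- estimateDispersions_(yt, sf, group)
    fit <- nbGlmFit_(yt, sf, as.integer(group) - 1L, disp)
    df <- ncol(y) - 2L
    p <- 2 * pt(-abs(fit$b1 / fit$se), df = df)
    padj <- p.adjust(p, method = "BH")
    l2 <- fit$b1 / log(2)
    status <- ifelse(abs(l2) > lfcThreshold & padj < alpha,
                     ifelse(l2 > 0, "de_up", "de_down"), "not_de")
    res$log2fc[!low] <- l2
    res$se[!low] <- fit$se / log(2)
    res$p[!low] <- p
    res$padj[!low] <- padj
    res$status[!low] <- status
  }
  res
}
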