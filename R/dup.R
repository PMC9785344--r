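#' @importFrom stats dhyper pchisq
NULL

#' Duplication-mode distribution of a gene set
#'
#' Counts genes of a set per duplication mode (WGD, tandem, proximal,
#' transposed, dispersed, non-duplicated). Genes absent from the catalog are
#' reported separately as unclassified and excluded from the proportions.
#'
#' @param geneSet character vector of gene ids (non-empty).
#' @param catalog data.frame with columns \code{gene_id}, \code{mode}.
#' @return list: \code{counts} (named 6-vector), \code{proportions}
#'   (over classified genes), \code{nClassified}, \code{nUnclassified},
#'   \code{unclassified} (the ids).
#' @export
tabulateModeDistribution <- function(geneSet, catalog) {
  stopifnot(length(geneSet) > 0)
  geneSet <- unique(as.character(geneSet))
  modes <- catalog$mode[match(geneSet, catalog$gene_id)]
  uncl <- geneSet[is.na(modes)]
  cl <- modes[!is.na(modes)]
  if (!length(cl)) stop("gene set has empty intersection with the catalog")
  cnt <- table(factor(cl, levels = DUP_MODES))
  cnt <- structure(as.integer(cnt), names = DUP_MODES)
  list(counts = cnt, proportions = cnt / sum(cnt),
       nClassified = sum(cnt), nUnclassified = length(uncl),
       unclassified = uncl)
}

#' Global goodness-of-fit of DEG mode distribution against the background
#'
#' Pearson chi-squared goodness-of-fit: observed per-mode DEG counts against
#' expected counts n * background proportions, df = modes - 1.
#'
#' @param degCounts named vector of observed counts per mode.
#' @param backgroundProportions proportions summing to 1 (same order).
#' @return list: \code{statistic}, \code{df}, \code{p}, \code{expected}.
#' @export
testGlobalDistribution <- function(degCounts, backgroundProportions) {
  stopifnot(length(degCounts) == length(backgroundProportions))
  p <- backgroundProportions / sum(backgroundProportions)
  expected <- sum(degCounts) * p
  if (any(expected <= 0)) {
    stop("zero expected cell(s); pool categories before testing")
  }
  stat <- sum((degCounts - expected)^2 / expected)
  df <- length(degCounts) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

# Two-tailed Fisher exact p for a 2x2 table by summing hypergeometric
# probabilities <= observed (with the conventional 1 + 1e-7 tie slack).
fisherExact2x2_ <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  min(1, p)
}

#' Per-mode enrichment of DEGs over the background (Fisher exact test)
#'
#' For one duplication mode, forms the 2x2 table (DEG in mode, DEG not in
#' mode; background in mode, background not in mode) and computes the
#' two-tailed Fisher exact p by summing hypergeometric probabilities no
#' larger than the observed table's, plus the odds ratio (with a Haldane
#' 0.5 correction when a zero cell occurs).
#'
#' @param degInMode,degTotal DEG counts (in the mode, total).
#' @param bgInMode,bgTotal background counts. Per the package's default
#'   convention the background is all expressed classified genes including
#'   the DEGs.
#' @return list: \code{p}, \code{oddsRatio}, \code{table}.
#' @export
testModeEnrichment <- function(degInMode, degTotal, bgInMode, bgTotal) {
  a <- degInMode; b <- degTotal - degInMode
  c <- bgInMode; d <- bgTotal - bgInMode
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative and totals >= in-mode counts")
  p <- fisherExact2x2_(a, b, c, d)
  if (any(c(a, b, c, d) == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(p = p, oddsRatio = or,
       table = matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("DEG", "background"),
                                      c("in_mode", "not_in_mode"))))
}

#' Duplication-mode enrichment table (DEGs vs expressed background)
#'
#' Combines \code{\link{tabulateModeDistribution}},
#' \code{\link{testGlobalDistribution}} and \code{\link{testModeEnrichment}}
#' into the per-mode report: counts and proportions for the DEG set and the
#' expressed background, per-mode odds ratios with two-tailed Fisher exact
#' p-values, and the global chi-squared goodness-of-fit test.
#'
#' @param degIds,backgroundIds gene id vectors; by default the background
#'   is used as-is (it may include the DEGs); set
#'   \code{excludeDegFromBackground = TRUE} to remove them.
#' @param catalog data.frame \code{gene_id}, \code{mode}.
#' @param excludeDegFromBackground logical (default FALSE).
#' @return list of class \code{"ModeEnrichment"}: \code{table} (data.frame
#'   mode, deg_count, deg_pct, bg_count, bg_pct, odds_ratio, p),
#'   \code{global} (chi-squared test), \code{deg}, \code{background}
#'   (tabulations).
#' @export
modeEnrichment <- function(degIds, backgroundIds, catalog,
                           excludeDegFromBackground = FALSE) {
  if (excludeDegFromBackground) backgroundIds <- setdiff(backgroundIds, degIds)
  deg <- tabulateModeDistribution(degIds, catalog)
  bg <- tabulateModeDistribution(backgroundIds, catalog)
  global <- testGlobalDistribution(deg$counts, bg$proportions)
  per <- lapply(DUP_MODES, function(m) {
    testModeEnrichment(deg$counts[[m]], deg$nClassified,
                       bg$counts[[m]], bg$nClassified)
  })
  tab <- data.frame(mode = DUP_MODES,
                    deg_count = as.integer(deg$counts),
                    deg_pct = 100 * as.numeric(deg$proportions),
                    bg_count = as.integer(bg$counts),
                    bg_pct = 100 * as.numeric(bg$proportions),
                    odds_ratio = vapply(per, `[[`, numeric(1), "oddsRatio"),
                    p = vapply(per, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, global = global, deg = deg, background = bg),
            class = "ModeEnrichment")
}

#' @export
print.ModeEnrichment <- function(x, ...) {
  cat(sprintf("Duplication-mode enrichment: chi-squared = %.3f, df = %d, p = %.3g\n",
              x$global$statistic, x$global$df, x$global$p))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Null cutoff for expression-profile correlation
#'
#' Draws \code{nPairs} unordered distinct gene pairs uniformly at random
#' from the expression matrix, computes the Pearson correlation of each
#' pair's profiles, and returns the empirical \code{level} quantile
#' (inclusive/type-7 convention) as the divergence cutoff: pairs correlated
#' below it are no more similar than random gene pairs at the corresponding
#' alpha. Constant-profile genes are skipped (their count is reported).
#' When fewer than \code{nPairs} distinct pairs exist, all pairs are used
#' exhaustively with a warning.
#'
#' @param expression numeric matrix of expression profiles (genes x samples,
#'   typically \code{log2(normalized + 1)}).
#' @param nPairs number of random pairs (default 10000).
#' @param level quantile level (default 0.95).
#' @param seed integer seed making the draw reproducible.
#' @return list of class \code{"NullCutoff"}: \code{cutoff}, \code{level},
#'   \code{samples} (the r values), \code{nSkippedConstant}, \code{seed}.
#' @export
nullCorrelationCutoff <- function(expression, nPairs = 10000, level = 0.95,
                                  seed = 1) {
  stopifnot(ncol(expression) >= 2)
  sds <- apply(expression, 1, stats::sd)
  keep <- which(sds > 0)
  nSkip <- nrow(expression) - length(keep)
  if (length(keep) < 2) stop("need at least 2 genes with nonconstant profiles")
  G <- length(keep)
  nAll <- G * (G - 1) / 2
  set.seed(seed)
  if (nAll <= nPairs) {
    warning(sprintf("only %d distinct pairs available; using all of them", nAll))
    idx <- utils::combn(G, 2)
    i1 <- idx[1, ]; i2 <- idx[2, ]
  } else {
    # uniform unordered pairs without replacement: oversample, canonicalize,
    # de-duplicate, repeat until nPairs distinct pairs are collected
    keys <- numeric(0)
    while (length(keys) < nPairs) {
      a <- sample.int(G, 2 * (nPairs - length(keys)) + 10, replace = TRUE)
      b <- sample.int(G, length(a), replace = TRUE)
      ok2 <- a != b
      lo <- pmin(a[ok2], b[ok2]); hi <- pmax(a[ok2], b[ok2])
      keys <- unique(c(keys, (lo - 1) * G + hi))
    }
    keys <- keys[seq_len(nPairs)]
    i1 <- (keys - 1) %/% G + 1
    i2 <- keys - (i1 - 1) * G
  }
  ex <- expression[keep, , drop = FALSE]
  r <- vapply(seq_along(i1),
              function(k) cor(ex[i1[k], ], ex[i2[k], ]), numeric(1))
  cutoff <- unname(quantile(r, level, type = 7))
  structure(list(cutoff = cutoff, level = level, samples = r,
                 nSkippedConstant = nSkip, seed = seed),
            class = "NullCutoff")
}

#' @export
print.NullCutoff <- function(x, ...) {
  cat(sprintf("NullCutoff: r* = %.4f (%.0f%% quantile of %d sampled pairs)\n",
              x$cutoff, 100 * x$level, length(x$samples)))
  invisible(x)
}

#' Classify expression divergence of duplicate pairs
#'
#' A duplicate pair has diverged in expression when the Pearson correlation
#' of its members' profiles falls below the resampled null cutoff; pairs at
#' or above the cutoff are expression-conserved. Following the study design,
#' when a DE table is supplied only pairs with at least one differentially
#' expressed member are classified (others get \code{divergence = "not_assessed"}).
#' Pairs with a constant-profile member are \code{"undefined"}; pairs with a
#' member missing from the matrix are skipped with a warning.
#'
#' @param pairs data.frame with columns \code{gene1}, \code{gene2} and
#'   optionally \code{mode}.
#' @param expression profile matrix (genes x samples), same transform as the
#'   one used for the null cutoff.
#' @param cutoff \code{\link{nullCorrelationCutoff}} result (or a number).
#' @param deResults optional DE table restricting classification to pairs
#'   with >= 1 DE member.
#' @return list of class \code{"PairDivergence"}: \code{pairs} (with
#'   \code{r} and \code{divergence} columns), \code{divergedFractionByMode}
#'   (over defined classified pairs; NA when a mode has none).
#' @export
classifyPairDivergence <- function(pairs, expression, cutoff, deResults = NULL) {
  rStar <- if (is.list(cutoff)) cutoff$cutoff else cutoff
  pairs <- as.data.frame(pairs)
  present <- pairs$gene1 %in% rownames(expression) &
    pairs$gene2 %in% rownames(expression)
  if (any(!present)) {
    warning(sum(!present), " pair(s) skipped: member missing from matrix")
  }
  out <- pairs[present, , drop = FALSE]
  sds1 <- apply(expression[out$gene1, , drop = FALSE], 1, stats::sd)
  sds2 <- apply(expression[out$gene2, , drop = FALSE], 1, stats::sd)
  r <- rep(NA_real_, nrow(out))
  ok <- sds1 > 0 & sds2 > 0
  r[ok] <- vapply(which(ok), function(k) {
    cor(expression[out$gene1[k], ], expression[out$gene2[k], ])
  }, numeric(1))
  out$r <- r
  classify <- rep(TRUE, nrow(out))
  if (!is.null(deResults)) {
    deIds <- deResults$gene_id[deResults$status %in% c("de_up", "de_down")]
    classify <- out$gene1 %in% deIds | out$gene2 %in% deIds
  }
  out$divergence <- ifelse(!classify, "not_assessed",
                           ifelse(is.na(r), "undefined",
                                  ifelse(r < rStar, "diverged", "conserved")))
  frac <- NULL
  if ("mode" %in% colnames(out)) {
    frac <- vapply(split(out$divergence, out$mode), function(v) {
      def <- v[v %in% c("diverged", "conserved")]
      if (!length(def)) NA_real_ else mean(def == "diverged")
    }, numeric(1))
  }
  structure(list(pairs = out, divergedFractionByMode = frac, cutoff = rStar),
            class = "PairDivergence")
}

#' @export
print.PairDivergence <- function(x, ...) {
  tb <- table(x$pairs$divergence)
  cat(sprintf("PairDivergence (cutoff r* = %.4f): %s\n", x$cutoff,
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
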