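#' @importFrom stats wilcox.test lm aggregate coef
NULL

#' Rank genes by length-normalized expression
#'
#' Score = mean raw reads across samples divided by gene length (bp),
#' correcting the comparison of expression strength across genes of
#' different lengths. Genes are returned in descending score order with ties
#' broken by gene id.
#'
#' @param counts count matrix or \code{NoduleExperiment}.
#' @param lengths named numeric vector of positive gene lengths (bp); must
#'   cover every gene in \code{counts}.
#' @return data.frame \code{gene_id}, \code{mean_reads}, \code{length_bp},
#'   \code{score}, sorted by decreasing score.
#' @export
rankByLengthNormalized <- function(counts, lengths) {
  if (is(counts, "NoduleExperiment")) counts <- BiocGenerics::counts(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("missing length for expressed gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  mr <- rowMeans(counts)
  out <- data.frame(gene_id = rownames(counts), mean_reads = mr,
                    length_bp = as.numeric(len), score = mr / len,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$score, out$gene_id), , drop = FALSE]
}

#' Genes in a reference annotation lacking supporting evidence
#'
#' Returns the sorted set difference \code{reference \ evidence}: genes
#' present in the reference annotation but absent from the evidence-backed
#' annotation, i.e. genes still experimentally unconfirmed.
#'
#' @param referenceIds,evidenceIds character vectors of gene ids.
#' @return sorted character vector.
#' @export
flagUnconfirmedGenes <- function(referenceIds, evidenceIds) {
  sort(setdiff(unique(as.character(referenceIds)), as.character(evidenceIds)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Averages replicate Ct measurements per (sample, gene), normalizes each
#' target gene to the reference gene within a sample (dCt = Ct_target -
#' Ct_reference), then to the calibrator sample (ddCt = dCt_sample -
#' dCt_calibrator), and reports fold = 2^-ddCt. The calibrator's fold is
#' exactly 1 for every gene.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene}, \code{ct};
#'   repeated (sample, gene) rows are treated as replicates and averaged.
#' @param referenceGene id of the reference (housekeeping) gene; must be
#'   measured in every sample.
#' @param calibratorSample id of the calibrator sample.
#' @return data.frame \code{sample}, \code{gene}, \code{ct}, \code{dct},
#'   \code{ddct}, \code{fold} for target genes.
#' @export
relativeExpressionDDCt <- function(ct, referenceGene, calibratorSample) {
  stopifnot(all(c("sample", "gene", "ct") %in% colnames(ct)))
  if (!calibratorSample %in% ct$sample) stop("calibrator sample not in table")
  m <- aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  ref <- m[m$gene == referenceGene, ]
  if (!all(unique(m$sample) %in% ref$sample)) {
    stop("reference gene '", referenceGene, "' missing Ct in some sample(s)")
  }
  tgt <- m[m$gene != referenceGene, , drop = FALSE]
  tgt$dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
  cal <- tgt[tgt$sample == calibratorSample, ]
  tgt$ddct <- tgt$dct - cal$dct[match(tgt$gene, cal$gene)]
  tgt$fold <- 2^(-tgt$ddct)
  tgt[order(tgt$gene, tgt$sample), , drop = FALSE]
}

#' Phenotype comparison between BNF groups
#'
#' Compares the nitrogen-fixation proxy (ethylene concentration from the
#' acetylene reduction assay) between high- and low-BNF groups with a
#' one-tailed Mann-Whitney U (rank-sum) test (alternative: high > low), fits
#' per-ploidy ordinary least-squares regressions of fresh mass on ethylene,
#' and reports distribution summaries (median and quartiles) per group. The
#' test is exact when both groups have at most 12 observations and no ties
#' occur; otherwise a midrank normal approximation is used.
#'
#' @param traits data.frame with columns \code{bnf_class}, \code{ethylene}
#'   and optionally \code{ploidy}, \code{fresh_mass}, \code{genotype}. When a
#'   \code{genotype} column is present, rows are collapsed to one observation
#'   per genotype (replicates share the plant-level measurement).
#' @return list of class \code{"PhenotypeComparison"}: \code{p} (one-tailed
#'   rank-sum p), \code{statistic} (U), \code{summaries}, and
#'   \code{regressions} (per-ploidy slope, intercept, r.squared) when mass
#'   and ploidy are available.
#' @export
comparePhenotypeGroups <- function(traits) {
  traits <- as.data.frame(traits)
  stopifnot(all(c("bnf_class", "ethylene") %in% colnames(traits)))
  if ("genotype" %in% colnames(traits)) {
    traits <- traits[!duplicated(traits$genotype), , drop = FALSE]
  }
  hi <- traits$ethylene[traits$bnf_class == "high"]
  lo <- traits$ethylene[traits$bnf_class == "low"]
  if (length(hi) < 2 || length(lo) < 2) {
    stop("each BNF group needs at least 2 observations")
  }
  ties <- anyDuplicated(c(hi, lo)) > 0
  exact <- !ties && max(length(hi), length(lo)) <= 12
  wt <- suppressWarnings(
    wilcox.test(hi, lo, alternative = "greater", exact = exact, correct = FALSE)
  )
  qs <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75))
    data.frame(q25 = q[1], median = q[2], q75 = q[3], n = length(x), row.names = NULL)
  }
  summaries <- rbind(cbind(group = "high", qs(hi)), cbind(group = "low", qs(lo)))
  regressions <- NULL
  if (all(c("fresh_mass", "ploidy") %in% colnames(traits))) {
    regressions <- do.call(rbind, lapply(split(traits, traits$ploidy), function(d) {
      if (nrow(d) < 3) return(NULL)
      f <- lm(fresh_mass ~ ethylene, data = d)
      data.frame(ploidy = d$ploidy[1], intercept = coef(f)[1],
                 slope = coef(f)[2], r.squared = summary(f)$r.squared,
                 n = nrow(d), row.names = NULL)
    }))
  }
  structure(list(p = wt$p.value, statistic = unname(wt$statistic),
                 exact = exact, summaries = summaries,
                 regressions = regressions),
            class = "PhenotypeComparison")
}

#' @export
print.PhenotypeComparison <- function(x, ...) {
  cat(sprintf("One-tailed rank-sum test (high > low): U = %g, p = %.3g (%s)\n",
              x$statistic, x$p, if (x$exact) "exact" else "normal approximation"))
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$regressions)) {
    cat("Fresh mass ~ ethylene, per ploidy:\n")
    print(x$regressions, row.names = FALSE)
  }
  invisible(x)
}
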