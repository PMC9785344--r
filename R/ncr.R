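#' @importFrom stats uniroot
NULL

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2, X = 0)

# average monoisotopic-free amino-acid masses (Da)
AA_AVG_MASS <- c(A = 89.0935, R = 174.2017, N = 132.1184, D = 133.1032,
                 C = 121.1590, E = 147.1293, Q = 146.1451, G = 75.0669,
                 H = 155.1552, I = 131.1736, L = 131.1736, K = 146.1882,
                 M = 149.2124, F = 165.1900, P = 115.1310, S = 105.0930,
                 T = 119.1197, W = 204.2262, Y = 181.1894, V = 117.1469,
                 X = 128.16)

# EMBOSS-style pKa values for the Henderson-Hasselbalch net-charge model
PKA_TABLE <- list(
  Nterm = 8.6, Cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

AA20 <- names(KD_HYDROPATHY)[1:20]

splitResidues_ <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

#' Heuristic signal-peptide detection
#'
#' A documented hydropathy heuristic standing in for dedicated predictors:
#' a signal peptide is called present when the first 30 residues contain a
#' window of 7 consecutive residues with mean Kyte-Doolittle hydropathy
#' >= 1.6 (the hydrophobic h-region). The cleavage position is the first
#' small residue (A, G, S, C or T) after that window within residues 15-35
#' (1-based; the mature peptide starts at the next residue); when no small
#' residue is found there, the window end + 5 is used.
#'
#' @param sequence single amino-acid string (>= 20 residues for a call).
#' @param minWindowMean mean-hydropathy threshold (default 1.6).
#' @return list: \code{present} (logical), \code{cleavage} (last residue of
#'   the signal peptide, NA when absent), \code{reason}.
#' @export
detectSignalPeptide <- function(sequence, minWindowMean = 1.6) {
  aa <- splitResidues_(sequence)
  n <- length(aa)
  if (n < 20) {
    return(list(present = FALSE, cleavage = NA_integer_, reason = "too short"))
  }
  head30 <- aa[seq_len(min(30, n))]
  h <- KD_HYDROPATHY[head30]
  h[is.na(h)] <- 0
  win <- NA_integer_
  if (length(h) >= 7) {
    means <- vapply(seq_len(length(h) - 6),
                    function(i) mean(h[i:(i + 6)]), numeric(1))
    hit <- which(means >= minWindowMean)
    if (length(hit)) win <- hit[1]
  }
  if (is.na(win)) {
    return(list(present = FALSE, cleavage = NA_integer_,
                reason = "no hydrophobic stretch"))
  }
  winEnd <- win + 6L
  lo <- max(15L, winEnd + 1L); hi <- min(35L, n)
  cleavage <- NA_integer_
  if (lo <= hi) {
    cand <- which(aa[lo:hi] %in% c("A", "G", "S", "C", "T"))
    if (length(cand)) cleavage <- lo + cand[1] - 1L
  }
  if (is.na(cleavage)) cleavage <- winEnd + 5L
  list(present = TRUE, cleavage = as.integer(min(cleavage, n)), reason = "ok")
}

netCharge_ <- function(aaCounts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_TABLE$Nterm))
  for (a in names(PKA_TABLE$positive)) {
    k <- aaCounts[a]; if (is.na(k)) k <- 0
    pos <- pos + k / (1 + 10^(pH - PKA_TABLE$positive[[a]]))
  }
  neg <- 1 / (1 + 10^(PKA_TABLE$Cterm - pH))
  for (a in names(PKA_TABLE$negative)) {
    k <- aaCounts[a]; if (is.na(k)) k <- 0
    neg <- neg + k / (1 + 10^(PKA_TABLE$negative[[a]] - pH))
  }
  unname(pos - neg)
}

#' Physicochemical parameters of a peptide
#'
#' Molecular weight (sum of free-residue average masses minus (n-1) waters),
#' isoelectric point (bisection on the Henderson-Hasselbalch net charge with
#' the package's documented pKa table), net charge at pH 7, and GRAVY (mean
#' Kyte-Doolittle hydropathy). Sequences containing X are flagged
#' approximate (X contributes an average residue mass, zero hydropathy, and
#' no ionizable group).
#'
#' @param sequence amino-acid string.
#' @return list: \code{mw} (Da), \code{pi}, \code{netCharge} (at pH 7),
#'   \code{gravy}, \code{approximate} (logical).
#' @examples
#' computePhysicochemical("G")$mw   # 75.07
#' computePhysicochemical("II")$gravy  # 4.5
#' @export
computePhysicochemical <- function(sequence) {
  aa <- splitResidues_(sequence)
  bad <- setdiff(unique(aa), c(AA20, "X"))
  if (length(bad)) stop("illegal residues: ", paste(bad, collapse = ", "))
  n <- length(aa)
  if (n == 0) stop("empty sequence")
  counts <- table(factor(aa, levels = c(AA20, "X")))
  mw <- sum(AA_AVG_MASS[names(counts)] * as.numeric(counts)) - (n - 1) * 18.01528
  f <- function(pH) netCharge_(counts, pH)
  pi <- uniroot(f, c(0, 14), tol = 1e-9)$root
  list(mw = mw, pi = pi, netCharge = f(7), gravy = mean(KD_HYDROPATHY[aa]),
       approximate = "X" %in% aa)
}

matchCysteinePattern_ <- function(cysGaps, bounds) {
  nrow(bounds) == length(cysGaps) &&
    all(cysGaps >= bounds[, 1] & cysGaps <= bounds[, 2])
}

#' Scan protein sequences for NCR-peptide candidates
#'
#' Each input sequence receives one candidate record with an explicit
#' verdict. A sequence is structurally NCR-like when its mature region (the
#' part after the predicted signal-peptide cleavage site, or the whole
#' sequence when no signal peptide is called) contains exactly 4 or 6
#' cysteines whose consecutive gaps all fall within the grammar's spacing
#' bounds. Confirmation further requires total (preprotein) length below
#' \code{maxLength} residues and a present signal peptide. Criteria are
#' checked in a fixed order and the first violated one is recorded as the
#' exclusion reason: parse, cysteine count, spacing, length, signal peptide.
#'
#' When \code{external} supplies per-sequence evidence columns (e.g.
#' \code{signal_peptide}, \code{localization}, \code{blast_hit}), a supplied
#' \code{signal_peptide} value overrides the heuristic verbatim, and
#' structurally passing candidates whose external evidence is missing or
#' unsupportive are downgraded to \code{"unconfirmed"}.
#'
#' @param proteins \code{Biostrings::AAStringSet} or named character vector.
#' @param pattern \code{\linkS4class{CysteinePattern}} grammar.
#' @param maxLength maximum preprotein length in residues (default 150,
#'   exclusive).
#' @param external optional data.frame keyed by \code{seq_id} with columns
#'   among \code{signal_peptide} ("present"/"absent"), \code{localization},
#'   \code{blast_hit}.
#' @return data.frame, one row per input: \code{seq_id}, \code{length},
#'   \code{n_cys_mature}, \code{cys_positions} (0-based, comma-separated),
#'   \code{matched_pattern} (4C/6C/none), \code{signal_peptide},
#'   \code{cleavage}, \code{region} (mature/full), \code{mw}, \code{pi},
#'   \code{net_charge}, \code{gravy}, \code{verdict}, \code{reason}.
#' @export
scanNcrCandidates <- function(proteins, pattern = cysteinePattern(),
                              maxLength = 150, external = NULL) {
  nms <- names(proteins)
  seqs <- as.character(proteins)
  names(seqs) <- if (is.null(nms)) paste0("seq", seq_along(seqs)) else nms
  ext <- NULL
  if (!is.null(external)) {
    external <- as.data.frame(external)
    stopifnot("seq_id" %in% colnames(external))
    ext <- external[match(names(seqs), external$seq_id), , drop = FALSE]
  }
  rows <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    s <- toupper(seqs[[i]])
    aa <- splitResidues_(s)
    n <- length(aa)
    rec <- data.frame(seq_id = id, length = n, n_cys_mature = NA_integer_,
                      cys_positions = "", matched_pattern = "none",
                      signal_peptide = "absent", cleavage = NA_integer_,
                      region = "full", mw = NA_real_, pi = NA_real_,
                      net_charge = NA_real_, gravy = NA_real_,
                      verdict = "excluded", reason = "",
                      stringsAsFactors = FALSE)
    if (n == 0 || length(setdiff(unique(aa), c(AA20, "X")))) {
      warning("sequence '", id, "' empty or contains non-IUPAC characters; excluded")
      rec$reason <- "parse error"
      return(rec)
    }
    pc <- computePhysicochemical(s)
    rec$mw <- pc$mw; rec$pi <- pc$pi
    rec$net_charge <- pc$netCharge; rec$gravy <- pc$gravy
    sigOverride <- NULL
    if (!is.null(ext) && "signal_peptide" %in% colnames(ext) &&
        !is.na(ext$signal_peptide[i])) {
      sigOverride <- as.character(ext$signal_peptide[i])
    }
    if (!is.null(sigOverride)) {
      sig <- list(present = identical(sigOverride, "present"),
                  cleavage = if (identical(sigOverride, "present")) {
                    sp <- detectSignalPeptide(s)
                    if (sig_ok <- !is.na(sp$cleavage)) sp$cleavage else 20L
                  } else NA_integer_,
                  reason = "external override")
    } else {
      sig <- detectSignalPeptide(s)
    }
    rec$signal_peptide <- if (sig$present) "present" else "absent"
    rec$cleavage <- sig$cleavage
    if (sig$present && !is.na(sig$cleavage) && sig$cleavage < n) {
      matureStart <- sig$cleavage + 1L
      rec$region <- "mature"
    } else {
      matureStart <- 1L
      rec$region <- "full"
    }
    mature <- aa[matureStart:n]
    cysIdx <- which(mature == "C") + matureStart - 1L  # full-sequence 1-based
    rec$n_cys_mature <- length(cysIdx)
    rec$cys_positions <- paste(cysIdx - 1L, collapse = ",")  # 0-based
    gaps <- if (length(cysIdx) >= 2) diff(cysIdx) - 1L else integer(0)
    matched <- "none"
    if (length(cysIdx) == 4 && matchCysteinePattern_(gaps, pattern@spacing4)) {
      matched <- "4C"
    } else if (length(cysIdx) == 6 && matchCysteinePattern_(gaps, pattern@spacing6)) {
      matched <- "6C"
    }
    rec$matched_pattern <- matched
    # ordered adjudication
    if (!length(cysIdx) %in% c(4, 6)) {
      rec$reason <- "cysteine count"
    } else if (matched == "none") {
      rec$reason <- "spacing"
    } else if (n >= maxLength) {
      rec$reason <- "length"
    } else if (!sig$present) {
      rec$reason <- if (identical(sig$reason, "too short")) "too short" else "signal peptide"
    } else {
      rec$verdict <- "confirmed"
      rec$reason <- "structure, length and signal peptide criteria met"
      if (!is.null(ext)) {
        supp <- TRUE
        if ("localization" %in% colnames(ext)) {
          loc <- ext$localization[i]
          supp <- supp && !is.na(loc) && grepl("extracellular", loc, ignore.case = TRUE)
        }
        if ("blast_hit" %in% colnames(ext)) {
          supp <- supp && !is.na(ext$blast_hit[i]) && nzchar(ext$blast_hit[i])
        }
        if (!supp) {
          rec$verdict <- "unconfirmed"
          rec$reason <- "external evidence missing or unsupportive"
        }
      }
    }
    rec
  })
  do.call(rbind, rows)
}

#' Adjudicate NCR candidates against differential-expression results
#'
#' Joins candidate records with DE status by gene id and reports summary
#' counts. Candidates whose gene was flagged \code{low_count} are marked
#' "omitted from the DEG analysis". Without a DE table the verdicts are
#' returned unchanged and no DE columns are added.
#'
#' @param candidates output of \code{\link{scanNcrCandidates}}.
#' @param deResults optional \code{\link{testDifferentialExpression}} table.
#' @return list: \code{candidates} (possibly with \code{log2fc},
#'   \code{padj}, \code{de_status}, \code{de_note} columns),
#'   \code{summary} (counts per verdict), and, with a DE table,
#'   \code{confirmedDe} (ids both confirmed and differentially expressed).
#' @export
adjudicateNcr <- function(candidates, deResults = NULL) {
  out <- candidates
  summary <- as.list(table(factor(out$verdict,
                                  levels = c("confirmed", "unconfirmed", "excluded"))))
  confirmedDe <- NULL
  if (!is.null(deResults)) {
    idx <- match(out$seq_id, deResults$gene_id)
    if (anyNA(idx)) {
      warning("candidate id(s) absent from DE table: ",
              paste(out$seq_id[is.na(idx)], collapse = ", "))
    }
    out$log2fc <- deResults$log2fc[idx]
    out$padj <- deResults$padj[idx]
    out$de_status <- deResults$status[idx]
    out$de_note <- ifelse(!is.na(out$de_status) & out$de_status == "low_count",
                          "omitted from the DEG analysis", "")
    confirmedDe <- out$seq_id[out$verdict == "confirmed" &
                                !is.na(out$de_status) &
                                out$de_status %in% c("de_up", "de_down")]
    summary$confirmed_de <- length(confirmedDe)
  }
  list(candidates = out, summary = summary, confirmedDe = confirmedDe)
}
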