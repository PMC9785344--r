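#' @importFrom utils read.delim write.table head
NULL

writeTsv_ <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header with \code{gene_id} followed by one integer column per
#' sample.
#'
#' @param path TSV file.
#' @return integer matrix with gene/sample dimnames.
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read a sample metadata TSV
#'
#' @param path TSV with at least \code{sample_id} and \code{bnf_class}.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a synthetic experiment bundle
#'
#' \code{writeBundle} writes counts.tsv, samples.tsv, proteins.fasta
#' (60-column wrap), dup_catalog.tsv, dup_pairs.tsv, annotation.tsv, ct.tsv
#' and truth.json under \code{outdir}. \code{readBundle} reads them back
#' into the in-memory bundle layout (the expected-mean matrix, which is
#' derivable only from the generator, is not part of the sidecar).
#'
#' @param bundle result of \code{\link{simulateBundle}}.
#' @param outdir output directory (created if needed).
#' @return \code{writeBundle}: the directory, invisibly; \code{readBundle}:
#'   a bundle list.
#' @export
writeBundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cts <- counts(bundle$experiment)
  writeTsv_(data.frame(gene_id = rownames(cts), cts, check.names = FALSE),
            file.path(outdir, "counts.tsv"))
  writeTsv_(as.data.frame(SummarizedExperiment::colData(bundle$experiment)),
            file.path(outdir, "samples.tsv"))
  if (!is.null(bundle$proteins)) {
    Biostrings::writeXStringSet(bundle$proteins,
                                file.path(outdir, "proteins.fasta"), width = 60)
  }
  if (!is.null(bundle$catalog)) {
    writeTsv_(bundle$catalog, file.path(outdir, "dup_catalog.tsv"))
  }
  if (!is.null(bundle$pairs)) {
    writeTsv_(bundle$pairs, file.path(outdir, "dup_pairs.tsv"))
  }
  if (!is.null(bundle$annotation)) {
    writeTsv_(bundle$annotation, file.path(outdir, "annotation.tsv"))
  }
  if (!is.null(bundle$ct)) {
    writeTsv_(bundle$ct, file.path(outdir, "ct.tsv"))
  }
  truth <- bundle$truth
  truth$log2Mu <- NULL
  truth$geneIds <- NULL
  # jsonlite drops names on atomic vectors; keep them via lists
  for (nm in c("deGenes", "trueModules", "decoyReasons", "plantedTerms")) {
    if (!is.null(truth[[nm]])) truth[[nm]] <- as.list(truth[[nm]])
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @rdname writeBundle
#' @param dir directory written by \code{writeBundle}.
#' @export
readBundle <- function(dir) {
  cts <- readCounts(file.path(dir, "counts.tsv"))
  meta <- readSampleMetadata(file.path(dir, "samples.tsv"))
  nex <- NoduleExperiment(cts, meta)
  out <- list(experiment = nex)
  fp <- function(f) file.path(dir, f)
  if (file.exists(fp("proteins.fasta"))) {
    out$proteins <- Biostrings::readAAStringSet(fp("proteins.fasta"))
  }
  if (file.exists(fp("dup_catalog.tsv"))) out$catalog <- read.delim(fp("dup_catalog.tsv"))
  if (file.exists(fp("dup_pairs.tsv"))) out$pairs <- read.delim(fp("dup_pairs.tsv"))
  if (file.exists(fp("annotation.tsv"))) out$annotation <- read.delim(fp("annotation.tsv"))
  if (file.exists(fp("ct.tsv"))) out$ct <- read.delim(fp("ct.tsv"))
  if (file.exists(fp("truth.json"))) {
    tr <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
    for (nm in c("deGenes", "trueModules", "decoyReasons", "plantedTerms")) {
      if (is.list(tr[[nm]])) tr[[nm]] <- unlist(tr[[nm]])
    }
    tr$geneIds <- rownames(cts)
    out$truth <- tr
  }
  out
}
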