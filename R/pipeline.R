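#' Default pipeline configuration
#'
#' Stage toggles, input paths and per-stage parameters with the study's
#' thresholds as defaults: DE |log2FC| > 1 at BH-adjusted p < 0.05 with the
#' low-count rule (raw mean < 2); NCR maximum length 150 residues; 10,000
#' random pairs at the 95\% level for the divergence null; soft power 6,
#' minimum module size 20 and eigengene merge height 0.45 for module
#' detection; enrichment FDR 0.05 and module-trait p < 0.01.
#'
#' @param outdir output directory.
#' @param seed top-level seed; every stage derives its own stream from it.
#' @param ... overrides for any default element (partial lists are merged).
#' @return nested list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outdir = "pipeline_out", seed = 1, ...) {
  cfg <- list(
    outdir = outdir,
    seed = seed,
    stages = list(simulate = TRUE, de = TRUE, ncr = TRUE,
                  dupDiverge = TRUE, modules = TRUE, enrich = TRUE),
    inputs = list(counts = NULL, samples = NULL, proteins = NULL,
                  catalog = NULL, pairs = NULL, annotation = NULL, ct = NULL),
    simulate = list(),
    de = list(lfcThreshold = 1, alpha = 0.05, lowCountMean = 2),
    ncr = list(maxLength = 150),
    dupDiverge = list(nPairs = 10000, level = 0.95),
    modules = list(beta = 6, minModuleSize = 20, mergeCutHeight = 0.45,
                   filterThreshold = 10, filterMinSamples = 3, traitAlpha = 0.01),
    enrich = list(fdrThreshold = 0.05)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror
#'   \code{\link{pipelineConfig}}.
#' @return \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

hashFile_ <- function(path) unname(tools::md5sum(path))

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order -- simulate (optional),
#' differential expression, NCR scan, duplication/divergence, co-expression
#' modules, enrichment -- writing each stage's outputs before the next
#' starts and logging stage-tagged lines to stderr. Inputs either come from
#' the simulate stage or from the paths in \code{config$inputs}. A failing
#' stage halts the run with an error naming the stage.
#'
#' @param config \code{\link{pipelineConfig}} result (or a YAML path).
#' @return run report (list, also written as report.json): per-stage input
#'   file hashes, parameters, output row counts, and warnings.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  log_ <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  runStage <- function(stage, fn) {
    log_(stage, "start")
    warns <- character(0)
    out <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    out$warnings <- warns
    report$stages[[stage]] <<- out
    log_(stage, "done")
    out
  }
  requireInput_ <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop(sprintf("%s: file not found (%s)", key,
                   if (is.null(p)) "no path configured" else p), call. = FALSE)
    }
    p
  }

  bundle <- NULL
  if (isTRUE(config$stages$simulate)) {
    runStage("simulate", function() {
      gc <- do.call(generatorConfig,
                    c(config$simulate, list(seed = deriveSeed(config$seed, "simulate"))))
      bdir <- file.path(outdir, "bundle")
      bundle <<- simulateBundle(gc, bdir)
      list(params = config$simulate,
           outputs = list(bundle = bdir),
           rows = list(genes = nrow(bundle$experiment),
                       samples = ncol(bundle$experiment)))
    })
    config$inputs <- list(counts = file.path(outdir, "bundle", "counts.tsv"),
                          samples = file.path(outdir, "bundle", "samples.tsv"),
                          proteins = file.path(outdir, "bundle", "proteins.fasta"),
                          catalog = file.path(outdir, "bundle", "dup_catalog.tsv"),
                          pairs = file.path(outdir, "bundle", "dup_pairs.tsv"),
                          annotation = file.path(outdir, "bundle", "annotation.tsv"),
                          ct = file.path(outdir, "bundle", "ct.tsv"))
  }

  nex <- de <- NULL
  needExpr <- any(unlist(config$stages[c("de", "dupDiverge", "modules", "enrich")]))
  if (needExpr) {
    cf <- requireInput_("counts"); sfp <- requireInput_("samples")
    nex <- NoduleExperiment(readCounts(cf), readSampleMetadata(sfp))
    nex <- computeSizeFactors(nex)
  }

  if (isTRUE(config$stages$de)) {
    de <- runStage("de", function() {
      p <- config$de
      tab <- testDifferentialExpression(nex, p$lfcThreshold, p$alpha, p$lowCountMean)
      qc <- replicateQC(nex)
      writeTsv_(tab, file.path(outdir, "de_results.tsv"))
      jsonlite::write_json(
        list(correlation = qc$correlation,
             pca = qc$pca, pcaVarianceExplained = qc$pcaVarianceExplained),
        file.path(outdir, "qc_report.json"), digits = NA)
      list(params = p,
           inputHashes = list(counts = hashFile_(cf), samples = hashFile_(sfp)),
           outputs = list(de_results = file.path(outdir, "de_results.tsv")),
           rows = list(genes = nrow(tab),
                       de = sum(tab$status %in% c("de_up", "de_down"))),
           table = tab)
    })$table
  }

  if (isTRUE(config$stages$ncr)) {
    runStage("ncr", function() {
      pf <- requireInput_("proteins")
      prot <- Biostrings::readAAStringSet(pf)
      cand <- scanNcrCandidates(prot, maxLength = config$ncr$maxLength)
      adj <- adjudicateNcr(cand, de)
      writeTsv_(adj$candidates, file.path(outdir, "ncr_candidates.tsv"))
      jsonlite::write_json(adj$summary, file.path(outdir, "ncr_report.json"),
                           auto_unbox = TRUE, digits = NA)
      list(params = config$ncr, inputHashes = list(proteins = hashFile_(pf)),
           rows = list(candidates = nrow(cand),
                       confirmed = sum(cand$verdict == "confirmed")))
    })
  }

  lm2 <- NULL
  if (isTRUE(config$stages$dupDiverge)) {
    runStage("dupDiverge", function() {
      cf2 <- requireInput_("catalog"); pf2 <- requireInput_("pairs")
      catalog <- read.delim(cf2, stringsAsFactors = FALSE)
      prs <- read.delim(pf2, stringsAsFactors = FALSE)
      lm2 <<- logNormalizedCounts(counts(nex), sizeFactors(nex))
      degIds <- if (!is.null(de)) de$gene_id[de$status %in% c("de_up", "de_down")] else character(0)
      me <- NULL
      if (length(degIds)) {
        me <- modeEnrichment(degIds, rownames(nex), catalog)
        writeTsv_(me$table, file.path(outdir, "mode_enrichment.tsv"))
      }
      nc <- nullCorrelationCutoff(lm2, nPairs = config$dupDiverge$nPairs,
                                  level = config$dupDiverge$level,
                                  seed = deriveSeed(config$seed, "null_cutoff"))
      pd <- classifyPairDivergence(prs, lm2, nc, deResults = de)
      writeTsv_(pd$pairs, file.path(outdir, "pair_divergence.tsv"))
      jsonlite::write_json(list(cutoff = nc$cutoff, level = nc$level,
                                nPairs = length(nc$samples), seed = nc$seed,
                                rSummary = unclass(summary(nc$samples))),
                           file.path(outdir, "null_cutoff.json"),
                           auto_unbox = TRUE, digits = NA)
      list(params = config$dupDiverge,
           inputHashes = list(catalog = hashFile_(cf2), pairs = hashFile_(pf2)),
           rows = list(pairs = nrow(pd$pairs)),
           cutoff = nc$cutoff,
           globalP = if (!is.null(me)) me$global$p else NA_real_)
    })
  }

  assignment <- filtered <- NULL
  if (isTRUE(config$stages$modules)) {
    runStage("modules", function() {
      p <- config$modules
      filtered <<- transformAndFilter(nex, threshold = p$filterThreshold,
                                      minSamples = p$filterMinSamples)
      adj <- adjacencySignedHybrid(filtered, beta = p$beta)
      tom <- topologicalOverlap(adj)
      assignment <<- detectModules(tom, filtered, minModuleSize = p$minModuleSize,
                                   mergeCutHeight = p$mergeCutHeight)
      writeTsv_(data.frame(gene_id = names(assignment), module = assignment),
                file.path(outdir, "modules.tsv"))
      me <- moduleEigengenes(filtered, assignment)
      writeTsv_(data.frame(module = rownames(me$eigengenes), me$eigengenes,
                           check.names = FALSE),
                file.path(outdir, "eigengenes.tsv"))
      traits <- traitMatrix(as.data.frame(SummarizedExperiment::colData(nex)))
      mt <- moduleTraitCorrelation(me$eigengenes, traits, flagAlpha = p$traitAlpha)
      writeTsv_(mt, file.path(outdir, "module_trait.tsv"))
      sizes <- table(assignment)
      jsonlite::write_json(
        list(nModules = length(setdiff(unique(assignment), "grey")),
             sizes = as.list(sizes),
             varianceExplained = as.list(me$varianceExplained)),
        file.path(outdir, "module_summary.json"), auto_unbox = TRUE, digits = NA)
      list(params = p,
           rows = list(filteredGenes = nrow(filtered),
                       modules = length(setdiff(unique(assignment), "grey"))))
    })
  }

  if (isTRUE(config$stages$enrich)) {
    runStage("enrich", function() {
      af <- requireInput_("annotation")
      ann <- read.delim(af, stringsAsFactors = FALSE)
      if (is.null(assignment)) stop("modules stage must run before enrichment")
      universe <- names(assignment)
      res <- do.call(rbind, lapply(setdiff(unique(assignment), "grey"), function(m) {
        r <- hypergeometricEnrichment(names(assignment)[assignment == m],
                                      ann, universe,
                                      fdrThreshold = config$enrich$fdrThreshold)
        if (nrow(r)) cbind(module = m, r) else NULL
      }))
      writeTsv_(res, file.path(outdir, "enrichment.tsv"))
      list(params = config$enrich, inputHashes = list(annotation = hashFile_(af)),
           rows = list(tests = if (is.null(res)) 0L else nrow(res),
                       enriched = if (is.null(res)) 0L else sum(res$enriched)))
    })
  }

  for (nm in names(report$stages)) report$stages[[nm]]$table <- NULL
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
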