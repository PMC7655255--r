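#' Pipeline configuration
#'
#' Builds and validates the configuration for
#' \code{\link{runFullPipeline}}. Either \code{expressionPath} +
#' \code{clinicalPath} point at the TSV inputs, or \code{synthetic} is a
#' list of \code{\link{simulateCohort}} arguments. Defaults follow the
#' standard analysis settings: screening at Wald P < 0.001, signatures of
#' at most 3 genes, 1000 resamples of 50\%, coexpression cut at PCC > 0.6
#' with P < 0.01.
#'
#' @param expressionPath,clinicalPath input TSVs (see
#'   \code{\link{readExpression}}, \code{\link{readClinical}}).
#' @param alreadyLog passed to \code{\link{readExpression}}.
#' @param synthetic list of \code{\link{simulateCohort}} arguments (used
#'   when no input paths are given).
#' @param trainFraction,screenPThreshold,maxSignatureSize,workers
#'   stage parameters.
#' @param resampleRepetitions,resampleFraction comparison-stage
#'   parameters.
#' @param pccThreshold,pccPThreshold coexpression-stage parameters.
#' @param minNonzeroFraction prevalence-filter parameter.
#' @param compareModelsPath optional TSV of competing models (see
#'   \code{\link{readModelFile}}).
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @param outputDir where reports are written.
#' @return a validated config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(expressionPath = NULL, clinicalPath = NULL,
                           alreadyLog = FALSE, synthetic = list(),
                           trainFraction = 0.5, screenPThreshold = 0.001,
                           maxSignatureSize = 3L, workers = 1L,
                           resampleRepetitions = 1000L,
                           resampleFraction = 0.5, pccThreshold = 0.6,
                           pccPThreshold = 0.01,
                           minNonzeroFraction = 0.5,
                           compareModelsPath = NULL, seed = 1L,
                           outputDir = "survsig-output") {
  cfg <- list(expressionPath = expressionPath, clinicalPath = clinicalPath,
              alreadyLog = isTRUE(alreadyLog), synthetic = synthetic,
              trainFraction = trainFraction,
              screenPThreshold = screenPThreshold,
              maxSignatureSize = as.integer(maxSignatureSize),
              workers = as.integer(workers),
              resampleRepetitions = as.integer(resampleRepetitions),
              resampleFraction = resampleFraction,
              pccThreshold = pccThreshold, pccPThreshold = pccPThreshold,
              minNonzeroFraction = minNonzeroFraction,
              compareModelsPath = compareModelsPath,
              seed = as.integer(seed), outputDir = outputDir)
  in.unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  if (!in.unit(cfg$trainFraction))
    stop("trainFraction must lie strictly between 0 and 1")
  if (!is.numeric(cfg$screenPThreshold) || cfg$screenPThreshold <= 0 ||
      cfg$screenPThreshold > 1)
    stop("screenPThreshold must lie in (0, 1]")
  if (cfg$maxSignatureSize < 1L) stop("maxSignatureSize must be >= 1")
  if (!in.unit(cfg$resampleFraction))
    stop("resampleFraction must lie strictly between 0 and 1")
  if (!in.unit(cfg$pccPThreshold))
    stop("pccPThreshold must lie strictly between 0 and 1")
  if (cfg$resampleRepetitions < 2L) stop("resampleRepetitions must be >= 2")
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror \code{\link{pipelineConfig}}
#'   arguments.
#' @return a validated config list.
#' @export
loadPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

.reportKM <- function(km)
  list(eventTimes = km$eventTimes, nAtRisk = km$nAtRisk,
       nEvents = km$nEvents, survival = km$survival)

.reportEval <- function(ev)
  list(n = ev$n,
       auc = ev$auc$auc, aucCI = c(ev$auc$ciLow, ev$auc$ciHigh),
       aucP = ev$auc$pValue,
       cIndex = ev$concordance$cIndex,
       cIndexCI = c(ev$concordance$ciLow, ev$concordance$ciHigh),
       cIndexP = ev$concordance$pValue,
       logrankChiSquare = ev$logrank$chiSquare,
       logrankP = ev$logrank$pValue,
       meanSurvivalLow = ev$meanSurvivalLow,
       meanSurvivalHigh = ev$meanSurvivalHigh,
       genesUsed = ev$genesUsed, genesMissing = ev$genesMissing,
       kmLow = .reportKM(ev$kmLow), kmHigh = .reportKM(ev$kmHigh))

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

#' Run the full signature-discovery pipeline
#'
#' Load or simulate a cohort, prevalence-filter it, split into training
#' and validation halves, screen genes by univariate Cox, exhaustively
#' search 1..k gene combinations for the maximum training AUC, evaluate
#' the winning signature on both halves (and on a cross-platform view for
#' synthetic runs), optionally compare it against competing models by
#' repeated subsampling, and write JSON/TSV reports plus a run log to the
#' output directory. Identical config and seed give byte-identical
#' reports.
#'
#' @param config a \code{"pipelineConfig"} (or YAML path).
#' @param verbose print stage progress.
#' @return invisibly, a list with the cohorts, screen, search result and
#'   evaluation reports.
#' @export
runFullPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outputDir, "run.log")
  cat("survSigSearch run, seed ", config$seed, "\n", file = logfile,
      sep = "")
  say <- function(...) vlog(..., verbose = verbose, logfile = logfile)

  if (!is.null(config$expressionPath)) {
    say("stage load: reading ", config$expressionPath)
    expr <- readExpression(config$expressionPath, config$alreadyLog)
    clin <- readClinical(config$clinicalPath)
    cohort <- assembleCohort(expr, clin)
  } else {
    args <- config$synthetic
    args$seed <- if (is.null(args$seed))
      deriveSeed(config$seed, "simulate") else args$seed
    say("stage simulate: ",
        paste(names(args),
              vapply(args, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", "))
    cohort <- do.call(simulateCohort, args)
  }
  say("cohort: ", nrow(cohort), " genes x ", ncol(cohort), " samples, ",
      sum(eventStatus(cohort)), " events")

  cohort <- filterLowExpression(cohort, config$minNonzeroFraction)
  say("stage filter: ", nrow(cohort), " genes retained")

  parts <- splitCohort(cohort, config$trainFraction,
                       seed = deriveSeed(config$seed, "split"))
  say("stage split: ", ncol(parts$train), " training / ",
      ncol(parts$validation), " validation samples")

  screen <- univariateScreen(parts$train, config$screenPThreshold)
  say("stage screen: ", length(screen@candidates), " of ",
      screen@nTested, " genes at Wald P < ", config$screenPThreshold)
  write.table(data.frame(gene_id = screen@candidates,
                         coefficient = screen@coefficients,
                         wald_p = screen@waldP),
              file.path(config$outputDir, "screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  search <- exhaustiveSearch(parts$train, screen,
                             maxSize = config$maxSignatureSize,
                             workers = config$workers)
  best <- search@best
  say("stage search: ", format(search@nEnumerated, big.mark = ","),
      " combinations, best AUC ", format(best@trainingAUC, digits = 4),
      " with ", paste(best@geneIds, collapse = "+"))
  .writeJSON(list(geneIds = best@geneIds,
                  coefficients = best@coefficients,
                  trainingAUC = best@trainingAUC,
                  nEnumerated = search@nEnumerated,
                  nSkippedNonConverged = search@nSkippedNonConverged,
                  perSizeBest = lapply(search@perSizeBest, function(mm)
                    list(geneIds = mm@geneIds,
                         coefficients = mm@coefficients,
                         trainingAUC = mm@trainingAUC))),
             file.path(config$outputDir, "search.json"))
  write.table(data.frame(
    size = names(search@perSizeBest),
    genes = vapply(search@perSizeBest, function(mm)
      paste(mm@geneIds, collapse = ","), character(1)),
    training_auc = vapply(search@perSizeBest, function(mm)
      mm@trainingAUC, numeric(1))),
    file.path(config$outputDir, "per_size_best.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  evals <- list(training = evaluateModel(best, parts$train),
                validation = evaluateModel(best, parts$validation))
  if (is.null(config$expressionPath) && length(best@geneIds) > 1L) {
    # emulate a platform lacking the signature's least influential marker
    drop.gene <- best@geneIds[which.min(abs(best@coefficients))]
    view <- makeCrossPlatformView(
      cohort[, colnames(parts$validation)],
      missingGenes = drop.gene, shift = 0.2, scale = 0.9,
      noiseSd = 0.1, seed = deriveSeed(config$seed, "platform"))
    evals$external <- evaluateModel(best, view)
  }
  for (nm in names(evals)) {
    ev <- evals[[nm]]
    say("stage evaluate[", nm, "]: AUC ", format(ev$auc$auc, digits = 4),
        ", C-index ", format(ev$concordance$cIndex, digits = 4),
        ", log-rank P ", format(ev$logrank$pValue, digits = 3))
    .writeJSON(.reportEval(ev),
               file.path(config$outputDir,
                         paste0("evaluation_", nm, ".json")))
    write.table(data.frame(
      sample_id = names(ev$scores), score = ev$scores,
      group = ifelse(names(ev$scores) %in% ev$groups$lowRisk,
                     "low", "high")),
      file.path(config$outputDir, paste0("risk_groups_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  comparison <- NULL
  if (!is.null(config$compareModelsPath)) {
    others <- readModelFile(config$compareModelsPath)
    mods <- c(list(best = best), others)
    comparison <- resampleCompare(
      cohort, mods, repetitions = config$resampleRepetitions,
      fraction = config$resampleFraction,
      seed = deriveSeed(config$seed, "compare"))
    say("stage compare: mean AUC ",
        paste(names(comparison$meanAUC),
              signif(comparison$meanAUC, 4), sep = "=", collapse = ", "))
    .writeJSON(list(modelNames = comparison$modelNames,
                    meanAUC = as.list(comparison$meanAUC),
                    meanC = as.list(comparison$meanC),
                    pairwiseP = comparison$pairwiseP,
                    nRedrawn = comparison$nRedrawn),
               file.path(config$outputDir, "comparison.json"))
  }

  say("pipeline complete")
  invisible(list(cohort = cohort, train = parts$train,
                 validation = parts$validation, screen = screen,
                 search = search, evaluations = evals,
                 comparison = comparison, config = config))
}
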