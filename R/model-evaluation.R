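#' Median-split risk stratification
#'
#' Samples are sorted by (score, sample ID) and the lower half assigned to
#' the low-risk group; with an odd count the extra sample goes to the
#' low-risk group. The threshold reported is the lowest high-risk score.
#' Ties at the boundary are resolved by sample-ID order, so the split is
#' deterministic.
#'
#' @param scores named per-sample risk scores (length >= 2).
#' @return list with \code{lowRisk}, \code{highRisk} (sample-ID vectors)
#'   and \code{threshold}.
#' @export
stratifyMedian <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples to stratify")
  if (is.null(names(scores)))
    names(scores) <- sprintf("S%d", seq_along(scores))
  if (max(scores) == min(scores))
    stop("all risk scores identical; no meaningful stratification")
  ord <- order(scores, names(scores))
  n <- length(scores)
  n.low <- ceiling(n / 2)
  low <- names(scores)[ord[seq_len(n.low)]]
  high <- names(scores)[ord[(n.low + 1L):n]]
  list(lowRisk = low, highRisk = high,
       threshold = min(scores[high]))
}

#' Project a signature onto a platform missing some genes
#'
#' Computes the risk score from the available signature genes only,
#' keeping the original coefficients and letting missing terms contribute
#' 0 — the standard way a published signature is reused on a platform
#' that lacks some of its markers. With no missing genes the result is
#' bit-identical to \code{\link{riskScore}}.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param expression genes-by-samples matrix or
#'   \linkS4class{SurvivalCohort}.
#' @return list with \code{scores}, \code{genesUsed}, \code{genesMissing}.
#' @export
projectSignature <- function(model, expression) {
  if (is(expression, "SurvivalCohort")) expression <- exprValues(expression)
  used <- intersect(model@geneIds, rownames(expression))
  missing.genes <- setdiff(model@geneIds, used)
  if (!length(used))
    stop("none of the signature genes is present on this platform")
  keep <- model@geneIds %in% used
  scores <- drop(crossprod(expression[model@geneIds[keep], , drop = FALSE],
                           model@coefficients[keep]))
  list(scores = scores, genesUsed = model@geneIds[keep],
       genesMissing = missing.genes)
}

#' Evaluate a signature on a cohort
#'
#' Computes risk scores (projecting over missing genes if needed),
#' median-splits the cohort into risk groups, and reports Kaplan-Meier
#' curves for both groups, the two-group log-rank test, the ROC-AUC of
#' score versus end-of-follow-up vital status, Harrell's C-index of score
#' versus survival, and the observed mean follow-up time per group (days).
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param cohort a \linkS4class{SurvivalCohort} containing at least one
#'   model gene.
#' @return an object of class \code{"evaluationReport"}: list with
#'   \code{kmLow}, \code{kmHigh}, \code{logrank}, \code{auc},
#'   \code{concordance}, \code{meanSurvivalLow}, \code{meanSurvivalHigh},
#'   \code{genesUsed}, \code{genesMissing}, \code{groups}, \code{scores}.
#' @export
evaluateModel <- function(model, cohort) {
  stopifnot(is(cohort, "SurvivalCohort"))
  proj <- projectSignature(model, cohort)
  scores <- proj$scores
  strat <- stratifyMedian(scores)
  cd <- clinicalData(cohort)
  lo <- rownames(cd) %in% strat$lowRisk
  km.low <- kmEstimate(cd$time[lo], cd$event[lo])
  km.high <- kmEstimate(cd$time[!lo], cd$event[!lo])
  lr <- logrankTest(cd$time[lo], cd$event[lo], cd$time[!lo], cd$event[!lo])
  structure(list(
    kmLow = km.low, kmHigh = km.high, logrank = lr,
    auc = rocAUC(cd$event, scores),
    concordance = concordanceIndex(cd$time, cd$event, scores),
    meanSurvivalLow = mean(cd$time[lo]),
    meanSurvivalHigh = mean(cd$time[!lo]),
    genesUsed = proj$genesUsed, genesMissing = proj$genesMissing,
    groups = strat, scores = scores, n = ncol(cohort)),
    class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat("Signature evaluation over", x$n, "samples",
      if (length(x$genesMissing))
        paste0("(", length(x$genesMissing), " signature gene(s) missing)"),
      "\n")
  cat(sprintf("  mean survival: low-risk %.0f vs high-risk %.0f days\n",
              x$meanSurvivalLow, x$meanSurvivalHigh))
  print(x$logrank)
  print(x$auc)
  print(x$concordance)
  invisible(x)
}

#' Per-subgroup evaluation by a clinical factor
#'
#' Re-evaluates the signature within each level of gender, AJCC stage or
#' histologic grade. Levels with fewer than \code{minN} samples, or whose
#' median split leaves a risk group without any event, are reported as
#' skipped (sparse strata such as stage IV cannot support the analysis).
#' \code{"unknown"} levels are always excluded. \code{mergeStages} pools
#' III and IV into one \code{"III+IV"} level.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param factor one of \code{"gender"}, \code{"stage"}, \code{"grade"}.
#' @param minN minimum samples per level.
#' @param mergeStages logical; pool stages III and IV.
#' @return named list: each element an \code{"evaluationReport"} or the
#'   string \code{"skipped"}.
#' @export
subgroupEvaluate <- function(model, cohort,
                             factor = c("gender", "stage", "grade"),
                             minN = 10L, mergeStages = FALSE) {
  factor <- match.arg(factor)
  lev <- clinicalData(cohort)[[factor]]
  if (mergeStages && factor == "stage")
    lev[lev %in% c("III", "IV")] <- "III+IV"
  lev[is.na(lev)] <- "unknown"
  out <- list()
  for (l in setdiff(unique(lev), "unknown")) {
    sub <- cohort[, lev == l]
    rep.l <- tryCatch({
      if (ncol(sub) < minN) stop("below minN")
      r <- evaluateModel(model, sub)
      cd <- clinicalData(sub)
      lo <- rownames(cd) %in% r$groups$lowRisk
      if (sum(cd$event[lo]) < 1 || sum(cd$event[!lo]) < 1)
        stop("a risk group has no events")
      r
    }, error = function(e) "skipped")
    out[[l]] <- rep.l
  }
  if (!length(out))
    warning("no evaluable level for factor ", factor)
  out
}

#' Pearson coexpression screen against marker genes
#'
#' For every non-marker gene and every marker, computes the Pearson
#' correlation over samples and its two-sided t-distribution P-value, and
#' retains pairs with \code{r > pccThreshold} and \code{P < pThreshold}
#' (defaults 0.6 and 0.01). The threshold is signed by default — strong
#' negative correlates are not retained — with \code{absolute = TRUE} as
#' an explicit alternative. Zero-variance genes are skipped with a
#' warning.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param markerGenes gene IDs of the signature markers.
#' @param pccThreshold correlation threshold.
#' @param pThreshold P-value threshold.
#' @param absolute use |r| instead of signed r.
#' @return data.frame with columns \code{gene_id}, \code{partner_marker},
#'   \code{pcc}, \code{p_value}.
#' @export
coexpressionScreen <- function(cohort, markerGenes, pccThreshold = 0.6,
                               pThreshold = 0.01, absolute = FALSE) {
  stopifnot(is(cohort, "SurvivalCohort"))
  missing.genes <- setdiff(markerGenes, rownames(cohort))
  if (length(missing.genes))
    stop("marker(s) not in cohort: ", paste(missing.genes, collapse = ", "))
  x <- exprValues(cohort)
  others <- setdiff(rownames(x), markerGenes)
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 samples for a correlation test")
  sd0 <- apply(x, 1L, sd) == 0
  if (any(sd0[others]))
    warning(sum(sd0[others]), " zero-variance gene(s) skipped")
  if (any(sd0[markerGenes]))
    stop("zero-variance marker gene")
  others <- others[!sd0[others]]
  r <- cor(t(x[others, , drop = FALSE]),
           t(x[markerGenes, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  pv <- 2 * pt(-abs(tstat), df = n - 2)
  eff <- if (absolute) abs(r) else r
  hit <- which(eff > pccThreshold & pv < pThreshold, arr.ind = TRUE)
  data.frame(gene_id = others[hit[, 1L]],
             partner_marker = markerGenes[hit[, 2L]],
             pcc = r[hit], p_value = pv[hit],
             stringsAsFactors = FALSE)
}
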