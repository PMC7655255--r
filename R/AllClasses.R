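#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

.CLINICAL_COLS <- c("time", "event", "gender", "stage", "grade", "age")
.GENDER_LEVELS <- c("male", "female", "unknown")
.STAGE_LEVELS <- c("I", "II", "III", "IV", "unknown")
.GRADE_LEVELS <- c("G1", "G2", "G3", "G4", "unknown")

#' SurvivalCohort: expression joined with survival records
#'
#' A \code{SurvivalCohort} couples a genes-by-samples matrix of
#' log2(x+1)-normalized expression (assay \code{"exprs"}) with per-sample
#' survival and covariate records in \code{colData}: \code{time} (days,
#' strictly positive), \code{event} (1 = death, 0 = censored),
#' \code{gender}, \code{stage} (AJCC I--IV), \code{grade} (G1--G4) and
#' \code{age}. It extends \linkS4class{SummarizedExperiment}, so all the
#' usual subsetting and accessor machinery applies; validity additionally
#' requires finite non-negative expression, unique gene and sample
#' identifiers, and at least one observed death (all survival statistics
#' degenerate otherwise).
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{SurvivalCohort}} (constructor),
#'   \code{\link{survivalTime}}, \code{\link{eventStatus}}
#' @exportClass SurvivalCohort
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- assay(object, "exprs")
    if (any(!is.finite(x)))
      msg <- c(msg, "expression values must all be finite")
    else if (any(x < 0))
      msg <- c(msg, "expression values must be >= 0 (log2(x+1) scale)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  cd <- colData(object)
  missing.cols <- setdiff(c("time", "event"), colnames(cd))
  if (length(missing.cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing.cols, collapse = ", ")))
  else {
    if (any(!is.finite(cd$time)) || any(cd$time <= 0))
      msg <- c(msg, "survival time must be finite and strictly positive")
    if (!all(cd$event %in% c(0, 1)))
      msg <- c(msg, "event must be 0 (censored) or 1 (death)")
    else if (ncol(object) > 0 && sum(cd$event) < 1)
      msg <- c(msg, "cohort must contain at least one event")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted Cox proportional-hazards model
#'
#' Result of \code{\link{fitCox}}: per-gene log hazard ratios with standard
#' errors and two-sided Wald tests, the maximized Efron-corrected log
#' partial likelihood, and a convergence flag. Non-convergence marks
#' monotone-likelihood (separation) fits whose coefficients diverge; the
#' search layer skips those deterministically.
#'
#' @slot geneIds ordered character vector of covariate (gene) identifiers.
#' @slot coefficients log hazard ratio per unit expression.
#' @slot se standard errors (NA where unidentifiable).
#' @slot waldZ,waldP Wald z = coef/se and its two-sided normal P.
#' @slot logLik maximized log partial likelihood.
#' @slot converged logical convergence flag.
#' @slot nIter Newton-Raphson iterations used.
#' @exportClass CoxFit
setClass("CoxFit", representation(
  geneIds = "character", coefficients = "numeric", se = "numeric",
  waldZ = "numeric", waldP = "numeric", logLik = "numeric",
  converged = "logical", nIter = "integer"))

setValidity("CoxFit", function(object) {
  p <- length(object@geneIds)
  lens <- c(length(object@coefficients), length(object@se),
            length(object@waldZ), length(object@waldP))
  if (any(lens != p))
    return("coefficient, se, z and p vectors must match geneIds in length")
  pv <- object@waldP[!is.na(object@waldP)]
  if (any(pv < 0 | pv > 1)) return("waldP must lie in [0, 1]")
  TRUE
})

#' Univariate Cox screening result
#'
#' Genes surviving the single-gene Cox Wald screen at a P-value threshold
#' (0.001 by default), in stable input order, with each candidate's
#' univariate coefficient and P-value.
#'
#' @slot candidates character vector of retained gene identifiers.
#' @slot coefficients,waldP per-candidate univariate statistics.
#' @slot threshold the screening P threshold used.
#' @slot nTested number of genes tested.
#' @slot nNonConverged genes dropped for non-convergent univariate fits.
#' @exportClass ScreenResult
setClass("ScreenResult", representation(
  candidates = "character", coefficients = "numeric", waldP = "numeric",
  threshold = "numeric", nTested = "integer", nNonConverged = "integer"))

setValidity("ScreenResult", function(object) {
  if (length(object@coefficients) != length(object@candidates) ||
      length(object@waldP) != length(object@candidates))
    return("per-candidate vectors must match candidates in length")
  if (any(object@waldP >= object@threshold))
    return("every retained candidate must have waldP below the threshold")
  TRUE
})

#' Prognostic signature model
#'
#' An ordered gene set with multivariate Cox coefficients. The risk score of
#' a sample is the linear predictor sum(coef_g * E_g) over the signature
#' genes (see \code{\link{riskScore}}).
#'
#' @slot geneIds ordered gene identifiers (length 1..k).
#' @slot coefficients finite Cox coefficients aligned with \code{geneIds}.
#' @slot trainingAUC training-set ROC-AUC of the risk score, NA if unknown.
#' @slot name optional model label (used by the comparison harness).
#' @exportClass SignatureModel
setClass("SignatureModel", representation(
  geneIds = "character", coefficients = "numeric", trainingAUC = "numeric",
  name = "character"))

setValidity("SignatureModel", function(object) {
  if (length(object@geneIds) < 1L)
    return("a signature needs at least one gene")
  if (length(object@coefficients) != length(object@geneIds))
    return("coefficients must match geneIds in length")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  if (anyDuplicated(object@geneIds))
    return("duplicate gene in signature")
  if (length(object@trainingAUC) != 1L ||
      (!is.na(object@trainingAUC) &&
       (object@trainingAUC < 0 || object@trainingAUC > 1)))
    return("trainingAUC must be a single value in [0,1] or NA")
  TRUE
})

#' Exhaustive search result
#'
#' The argmax of the AUC objective over all enumerated gene combinations,
#' plus enumeration bookkeeping: total combinations evaluated, combinations
#' skipped for non-convergent Cox fits, and the best model per signature
#' size.
#'
#' @slot best the winning \linkS4class{SignatureModel}.
#' @slot nEnumerated total combinations enumerated.
#' @slot nSkippedNonConverged combinations skipped (degenerate fits).
#' @slot perSizeBest list mapping size (as character) to the best
#'   \linkS4class{SignatureModel} of that size.
#' @exportClass SearchResult
setClass("SearchResult", representation(
  best = "SignatureModel", nEnumerated = "numeric",
  nSkippedNonConverged = "numeric", perSizeBest = "list"))

setValidity("SearchResult", function(object) {
  if (object@nEnumerated < 1) return("nEnumerated must be positive")
  aucs <- vapply(object@perSizeBest, function(m) m@trainingAUC, numeric(1))
  if (length(aucs) && any(aucs > object@best@trainingAUC + 1e-12))
    return("best must dominate every per-size best on training AUC")
  TRUE
})
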