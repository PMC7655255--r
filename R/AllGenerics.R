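#' Accessors for SurvivalCohort and model objects
#'
#' \code{survivalTime} and \code{eventStatus} return the follow-up time in
#' days and the death indicator; \code{exprValues} returns the
#' log2-normalized genes-by-samples matrix; \code{clinicalData} the full
#' per-sample table. \code{signatureGenes} and \code{signatureCoefficients}
#' expose a model's gene set and Cox coefficients.
#'
#' @param x a \linkS4class{SurvivalCohort} or \linkS4class{SignatureModel}.
#' @return vectors / matrices as described per accessor.
#' @examples
#' coh <- simulateCohort(nSamples = 40, nGenes = 10, seed = 1)
#' head(survivalTime(coh))
#' table(eventStatus(coh))
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("survivalTime", function(x) standardGeneric("survivalTime"))

#' @rdname cohort-accessors
#' @export
setGeneric("eventStatus", function(x) standardGeneric("eventStatus"))

#' @rdname cohort-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname cohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname cohort-accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname cohort-accessors
#' @export
setGeneric("signatureCoefficients",
           function(x) standardGeneric("signatureCoefficients"))

#' @rdname cohort-accessors
#' @export
setMethod("survivalTime", "SurvivalCohort",
          function(x) as.numeric(colData(x)$time))

#' @rdname cohort-accessors
#' @export
setMethod("eventStatus", "SurvivalCohort",
          function(x) as.numeric(colData(x)$event))

#' @rdname cohort-accessors
#' @export
setMethod("exprValues", "SurvivalCohort", function(x) assay(x, "exprs"))

#' @rdname cohort-accessors
#' @export
setMethod("clinicalData", "SurvivalCohort",
          function(x) as.data.frame(colData(x)))

#' @rdname cohort-accessors
#' @export
setMethod("signatureGenes", "SignatureModel", function(x) x@geneIds)

#' @rdname cohort-accessors
#' @export
setMethod("signatureCoefficients", "SignatureModel",
          function(x) stats::setNames(x@coefficients, x@geneIds))

#' @rdname cohort-accessors
#' @export
setMethod("signatureGenes", "CoxFit", function(x) x@geneIds)

#' @describeIn cohort-accessors coefficients of a fitted Cox model.
#' @param object a \linkS4class{CoxFit}.
#' @param ... ignored.
#' @export
setMethod("coef", "CoxFit",
          function(object, ...) stats::setNames(object@coefficients,
                                                object@geneIds))

#' @describeIn cohort-accessors log partial likelihood of a fitted Cox model.
#' @export
setMethod("logLik", "CoxFit", function(object, ...) object@logLik)

setMethod("show", "SurvivalCohort", function(object) {
  cat("SurvivalCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  ev <- sum(colData(object)$event)
  cat(sprintf("  events: %d deaths, %d censored (%.1f%% censored)\n",
              ev, ncol(object) - ev,
              100 * (1 - ev / max(1, ncol(object)))))
  cat(sprintf("  follow-up: median %.0f days\n",
              stats::median(colData(object)$time)))
  callNextMethod()
})

setMethod("show", "CoxFit", function(object) {
  cat("CoxFit (", length(object@geneIds), " covariate(s); ",
      if (object@converged) "converged" else "NOT converged",
      " in ", object@nIter, " iterations)\n", sep = "")
  print(data.frame(coef = object@coefficients, se = object@se,
                   z = object@waldZ, p = object@waldP,
                   row.names = object@geneIds))
  cat("log partial likelihood:", format(object@logLik), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", length(object@candidates), "of", object@nTested,
      "genes retained at Wald P <", format(object@threshold), "\n")
  if (object@nNonConverged > 0)
    cat("  (", object@nNonConverged, "non-convergent univariate fits )\n")
})

setMethod("show", "SignatureModel", function(object) {
  nm <- if (length(object@name)) object@name else "signature"
  cat("SignatureModel '", nm, "': risk score = ", sep = "")
  cat(paste(sprintf("%+.4f*%s", object@coefficients, object@geneIds),
            collapse = " "), "\n")
  if (!is.na(object@trainingAUC))
    cat("  training AUC:", format(object@trainingAUC, digits = 4), "\n")
})

setMethod("show", "SearchResult", function(object) {
  cat("SearchResult over", format(object@nEnumerated, big.mark = ","),
      "combinations (", object@nSkippedNonConverged, "skipped )\n")
  cat("best model:\n")
  show(object@best)
})
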