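#' Read competing signature models from a TSV file
#'
#' Expects columns \code{model_name}, \code{gene_id}, \code{coefficient}:
#' one row per gene, grouped by model. This is how published comparator
#' signatures (gene sets with fixed published coefficients) enter the
#' comparison harness.
#'
#' @param path TSV path.
#' @return named list of \linkS4class{SignatureModel}s.
#' @export
readModelFile <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("model_name", "gene_id", "coefficient")
  if (!all(need %in% colnames(df)))
    stop("model file needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$model_name), function(d)
    new("SignatureModel", geneIds = as.character(d$gene_id),
        coefficients = as.numeric(d$coefficient),
        trainingAUC = NA_real_, name = d$model_name[1L]))
  out[unique(df$model_name)]
}

#' Repeated-subsampling model comparison
#'
#' Draws \code{repetitions} random without-replacement subsamples of
#' \code{floor(fraction * n)} samples (50\% by default), scores every
#' model on each subsample via \code{\link{projectSignature}}, records the
#' per-resample AUC and C-index, and compares models by two-sided Welch
#' t-tests on the AUC vectors. The same subsamples are used for all
#' models (a paired design; set \code{paired = FALSE} to redraw per
#' model). Subsamples lacking both vital-status classes are redrawn with
#' bounded retries and counted.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param models named list of \linkS4class{SignatureModel}s.
#' @param repetitions number of resamples R (>= 2; the conventional
#'   full-scale choice is 1000).
#' @param fraction subsample fraction in (0, 1).
#' @param seed integer seed; same seed, bit-identical report.
#' @param paired share subsamples across models.
#' @return an object of class \code{"comparisonReport"}: list with
#'   \code{modelNames}, \code{aucSamples}, \code{cSamples} (R x models
#'   matrices), \code{meanAUC}, \code{meanC}, \code{pairwiseP},
#'   \code{nRedrawn}, \code{seed}.
#' @export
resampleCompare <- function(cohort, models, repetitions = 1000L,
                            fraction = 0.5, seed = 1L, paired = TRUE) {
  stopifnot(is(cohort, "SurvivalCohort"), length(models) >= 1L)
  if (repetitions < 2L) stop("repetitions must be >= 2")
  if (repetitions < 30L)
    warning("small repetition count; t-test P-values will be unstable")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m)
      if (length(m@name)) m@name else "model", character(1))
  nm <- names(models)
  n <- ncol(cohort)
  k <- max(2L, floor(fraction * n))
  cd <- clinicalData(cohort)
  scores <- lapply(models, function(m) projectSignature(m, cohort)$scores)

  n.models <- length(models)
  auc.mat <- matrix(NA_real_, repetitions, n.models,
                    dimnames = list(NULL, nm))
  c.mat <- auc.mat
  n.redrawn <- 0L
  withSeed(seed, {
    n.draws <- if (paired) 1L else n.models
    for (r in seq_len(repetitions)) {
      for (d in seq_len(n.draws)) {
        idx <- NULL
        for (try in seq_len(100L)) {
          cand <- sample.int(n, k)
          ev <- cd$event[cand]
          if (any(ev == 1) && any(ev == 0)) { idx <- cand; break }
          n.redrawn <- n.redrawn + 1L
        }
        if (is.null(idx))
          stop("could not draw a subsample with both outcome classes")
        cols <- if (paired) seq_len(n.models) else d
        for (j in cols) {
          s <- scores[[j]][idx]
          auc.mat[r, j] <- .aucFast(cd$event[idx], s)
          c.mat[r, j] <- concordanceIndex(cd$time[idx], cd$event[idx],
                                          s)$cIndex
        }
      }
    }
  })

  pw <- matrix(1, n.models, n.models, dimnames = list(nm, nm))
  for (i in seq_len(n.models)) for (j in seq_len(n.models)) {
    if (i >= j) next
    a <- auc.mat[, i]; b <- auc.mat[, j]
    p <- if (isTRUE(all.equal(a, b)) || (sd(a) == 0 && sd(b) == 0)) 1
    else t.test(a, b)$p.value
    pw[i, j] <- pw[j, i] <- p
  }
  structure(list(modelNames = nm, aucSamples = auc.mat, cSamples = c.mat,
                 meanAUC = colMeans(auc.mat), meanC = colMeans(c.mat),
                 pairwiseP = pw, nRedrawn = n.redrawn, seed = seed,
                 repetitions = repetitions, fraction = fraction,
                 paired = paired),
            class = "comparisonReport")
}

#' @export
print.comparisonReport <- function(x, ...) {
  cat("Resampling comparison:", x$repetitions, "draws of",
      sprintf("%.0f%%", 100 * x$fraction), "of the cohort\n")
  print(data.frame(meanAUC = x$meanAUC, meanC = x$meanC))
  cat("pairwise Welch t-test P (AUC):\n")
  print(signif(x$pairwiseP, 3))
  invisible(x)
}
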