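#' Simulate a survival cohort with a planted prognostic signature
#'
#' Generates log-scale expression for many null genes plus a small planted
#' gene set whose linear combination drives the hazard under a
#' proportional-hazards model with exponential event times and independent
#' exponential right-censoring.
#'
#' Expression is drawn per gene/sample as \code{max(0, Normal(location,
#' scale))}, with an independent \code{zeroInflation} fraction of values
#' forced to 0, honouring the \code{log2(x+1) >= 0} domain of normalized
#' RNA-seq data. The linear predictor of sample \code{i} is
#' \code{eta_i = sum_g beta_g * x[g, i]} over the planted genes (computed
#' from the final, clipped expression values, so a Cox fit on the planted
#' genes is estimating exactly the generating coefficients). Event times
#' are exponential with rate \code{baselineHazard * exp(eta_i)}; the
#' censoring rate constant is tuned by solving
#' \code{mean(lc / (lc + lambda_i)) = censorRate} over the realized
#' per-sample hazards, which makes the expected censored fraction equal the
#' target under any covariate effect. Observed time is the minimum of event
#' and censoring time.
#'
#' Defaults emulate a liver-cancer RNA-seq cohort: 370 samples, a 3-gene
#' signature with coefficients (0.7675, 0.1726, -0.2466) in log-hazard
#' units, 65\% censoring, and a baseline hazard (1.5e-4 per day) placing
#' observed follow-up on the one-to-two-year scale typical of
#' liver-cancer cohorts.
#' Gender/stage/grade covariates are drawn from realistic marginal
#' frequencies, independent of survival (they carry no signal).
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param plantedGenes integer indices (distinct, <= nGenes) of the
#'   signature genes.
#' @param plantedBetas log hazard ratio per planted gene, aligned with
#'   \code{plantedGenes}.
#' @param baselineHazard event rate per day at eta = 0.
#' @param censorRate target censored proportion in [0, 1).
#' @param expressionLocation,expressionScale mean and sd of log-scale
#'   expression before clipping at 0.
#' @param zeroInflation proportion of values forced to 0.
#' @param seed integer seed; the same seed yields a bit-identical cohort.
#' @return a \linkS4class{SurvivalCohort}; planted gene IDs and betas are
#'   stored in \code{metadata()} under \code{planted}.
#' @examples
#' coh <- simulateCohort(nSamples = 100, nGenes = 50, seed = 7)
#' S4Vectors::metadata(coh)$planted
#' @export
simulateCohort <- function(nSamples = 370L, nGenes = 1000L,
                           plantedGenes = 1:3,
                           plantedBetas = c(0.7675, 0.1726, -0.2466),
                           baselineHazard = 1.5e-4, censorRate = 0.65,
                           expressionLocation = 2, expressionScale = 1,
                           zeroInflation = 0.2, seed = 1L) {
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  if (zeroInflation < 0 || zeroInflation >= 1)
    stop("zeroInflation must lie in [0, 1)")
  if (expressionScale <= 0) stop("expressionScale must be > 0")
  if (baselineHazard <= 0) stop("baselineHazard must be > 0")
  plantedGenes <- as.integer(plantedGenes)
  if (length(plantedGenes) != length(plantedBetas))
    stop("plantedBetas must align with plantedGenes")
  if (length(plantedGenes) &&
      (anyDuplicated(plantedGenes) || any(plantedGenes < 1) ||
       any(plantedGenes > nGenes)))
    stop("plantedGenes must be distinct indices within 1..nGenes")
  if (!length(plantedGenes) || all(plantedBetas == 0))
    warning("no planted signal: all univariate tests are null")

  withSeed(seed, {
    x <- matrix(rnorm(nGenes * nSamples, expressionLocation,
                      expressionScale), nrow = nGenes)
    x[x < 0] <- 0
    if (zeroInflation > 0)
      x[matrix(runif(length(x)) < zeroInflation, nrow = nGenes)] <- 0
    gene.ids <- sprintf("SYNG%06d", seq_len(nGenes))
    sample.ids <- sprintf("SAMP%04d", seq_len(nSamples))
    dimnames(x) <- list(gene.ids, sample.ids)

    eta <- if (length(plantedGenes))
      drop(crossprod(x[plantedGenes, , drop = FALSE], plantedBetas))
    else rep(0, nSamples)
    lambda <- baselineHazard * exp(eta)
    event.time <- rexp(nSamples, rate = lambda)
    if (censorRate > 0) {
      lc <- .tuneCensorRate(lambda, censorRate)
      censor.time <- rexp(nSamples, rate = lc)
    } else censor.time <- rep(Inf, nSamples)
    obs.time <- pmin(event.time, censor.time)
    event <- as.numeric(event.time <= censor.time)

    clin <- data.frame(
      sample_id = sample.ids,
      time = obs.time, event = event,
      gender = sample(c("male", "female"), nSamples, replace = TRUE,
                      prob = c(0.67, 0.33)),
      stage = sample(.STAGE_LEVELS, nSamples, replace = TRUE,
                     prob = c(0.46, 0.23, 0.23, 0.015, 0.065)),
      grade = sample(.GRADE_LEVELS, nSamples, replace = TRUE,
                     prob = c(0.15, 0.48, 0.32, 0.03, 0.02)),
      age = round(rnorm(nSamples, 60, 10)),
      stringsAsFactors = FALSE)
    clin$age[clin$age < 18] <- 18

    coh <- SurvivalCohort(x, clin)
    metadata(coh)$planted <- list(geneIds = gene.ids[plantedGenes],
                                  betas = plantedBetas)
    metadata(coh)$seed <- seed
    coh
  })
}

# Censoring-rate constant: under C ~ Exp(lc) independent of T_i ~
# Exp(lambda_i), P(censored | lambda_i) = lc / (lc + lambda_i); solve the
# mean over samples for the target rate (monotone in lc, so uniroot on a
# log grid always brackets).
.tuneCensorRate <- function(lambda, rate) {
  f <- function(lc) mean(lc / (lc + lambda)) - rate
  lo <- min(lambda) * 1e-8
  hi <- max(lambda) * 1e8
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Distort a cohort into a cross-platform view
#'
#' Emulates measuring the same patients on a different expression platform
#' on which some signature genes are absent: the listed genes are removed
#' and every remaining value is affinely distorted as
#' \code{scale * x + shift} plus small seeded Gaussian noise, then clipped
#' at 0 to stay on the non-negative log scale. Clinical records are
#' unchanged, so a signature can be projected onto the view and evaluated
#' against the same outcomes.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param missingGenes gene IDs to drop (must be a subset of the cohort's
#'   genes; may be empty).
#' @param shift,scale affine distortion parameters.
#' @param noiseSd standard deviation of the added platform noise (0 = none).
#' @param seed integer seed for the noise.
#' @return a \linkS4class{SurvivalCohort} on the reduced gene set.
#' @export
makeCrossPlatformView <- function(cohort, missingGenes = character(),
                                  shift = 0, scale = 1, noiseSd = 0,
                                  seed = 1L) {
  bad <- setdiff(missingGenes, rownames(cohort))
  if (length(bad))
    stop("missingGenes not in cohort: ", paste(bad, collapse = ", "))
  keep <- setdiff(rownames(cohort), missingGenes)
  if (!length(keep))
    stop("cross-platform view would remove every gene")
  out <- cohort[keep, ]
  x <- exprValues(out) * scale + shift
  if (noiseSd > 0)
    x <- x + withSeed(seed, matrix(rnorm(length(x), 0, noiseSd),
                                   nrow = nrow(x)))
  x[x < 0] <- 0
  SummarizedExperiment::assay(out, "exprs") <- x
  validObject(out)
  out
}
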