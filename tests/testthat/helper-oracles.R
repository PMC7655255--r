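# Independent oracles and fixture builders. Everything here is written
# against the definitions directly (explicit loops over risk sets and
# pairs), deliberately sharing no code with the package internals.

# direct log partial likelihood for one covariate, looped over events
oracleCoxPLL <- function(beta, time, status, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sD <- sum(exp(beta * x[D]))
    sR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      frac <- if (ties == "breslow") 0 else l / d
      ll <- ll - log(sR - frac * sD)
    }
  }
  ll
}

# grid maximization of the 1-covariate partial likelihood: coarse grid,
# then a refined pass around the coarse argmax
oracleGridCoxBeta <- function(time, status, x, ties = "efron",
                              lim = 8, coarse = 0.05, fine = 1e-4) {
  grid <- seq(-lim, lim, by = coarse)
  ll <- vapply(grid, oracleCoxPLL, numeric(1),
               time = time, status = status, x = x, ties = ties)
  b0 <- grid[which.max(ll)]
  grid2 <- seq(b0 - coarse, b0 + coarse, by = fine)
  ll2 <- vapply(grid2, oracleCoxPLL, numeric(1),
                time = time, status = status, x = x, ties = ties)
  list(beta = grid2[which.max(ll2)], boundary = abs(b0) >= lim - coarse)
}

# pair-enumeration Harrell C
oracleCIndex <- function(time, status, risk) {
  conc <- 0; npairs <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || status[i] != 1 || !(time[i] < time[j])) next
    npairs <- npairs + 1
    conc <- conc + if (risk[i] > risk[j]) 1
    else if (risk[i] == risk[j]) 0.5 else 0
  }
  conc / npairs
}

# pair-enumeration Mann-Whitney AUC
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# naive exhaustive-search oracle: re-fit every combination with
# survival::coxph and take the argmax under the documented tie-break
oracleSearch <- function(cohort, candidates, maxSize) {
  cd <- clinicalData(cohort)
  x <- exprValues(cohort)
  best <- NULL
  for (k in seq_len(maxSize)) {
    combos <- utils::combn(seq_along(candidates), k, simplify = FALSE)
    for (idx in combos) {
      genes <- candidates[idx]
      X <- t(x[genes, , drop = FALSE])
      fit <- tryCatch(
        survival::coxph(survival::Surv(cd$time, cd$event) ~ X,
                        ties = "efron"),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(fit) || any(abs(stats::coef(fit)) > 20)) next
      sc <- drop(X %*% stats::coef(fit))
      auc <- oracleAUC(cd$event, sc)
      if (is.null(best) || auc > best$auc + 1e-12)
        best <- list(genes = genes, auc = auc)
    }
  }
  best
}

# small deterministic cohort with hand-set times/events/expression
makeToyCohort <- function(expr, time, event, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(time))
  colnames(expr) <- ids
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("G%02d", seq_len(nrow(expr)))
  SurvivalCohort(expr, data.frame(sample_id = ids, time = time,
                                  event = event,
                                  stringsAsFactors = FALSE))
}

makeModel <- function(genes, coefs, auc = NA_real_, name = "m") {
  new("SignatureModel", geneIds = genes, coefficients = coefs,
      trainingAUC = auc, name = name)
}

writeTempTSV <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
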