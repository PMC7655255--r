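# Exhaustive AUC-maximizing search over all 1..k gene combinations.
# Combinations are enumerated size-major (all singles, then pairs, ...),
# lexicographically within each size, and addressed by a global rank so
# the traversal can be partitioned into contiguous chunks for parallel or
# resumable runs without materializing the full stream (the full-scale
# problem is ~1.2e7 combinations).

# lexicographic unranking of the r-th (1-based) k-combination of 1..m
.combUnrank <- function(m, k, r) {
  comb <- integer(k)
  x <- 1L
  r <- r - 1
  for (i in seq_len(k)) {
    repeat {
      cnt <- choose(m - x, k - i)
      if (r < cnt) break
      r <- r - cnt
      x <- x + 1L
    }
    comb[i] <- x
    x <- x + 1L
  }
  comb
}

# lexicographic successor, or NULL after the last combination
.combNext <- function(comb, m) {
  k <- length(comb)
  i <- k
  while (i >= 1L && comb[i] == m - k + i) i <- i - 1L
  if (i == 0L) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < k) comb[(i + 1L):k] <- comb[i] + seq_len(k - i)
  comb
}

#' Count combinations of sizes 1..maxSize
#'
#' @param m number of candidates.
#' @param maxSize largest combination size.
#' @return \code{sum_{j=1..maxSize} choose(m, j)}.
#' @examples
#' combinationCount(415, 3)   # 11,912,575
#' @export
combinationCount <- function(m, maxSize) {
  sum(choose(m, seq_len(min(maxSize, m))))
}

# map a global rank to list(size, withinRank)
.rankToSize <- function(m, maxSize, r) {
  for (j in seq_len(maxSize)) {
    cnt <- choose(m, j)
    if (r <= cnt) return(list(size = j, rank = r))
    r <- r - cnt
  }
  stop("rank out of range")
}

# global rank range [lo, hi] of chunk `i` of `w` over total `total`
.chunkRange <- function(total, i, w) {
  bounds <- floor(total * (0:w) / w)
  c(bounds[i] + 1, bounds[i + 1])
}

#' Enumerate gene combinations (optionally one chunk of the stream)
#'
#' Yields every subset of size 1..\code{maxSize} of \code{candidates}
#' exactly once, size-major and in lexicographic candidate-index order
#' within each size. \code{chunk = c(i, w)} restricts the output to the
#' i-th of \code{w} contiguous rank ranges, the partition the parallel
#' search uses; concatenating all chunks reproduces the full stream.
#'
#' @param candidates character vector of gene IDs.
#' @param maxSize largest subset size; capped at the candidate count with
#'   a warning.
#' @param chunk integer pair \code{c(i, w)}; default the whole stream.
#' @return list of character vectors (gene-ID combinations).
#' @export
enumerateCombinations <- function(candidates, maxSize = 3L,
                                  chunk = c(1L, 1L)) {
  m <- length(candidates)
  if (maxSize < 1L) stop("maxSize must be >= 1")
  if (maxSize > m) {
    warning("maxSize exceeds candidate count; capped at ", m)
    maxSize <- m
  }
  total <- combinationCount(m, maxSize)
  rng <- .chunkRange(total, chunk[1L], chunk[2L])
  if (rng[1L] > rng[2L]) return(list())
  out <- vector("list", rng[2L] - rng[1L] + 1)
  pos <- .rankToSize(m, maxSize, rng[1L])
  comb <- .combUnrank(m, pos$size, pos$rank)
  for (ii in seq_along(out)) {
    out[[ii]] <- candidates[comb]
    nxt <- .combNext(comb, m)
    if (is.null(nxt)) {
      if (length(comb) < maxSize) nxt <- seq_len(length(comb) + 1L)
    }
    comb <- nxt
  }
  out
}

#' Univariate Cox screen
#'
#' Fits one single-gene Cox model per gene and retains, in stable input
#' order, the genes whose fit converged with a Wald P-value below
#' \code{pThreshold} (default 0.001, the conventional screening cut for
#' genome-wide candidate selection).
#'
#' @param cohort a \linkS4class{SurvivalCohort} (already prevalence
#'   filtered).
#' @param pThreshold Wald P-value cut in (0, 1].
#' @return a \linkS4class{ScreenResult}.
#' @export
univariateScreen <- function(cohort, pThreshold = 0.001) {
  stopifnot(is(cohort, "SurvivalCohort"))
  if (pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must lie in (0, 1]")
  prep <- .coxPrep(survivalTime(cohort), eventStatus(cohort))
  Xall <- t(exprValues(cohort))[prep$ord, , drop = FALSE]
  genes <- rownames(cohort)
  coefs <- pvals <- rep(NA_real_, length(genes))
  n.nonconv <- 0L
  for (g in seq_along(genes)) {
    fit <- .coxEngine(NULL, NULL, Xall[, g, drop = FALSE], prep = prep)
    if (!fit$converged) {
      n.nonconv <- n.nonconv + 1L
      next
    }
    coefs[g] <- fit$coef
    pvals[g] <- fit$p
  }
  keep <- which(!is.na(pvals) & pvals < pThreshold)
  if (!length(keep))
    stop("no gene passed the univariate screen at P < ", pThreshold,
         "; consider a looser threshold")
  new("ScreenResult", candidates = genes[keep],
      coefficients = coefs[keep], waldP = pvals[keep],
      threshold = pThreshold, nTested = length(genes),
      nNonConverged = n.nonconv)
}

#' Fit and score one gene combination
#'
#' Fits a multivariate Cox model on the combination, computes the risk
#' score (linear predictor) on the same cohort, and returns the AUC of the
#' score against end-of-follow-up vital status. Non-convergent
#' (separation-degenerate) fits return \code{NULL}, the skip marker the
#' search counts.
#'
#' @param cohort a \linkS4class{SurvivalCohort} (the training cohort).
#' @param geneIds the combination.
#' @return list with \code{fit} (a \linkS4class{CoxFit}) and \code{auc},
#'   or NULL when the fit does not converge.
#' @export
evaluateCombination <- function(cohort, geneIds) {
  fit <- fitCox(cohort, geneIds)
  if (!fit@converged) return(NULL)
  scores <- drop(crossprod(exprValues(cohort)[geneIds, , drop = FALSE],
                           fit@coefficients))
  list(fit = fit, auc = .aucFast(eventStatus(cohort), scores))
}

# Evaluate one contiguous rank chunk; returns running bests + counters.
# `Xall` is samples x candidates, already ordered by prep$ord; `status`
# is the AUC label vector in that same order.
.searchChunk <- function(rng, m, maxSize, prep, Xall, status) {
  best <- NULL
  per.size <- vector("list", maxSize)
  n.skip <- 0L
  if (rng[1L] > rng[2L])
    return(list(best = best, perSize = per.size, nSkip = n.skip))
  pos <- .rankToSize(m, maxSize, rng[1L])
  comb <- .combUnrank(m, pos$size, pos$rank)
  for (r in rng[1L]:rng[2L]) {
    fit <- .coxEngine(NULL, NULL, Xall[, comb, drop = FALSE], prep = prep)
    if (!fit$converged) {
      n.skip <- n.skip + 1L
    } else {
      auc <- .aucFast(status,
                      drop(Xall[, comb, drop = FALSE] %*% fit$coef))
      k <- length(comb)
      cand <- list(auc = auc, idx = comb, coef = fit$coef)
      # enumeration order is size-major lexicographic, so replacing only
      # on a strictly larger AUC realizes the (AUC, smaller size,
      # lexicographic) tie-break exactly
      if (is.null(best) || auc > best$auc) best <- cand
      if (is.null(per.size[[k]]) || auc > per.size[[k]]$auc)
        per.size[[k]] <- cand
    }
    nxt <- .combNext(comb, m)
    if (is.null(nxt) && length(comb) < maxSize)
      nxt <- seq_len(length(comb) + 1L)
    if (is.null(nxt)) break
    comb <- nxt
  }
  list(best = best, perSize = per.size, nSkip = n.skip)
}

.betterThan <- function(a, b) {
  # chunk-merge comparator matching the in-chunk tie-break: higher AUC,
  # then smaller size, then lexicographically smaller index vector
  if (is.null(b)) return(TRUE)
  if (a$auc != b$auc) return(a$auc > b$auc)
  if (length(a$idx) != length(b$idx)) return(length(a$idx) < length(b$idx))
  d <- which(a$idx != b$idx)
  length(d) > 0 && a$idx[d[1L]] < b$idx[d[1L]]
}

#' Exhaustive AUC-maximizing signature search
#'
#' Evaluates every combination of 1..\code{maxSize} screened candidate
#' genes by multivariate Cox fit and training-set ROC-AUC, and returns the
#' maximum-AUC signature. Ties break toward fewer genes, then
#' lexicographic candidate order, so serial, multi-worker and chunked runs
#' are bit-identical. Non-convergent (separation) fits are skipped, never
#' scored.
#'
#' @param cohort the training \linkS4class{SurvivalCohort}.
#' @param screen a \linkS4class{ScreenResult} (or character vector of
#'   candidate gene IDs).
#' @param maxSize largest signature size (default 3).
#' @param workers number of parallel workers (forked; result is
#'   independent of this value).
#' @param nChunks number of deterministic chunks (default
#'   \code{workers}); the chunking never affects the result.
#' @param chunk optional \code{c(i, w)} to evaluate only one chunk of the
#'   traversal (resumable runs); see \code{\link{mergeSearchResults}}.
#' @return a \linkS4class{SearchResult} (for \code{chunk}, a partial one
#'   whose counters cover that chunk only).
#' @export
exhaustiveSearch <- function(cohort, screen, maxSize = 3L, workers = 1L,
                             nChunks = workers, chunk = NULL) {
  candidates <- if (is(screen, "ScreenResult")) screen@candidates
  else as.character(screen)
  if (!length(candidates)) stop("no candidate genes to search over")
  m <- length(candidates)
  if (maxSize > m) {
    warning("maxSize exceeds candidate count; capped at ", m)
    maxSize <- as.integer(m)
  }
  prep <- .coxPrep(survivalTime(cohort), eventStatus(cohort))
  Xall <- t(exprValues(cohort)[candidates, , drop = FALSE])[prep$ord, ,
                                                            drop = FALSE]
  status <- prep$status
  total <- combinationCount(m, maxSize)

  ranges <- if (!is.null(chunk)) list(.chunkRange(total, chunk[1L],
                                                  chunk[2L]))
  else lapply(seq_len(max(1L, nChunks)), .chunkRange,
              total = total, w = max(1L, nChunks))
  worker <- function(rng) .searchChunk(rng, m, maxSize, prep, Xall, status)
  parts <- if (workers > 1L)
    parallel::mclapply(ranges, worker, mc.cores = workers)
  else lapply(ranges, worker)

  best <- NULL
  per.size <- vector("list", maxSize)
  n.skip <- 0
  for (part in parts) {
    n.skip <- n.skip + part$nSkip
    if (!is.null(part$best) && .betterThan(part$best, best))
      best <- part$best
    for (k in seq_len(maxSize))
      if (!is.null(part$perSize[[k]]) &&
          .betterThan(part$perSize[[k]], per.size[[k]]))
        per.size[[k]] <- part$perSize[[k]]
  }
  n.enum <- if (!is.null(chunk))
    ranges[[1L]][2L] - ranges[[1L]][1L] + 1 else total
  if (is.null(best))
    stop("every combination was skipped as non-convergent")
  as.model <- function(x) new("SignatureModel",
                              geneIds = candidates[x$idx],
                              coefficients = as.numeric(x$coef),
                              trainingAUC = x$auc, name = "best")
  psb <- Filter(Negate(is.null), per.size)
  names(psb) <- vapply(psb, function(x) as.character(length(x$idx)),
                       character(1))
  new("SearchResult", best = as.model(best), nEnumerated = n.enum,
      nSkippedNonConverged = n.skip,
      perSizeBest = lapply(psb, as.model))
}

#' Merge chunked search results
#'
#' Combines partial \linkS4class{SearchResult}s produced with the
#' \code{chunk} argument of \code{\link{exhaustiveSearch}} into the result
#' a monolithic run would produce.
#'
#' @param results list of \linkS4class{SearchResult}s.
#' @return a \linkS4class{SearchResult}.
#' @export
mergeSearchResults <- function(results) {
  stopifnot(length(results) >= 1L)
  to.cand <- function(m) list(auc = m@trainingAUC, idx = NULL,
                              model = m)
  better.model <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a@trainingAUC != b@trainingAUC) return(a@trainingAUC > b@trainingAUC)
    if (length(a@geneIds) != length(b@geneIds))
      return(length(a@geneIds) < length(b@geneIds))
    d <- which(a@geneIds != b@geneIds)
    length(d) > 0 && a@geneIds[d[1L]] < b@geneIds[d[1L]]
  }
  best <- NULL
  per.size <- list()
  n.enum <- 0; n.skip <- 0
  for (res in results) {
    n.enum <- n.enum + res@nEnumerated
    n.skip <- n.skip + res@nSkippedNonConverged
    if (better.model(res@best, best)) best <- res@best
    for (k in names(res@perSizeBest))
      if (is.null(per.size[[k]]) ||
          better.model(res@perSizeBest[[k]], per.size[[k]]))
        per.size[[k]] <- res@perSizeBest[[k]]
  }
  new("SearchResult", best = best, nEnumerated = n.enum,
      nSkippedNonConverged = n.skip,
      perSizeBest = per.size[order(as.integer(names(per.size)))])
}

#' Risk score of a signature on an expression matrix
#'
#' The risk score of sample i is \code{sum_g coef_g * E_gi} over the
#' signature genes, the linear predictor of the multivariate Cox model.
#' All signature genes must be present; use
#' \code{\link{projectSignature}} for platforms missing some genes.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param data a genes-by-samples matrix or \linkS4class{SurvivalCohort}.
#' @return named numeric vector of per-sample scores.
#' @examples
#' mod <- new("SignatureModel",
#'            geneIds = c("LINC00426", "GTPBP4", "TREM1"),
#'            coefficients = c(-0.2466, 0.7675, 0.1726),
#'            trainingAUC = NA_real_, name = "threeRNA")
#' E <- matrix(c(2, 3, 1), 3, dimnames = list(signatureGenes(mod), "S1"))
#' riskScore(mod, E)   # 1.9819
#' @export
setGeneric("riskScore", function(model, data) standardGeneric("riskScore"))

#' @rdname riskScore
#' @export
setMethod("riskScore", signature("SignatureModel", "matrix"),
          function(model, data) {
            missing.genes <- setdiff(model@geneIds, rownames(data))
            if (length(missing.genes))
              stop("gene(s) absent from expression data: ",
                   paste(missing.genes, collapse = ", "),
                   "; use projectSignature() for partial platforms")
            drop(crossprod(data[model@geneIds, , drop = FALSE],
                           model@coefficients))
          })

#' @rdname riskScore
#' @export
setMethod("riskScore", signature("SignatureModel", "SurvivalCohort"),
          function(model, data) riskScore(model, exprValues(data)))
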