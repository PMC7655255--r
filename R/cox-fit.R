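# Cox proportional-hazards fitting by Newton-Raphson on the Efron
# tie-corrected log partial likelihood. Written from scratch: this engine
# (not a wrapper) is what the exhaustive signature search runs millions of
# times, so the per-iteration work is fully vectorized over untied event
# times (suffix cumulative sums give every risk-set aggregate in O(n));
# only tied death times take a short explicit loop.

# Pre-sort a cohort once so repeated fits (screening, search) skip the
# O(n log n) ordering. `X` rows are samples here.
.coxPrep <- function(time, status, X = NULL) {
  ord <- order(time)
  time <- time[ord]
  status <- as.numeric(status[ord])
  # first position sharing each time value = start of that risk set
  first <- match(time, time)
  ev <- which(status == 1)
  list(time = time, status = status, ord = ord, first = first, ev = ev,
       X = if (!is.null(X)) X[ord, , drop = FALSE])
}

# Log partial likelihood, score and information at `beta` on prepped data.
# Efron ties: for a group of d deaths at one time, the l-th factor
# (l = 0..d-1) subtracts l/d of the deaths' own weight from the risk-set
# sums; Breslow sets that fraction to 0.
.coxLLK <- function(prep, X, beta, ties = "efron", gradient = TRUE) {
  n <- length(prep$time)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta.c <- eta - max(eta)               # shift-invariant; avoids overflow
  w <- exp(eta.c)
  S0 <- revcumsum(w)

  ev <- prep$ev
  if (!length(ev)) stop("no events in data")
  fi <- prep$first[ev]
  # split event positions into untied and tied groups
  grp <- fi                              # group key = risk-set start
  dup <- duplicated(grp) | duplicated(grp, fromLast = TRUE)
  ll <- sum(eta.c[ev])
  U <- NULL; H <- NULL
  if (gradient) {
    WX <- w * X
    S1 <- apply(WX, 2L, function(col) rev(cumsum(rev(col))))
    S1 <- matrix(S1, nrow = n)
    XX <- X[, rep(seq_len(p), each = p), drop = FALSE] *
      X[, rep(seq_len(p), times = p), drop = FALSE]
    WXX <- w * XX
    S2 <- apply(WXX, 2L, function(col) rev(cumsum(rev(col))))
    S2 <- matrix(S2, nrow = n)
    U <- numeric(p); H <- matrix(0, p, p)
  }

  # untied events: fully vectorized
  u.ev <- ev[!dup]
  if (length(u.ev)) {
    ufi <- prep$first[u.ev]
    s0 <- S0[ufi]
    ll <- ll - sum(log(s0))
    if (gradient) {
      xbar <- S1[ufi, , drop = FALSE] / s0
      U <- U + colSums(X[u.ev, , drop = FALSE] - xbar)
      H <- H + matrix(colSums(S2[ufi, , drop = FALSE] / s0), p, p) -
        crossprod(xbar)
    }
  }

  # tied events: loop over death-time groups
  t.ev <- ev[dup]
  if (length(t.ev)) {
    for (g in split(t.ev, prep$first[t.ev])) {
      d <- length(g)
      start <- prep$first[g[1L]]
      s0r <- S0[start]
      s0d <- sum(w[g])
      if (gradient) {
        s1r <- S1[start, ]
        s2r <- S2[start, ]
        s1d <- colSums(WX[g, , drop = FALSE])
        s2d <- colSums(WXX[g, , drop = FALSE])
      }
      fracs <- if (ties == "breslow") rep(0, d) else (seq_len(d) - 1) / d
      for (frac in fracs) {
        den <- s0r - frac * s0d
        ll <- ll - log(den)
        if (gradient) {
          xb <- (s1r - frac * s1d) / den
          U <- U - xb
          H <- H + matrix((s2r - frac * s2d) / den, p, p) - tcrossprod(xb)
        }
      }
      if (gradient)
        U <- U + colSums(X[g, , drop = FALSE])
    }
  }
  list(ll = ll, U = U, H = H)
}

# Newton-Raphson with step-halving and a monotone-likelihood guard.
.coxEngine <- function(time, status, X, ties = c("efron", "breslow"),
                       maxIter = 30L, tol = 1e-8, prep = NULL) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(prep)) prep <- .coxPrep(time, status, X)
  Xs <- if (!is.null(prep$X)) prep$X else X
  n <- length(prep$time)
  p <- ncol(Xs)
  if (sum(prep$status) < 1) stop("no events in data")

  # zero-variance covariates are unidentifiable: pin their beta at 0
  keep <- apply(Xs, 2L, function(col) max(col) > min(col))
  beta <- numeric(p)
  se <- rep(NA_real_, p)
  converged <- TRUE
  iter <- 0L
  ll <- NA_real_

  if (any(keep)) {
    Xk <- Xs[, keep, drop = FALSE]
    pk <- ncol(Xk)
    bk <- numeric(pk)
    cur <- .coxLLK(prep, Xk, bk, ties = ties)
    repeat {
      iter <- iter + 1L
      delta <- tryCatch(solve(cur$H, cur$U), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        converged <- FALSE
        break
      }
      step <- delta
      new.b <- bk + step
      new <- .coxLLK(prep, Xk, new.b, ties = ties)
      halvings <- 0L
      while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) &&
             halvings < 20L) {
        step <- step / 2
        new.b <- bk + step
        new <- .coxLLK(prep, Xk, new.b, ties = ties)
        halvings <- halvings + 1L
      }
      if (!is.finite(new$ll)) {
        converged <- FALSE
        break
      }
      moved <- max(abs(new.b - bk))
      bk <- new.b
      cur <- new
      if (any(abs(bk) > 20)) {          # monotone likelihood / separation
        converged <- FALSE
        break
      }
      if (max(abs(cur$U)) < tol || moved < tol) break
      if (iter >= maxIter) {
        converged <- FALSE
        break
      }
    }
    beta[keep] <- bk
    ll <- cur$ll
    if (converged) {
      inv <- tryCatch(solve(cur$H), error = function(e) NULL)
      if (is.null(inv) || any(diag(inv) <= 0)) converged <- FALSE
      else {
        se[keep] <- sqrt(diag(as.matrix(inv)))
        # a flat likelihood ridge (se exploding in log-hazard units) is
        # monotone likelihood that stalled just inside the |beta| bound
        if (any(se[keep] > 100)) converged <- FALSE
      }
    }
  } else {
    ll <- .coxLLK(prep, Xs[, 1L, drop = FALSE] * 0, 0,
                  ties = ties, gradient = FALSE)$ll
  }
  z <- beta / se
  list(coef = unname(beta), se = unname(se), z = unname(z),
       p = unname(2 * pnorm(-abs(z))), loglik = unname(ll),
       converged = converged, iter = iter)
}

#' Fit a Cox proportional-hazards model on cohort genes
#'
#' Maximizes the Efron tie-corrected log partial likelihood by
#' Newton-Raphson with step-halving. Convergence requires the maximal
#' score component or parameter change to fall below \code{tol} within
#' \code{maxIter} iterations; a coefficient diverging past |beta| > 20
#' signals monotone likelihood (perfect separation) and the fit is flagged
#' non-convergent so that downstream search can skip it deterministically.
#' Wald statistics are z = beta/SE with two-sided normal P-values.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param geneIds ordered character vector of genes to use as covariates;
#'   at most \code{ncol(cohort)/5} genes (overfit guard; a single
#'   covariate is always allowed).
#' @param ties \code{"efron"} (default) or \code{"breslow"} tie handling;
#'   the two coincide on tie-free data.
#' @param maxIter,tol Newton-Raphson controls.
#' @return a \linkS4class{CoxFit}.
#' @examples
#' coh <- simulateCohort(nSamples = 120, nGenes = 5, plantedGenes = 1,
#'                       plantedBetas = 1, censorRate = 0.2, seed = 3)
#' fitCox(coh, rownames(coh)[1])
#' @export
fitCox <- function(cohort, geneIds, ties = c("efron", "breslow"),
                   maxIter = 30L, tol = 1e-8) {
  ties <- match.arg(ties)
  stopifnot(is(cohort, "SurvivalCohort"))
  geneIds <- as.character(geneIds)
  missing.genes <- setdiff(geneIds, rownames(cohort))
  if (length(missing.genes))
    stop("gene(s) not in cohort: ", paste(missing.genes, collapse = ", "))
  if (length(geneIds) > max(1, ncol(cohort) / 5))
    stop("too many covariates for the sample size (limit n/5)")
  X <- t(exprValues(cohort)[geneIds, , drop = FALSE])
  fit <- .coxEngine(survivalTime(cohort), eventStatus(cohort), X,
                    ties = ties, maxIter = maxIter, tol = tol)
  new("CoxFit", geneIds = geneIds, coefficients = fit$coef, se = fit$se,
      waldZ = fit$z, waldP = fit$p, logLik = fit$loglik,
      converged = fit$converged, nIter = fit$iter)
}
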