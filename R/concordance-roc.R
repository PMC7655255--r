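#' Harrell's concordance index for censored survival data
#'
#' A pair (i, j) is comparable iff \code{t_i < t_j} and subject i died
#' (the shorter time must be an observed event); tied event times are not
#' comparable. A comparable pair is concordant when the earlier death has
#' the higher risk score; risk-score ties count 0.5. The standard error
#' uses a Noether-type normal approximation over comparable pairs, the 95\%
#' CI is \code{c +/- 1.96 SE} truncated to [0, 1], and the P-value tests
#' c = 0.5.
#'
#' @param times follow-up times.
#' @param events 0/1 death indicators.
#' @param riskScores higher = predicted to die earlier.
#' @return an object of class \code{"concordanceResult"}: list with
#'   \code{cIndex}, \code{comparablePairs}, \code{concordant} (ties counted
#'   0.5), \code{se}, \code{ciLow}, \code{ciHigh}, \code{pValue}.
#' @examples
#' concordanceIndex(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))$cIndex  # 1
#' @export
concordanceIndex <- function(times, events, riskScores) {
  n <- length(times)
  if (length(events) != n || length(riskScores) != n)
    stop("times, events and riskScores must have equal length")
  events <- as.numeric(events)
  # comparable[i, j]: i dies strictly before j's (event or censoring) time
  comp <- outer(times, times, "<") & (events == 1)
  disc <- outer(riskScores, riskScores, ">")
  tied <- outer(riskScores, riskScores, "==")
  n.pairs <- sum(comp)
  if (n.pairs == 0) stop("no comparable pairs")
  conc <- sum(comp & disc) + 0.5 * sum(comp & tied)
  c.index <- conc / n.pairs
  se <- sqrt(c.index * (1 - c.index) / n.pairs)
  z <- if (se > 0) (c.index - 0.5) / se else 0
  structure(list(cIndex = c.index, comparablePairs = n.pairs,
                 concordant = conc, se = se,
                 ciLow = max(0, c.index - 1.96 * se),
                 ciHigh = min(1, c.index + 1.96 * se),
                 pValue = 2 * pnorm(-abs(z))),
            class = "concordanceResult")
}

#' @export
print.concordanceResult <- function(x, ...) {
  cat(sprintf("C-index = %.3f (95%% CI %.3f-%.3f), P = %.3g over %d pairs\n",
              x$cIndex, x$ciLow, x$ciHigh, x$pValue, x$comparablePairs))
  invisible(x)
}

# Fast AUC (Mann-Whitney with ties counted 0.5) without CI machinery;
# this is the inner loop of the exhaustive search.
.aucFast <- function(labels, scores) {
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' Binary ROC-AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen positive
#' (death) outscores a randomly chosen negative, ties counted 0.5. The
#' variance uses DeLong's structural-component estimator; the 95\% CI is
#' normal-approximation based and the P-value tests AUC = 0.5.
#'
#' @param labels 0/1 class labels (1 = positive/death).
#' @param scores real-valued predictor (the risk score).
#' @return an object of class \code{"rocResult"}: list with \code{auc},
#'   \code{ciLow}, \code{ciHigh}, \code{pValue}, \code{nPositive},
#'   \code{nNegative}.
#' @examples
#' rocAUC(c(1, 0, 1, 0), c(0.9, 0.8, 0.1, 0.2))$auc  # 0.5
#' @export
rocAUC <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("both classes must be present")
  auc <- .aucFast(labels, scores)
  # DeLong structural components: V10 per positive, V01 per negative
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- if (se > 0) (auc - 0.5) / se else 0
  structure(list(auc = auc, se = se,
                 ciLow = max(0, auc - 1.96 * se),
                 ciHigh = min(1, auc + 1.96 * se),
                 pValue = 2 * pnorm(-abs(z)),
                 nPositive = m, nNegative = n),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f (95%% CI %.3f-%.3f), P = %.3g (%d positives, %d negatives)\n",
    x$auc, x$ciLow, x$ciHigh, x$pValue, x$nPositive, x$nNegative))
  invisible(x)
}
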