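#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function as the running product of
#' \code{(1 - d_j / n_j)} over distinct event times, where \code{d_j} is
#' the number of deaths and \code{n_j} the number at risk at the j-th
#' event time. Censored observations leave the risk set without
#' contributing a factor.
#'
#' @param times positive follow-up times.
#' @param events 0/1 death indicators aligned with \code{times}.
#' @return an object of class \code{"kmCurve"}: a list with
#'   \code{eventTimes}, \code{nAtRisk}, \code{nEvents} and \code{survival}
#'   (all aligned over distinct event times).
#' @examples
#' km <- kmEstimate(c(5, 10, 15), c(0, 1, 1))
#' km$survival   # 0.5 at t=10, 0 at t=15
#' @export
kmEstimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(times <= 0)) stop("times must be positive")
  events <- as.numeric(events)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) < 1) stop("at least one event is required")
  te <- sort(unique(times[events == 1]))
  sorted <- sort(times)
  n.at.risk <- length(times) - findInterval(te, sorted, left.open = TRUE)
  d <- tabulate(match(times[events == 1], te), nbins = length(te))
  surv <- cumprod(1 - d / n.at.risk)
  structure(list(eventTimes = te, nAtRisk = n.at.risk, nEvents = d,
                 survival = surv), class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$eventTimes), "event times\n")
  print(data.frame(time = x$eventTimes, n.risk = x$nAtRisk,
                   n.event = x$nEvents, survival = x$survival))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a \code{"kmCurve"}.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities (1 before the first event).
#' @export
kmSurvivalAt <- function(km, t) {
  idx <- findInterval(t, km$eventTimes)
  c(1, km$survival)[idx + 1L]
}

#' Two-group log-rank test
#'
#' At every distinct event time the observed number of deaths in group 1
#' is compared with its hypergeometric expectation given the pooled risk
#' set; the squared summed difference over the summed variance is
#' chi-square with 1 degree of freedom under the null of equal hazards.
#'
#' @param times1,events1 follow-up and 0/1 death indicator, group 1.
#' @param times2,events2 same for group 2.
#' @return an object of class \code{"logrankResult"}: list with
#'   \code{chiSquare}, \code{df}, \code{pValue}, \code{observed} and
#'   \code{expected} (group-1 counts).
#' @export
logrankTest <- function(times1, events1, times2, events2) {
  if (!length(times1) || !length(times2))
    stop("both groups must be nonempty")
  events1 <- as.numeric(events1); events2 <- as.numeric(events2)
  if (sum(events1) + sum(events2) < 1)
    stop("at least one event is required")
  all.times <- c(times1, times2)
  all.events <- c(events1, events2)
  te <- sort(unique(all.times[all.events == 1]))
  s1 <- sort(times1); sa <- sort(all.times)
  n1 <- length(times1) - findInterval(te, s1, left.open = TRUE)
  n <- length(all.times) - findInterval(te, sa, left.open = TRUE)
  d1 <- tabulate(match(times1[events1 == 1], te), nbins = length(te))
  d <- tabulate(match(all.times[all.events == 1], te), nbins = length(te))
  expected <- d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  V <- sum(v)
  O <- sum(d1); E <- sum(expected)
  if (V <= 0) {
    warning("zero log-rank variance; no comparable structure")
    chi <- 0; p <- 1
  } else {
    chi <- (O - E)^2 / V
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(chiSquare = chi, df = 1L, pValue = p,
                 observed = O, expected = E, variance = V),
            class = "logrankResult")
}

#' @export
print.logrankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, P = %.4g\n",
              x$chiSquare, x$df, x$pValue))
  cat(sprintf("  group 1: observed %.0f vs expected %.2f deaths\n",
              x$observed, x$expected))
  invisible(x)
}
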