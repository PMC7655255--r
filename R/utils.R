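#' @importFrom stats rnorm rexp rbinom runif pchisq pnorm pt qnorm sd var
#'   uniroot t.test cor median
#' @importFrom utils read.delim write.table combn head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never clobber user state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed)
      old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has.seed)
        assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derivation from one root seed, kept below
# 2^31 so it is always a valid R integer.
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

vlog <- function(..., verbose = TRUE, logfile = NULL) {
  msg <- paste0(...)
  if (isTRUE(verbose)) message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  invisible(msg)
}

# Suffix (reverse cumulative) sums, the risk-set aggregation primitive.
revcumsum <- function(x) rev(cumsum(rev(x)))
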