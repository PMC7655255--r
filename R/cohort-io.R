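#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header row holds sample identifiers; every body cell must be a
#' non-negative number. Unless \code{alreadyLog = TRUE} every raw value
#' \code{v} is normalized as \code{log2(v + 1)}, the standard transform for
#' upper-quartile-normalized RNA-seq abundances (FPKM-UQ). Array data that
#' arrive already on a log scale should be read with
#' \code{alreadyLog = TRUE} and are used as-is.
#'
#' @param path path to the TSV file.
#' @param alreadyLog logical; if TRUE the values are taken to be on the log
#'   scale already and are not re-transformed.
#' @return a numeric matrix (genes in rows) of log-scale expression.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "G1\t3\t0", "G2\t1023\t1"), tf)
#' readExpression(tf)   # log2(x+1): 2 and 0; 10 and 1
#' @export
readExpression <- function(path, alreadyLog = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file needs a gene-ID column plus at least one sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in expression file: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in expression header")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow = nrow(mat)))) & !is.na(mat),
      arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                   genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
    mat <- matrix(as.numeric(mat), nrow = nrow(mat))
  }
  nas <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(nas))
    stop(sprintf("missing/malformed expression cell at gene '%s', sample '%s'",
                 genes[nas[1L, 1L]], samples[nas[1L, 2L]]))
  if (any(mat < 0))
    stop("negative expression values are not allowed")
  dimnames(mat) <- list(genes, samples)
  if (!alreadyLog) mat <- log2(mat + 1)
  mat
}

.mapEnum <- function(x, levels, strip = NULL) {
  x <- trimws(as.character(x))
  if (!is.null(strip)) x <- sub(strip, "", x, ignore.case = TRUE)
  x[is.na(x) | x == "" | toupper(x) == "NA"] <- "unknown"
  low <- tolower(x)
  out <- levels[match(low, tolower(levels))]
  out[is.na(out)] <- "unknown"
  out
}

#' Read a clinical table from TSV
#'
#' Expects columns \code{sample_id}, \code{time_days}, \code{event},
#' \code{gender}, \code{stage}, \code{grade}, \code{age}; the token
#' \code{"NA"} (or an empty cell) encodes unknown. Rows with missing
#' survival time or event are dropped and counted in the
#' \code{"nDropped"} attribute, mirroring the usual exclusion of
#' survival-time-missing specimens during cohort assembly. Stage accepts
#' either \code{"II"} or \code{"Stage II"}; grade \code{"G1"}..\code{"G4"}.
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}, \code{gender}, \code{stage}, \code{grade}, \code{age};
#'   attribute \code{nDropped} counts removed rows.
#' @export
readClinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "time_days", "event")
  missing.cols <- setdiff(need, colnames(df))
  if (length(missing.cols))
    stop("clinical file lacks column(s): ",
         paste(missing.cols, collapse = ", "))
  time <- suppressWarnings(as.numeric(df$time_days))
  event <- suppressWarnings(as.numeric(df$event))
  keep <- !is.na(time) & !is.na(event)
  n.dropped <- sum(!keep)
  if (n.dropped)
    message(n.dropped, " clinical row(s) dropped for missing time/event")
  df <- df[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (!nrow(df)) {
    warning("no valid clinical rows after dropping incomplete records")
    out <- data.frame(sample_id = character(), time = numeric(),
                      event = numeric(), gender = character(),
                      stage = character(), grade = character(),
                      age = numeric(), stringsAsFactors = FALSE)
    attr(out, "nDropped") <- n.dropped
    return(out)
  }
  if (any(time <= 0))
    stop("survival time must be strictly positive (days)")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored/alive) or 1 (death)")
  getcol <- function(nm) if (nm %in% colnames(df)) df[[nm]] else NA
  age <- suppressWarnings(as.numeric(getcol("age")))
  if (any(!is.na(age) & age < 0)) stop("age must be >= 0")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    time = time, event = event,
    gender = .mapEnum(getcol("gender"), .GENDER_LEVELS),
    stage = .mapEnum(getcol("stage"), .STAGE_LEVELS, strip = "^stage[ _]*"),
    grade = .mapEnum(getcol("grade"), .GRADE_LEVELS),
    age = age, stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in clinical file")
  attr(out, "nDropped") <- n.dropped
  out
}

#' Construct a SurvivalCohort
#'
#' Joins an expression matrix with clinical records on the intersection of
#' their sample identifiers; samples present in only one input are dropped
#' with a message. \code{SurvivalCohort} is the low-level constructor used
#' by \code{assembleCohort} and the simulator.
#'
#' @param expression numeric genes-by-samples matrix, log scale, >= 0.
#' @param clinical data.frame as returned by \code{\link{readClinical}}
#'   (columns \code{sample_id}, \code{time}, \code{event}, optionally
#'   \code{gender}, \code{stage}, \code{grade}, \code{age}).
#' @return a \linkS4class{SurvivalCohort}.
#' @export
assembleCohort <- function(expression, clinical) {
  common <- intersect(colnames(expression), clinical$sample_id)
  if (!length(common))
    stop("expression and clinical tables share no sample identifiers")
  n.expr.only <- ncol(expression) - length(common)
  n.clin.only <- nrow(clinical) - length(common)
  if (n.expr.only || n.clin.only)
    message("dropping ", n.expr.only, " expression-only and ", n.clin.only,
            " clinical-only sample(s)")
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  SurvivalCohort(expression[, common, drop = FALSE], clin)
}

#' @rdname assembleCohort
#' @export
SurvivalCohort <- function(expression, clinical) {
  stopifnot(is.matrix(expression), is.data.frame(clinical))
  if (!identical(colnames(expression), clinical$sample_id))
    stop("expression columns and clinical sample_id must match in order")
  fill <- function(nm, default) {
    if (nm %in% colnames(clinical)) clinical[[nm]] else
      rep(default, nrow(clinical))
  }
  cd <- DataFrame(
    time = as.numeric(clinical$time),
    event = as.numeric(clinical$event),
    gender = fill("gender", "unknown"),
    stage = fill("stage", "unknown"),
    grade = fill("grade", "unknown"),
    age = as.numeric(fill("age", NA_real_)),
    row.names = clinical$sample_id)
  new("SurvivalCohort", SummarizedExperiment(
    assays = list(exprs = expression), colData = cd))
}

#' Prevalence filter: drop genes that are mostly zero
#'
#' A gene is retained iff its expression is nonzero (> 0) in at least
#' \code{ceiling(minNonzeroFraction * n)} of the \code{n} samples; the
#' default fraction 0.5 implements the "nonzero in at least half of the
#' specimens" rule. The number of retained genes is attached as attribute
#' \code{"nRetained"}. The filter is idempotent.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param minNonzeroFraction minimum fraction of samples with value > 0.
#' @return the filtered \linkS4class{SurvivalCohort}.
#' @export
filterLowExpression <- function(cohort, minNonzeroFraction = 0.5) {
  x <- exprValues(cohort)
  need <- ceiling(minNonzeroFraction * ncol(x))
  keep <- rowSums(x > 0) >= need
  if (!any(keep))
    stop("prevalence filter removed every gene")
  out <- cohort[keep, ]
  attr(out, "nRetained") <- sum(keep)
  out
}

#' Random train/validation split
#'
#' Simple random (unstratified) allocation without replacement: the
#' training part receives \code{round(n * trainFraction)} samples and the
#' validation part the remainder; the two parts partition the cohort and
#' the allocation is reproducible under \code{seed}.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param trainFraction proportion in (0, 1).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{validation}.
#' @export
splitCohort <- function(cohort, trainFraction = 0.5, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  n <- ncol(cohort)
  n.train <- round(n * trainFraction)
  if (n.train < 1L || n.train >= n)
    stop("split would leave an empty part")
  idx <- withSeed(seed, sample.int(n, n.train))
  list(train = cohort[, sort(idx)],
       validation = cohort[, sort(setdiff(seq_len(n), idx))])
}

#' Write cohort inputs back to the TSV interchange formats
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param exprPath,clinPath output file paths (either may be NULL to skip).
#' @return invisibly, the cohort.
#' @export
writeCohort <- function(cohort, exprPath = NULL, clinPath = NULL) {
  if (!is.null(exprPath)) {
    df <- data.frame(gene = rownames(cohort),
                     exprValues(cohort), check.names = FALSE)
    write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(clinPath)) {
    cd <- clinicalData(cohort)
    df <- data.frame(sample_id = rownames(cd), time_days = cd$time,
                     event = cd$event, gender = cd$gender, stage = cd$stage,
                     grade = cd$grade, age = cd$age, check.names = FALSE)
    write.table(df, clinPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}
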