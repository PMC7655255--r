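test_that("expression reader normalizes log2(x+1) and validates input", {
  tf <- writeTempTSV(c("gene\tS1\tS2\tS3",
                       "G1\t0\t3\t1023",
                       "G2\t1\t7\t15"))
  m <- readExpression(tf)
  expect_equal(unname(m["G1", ]), c(0, 2, 10))
  expect_equal(unname(m["G2", ]), c(1, 3, 4))
  # monotone: raw order preserved after the transform
  raw <- c(0.3, 2, 5, 100)
  expect_true(all(diff(log2(raw + 1)) > 0))

  m2 <- readExpression(tf, alreadyLog = TRUE)
  expect_equal(unname(m2["G1", ]), c(0, 3, 1023))

  expect_error(readExpression(writeTempTSV(
    c("gene\tS1", "G1\t2", "G1\t3"))), "duplicate gene")
  expect_error(readExpression(writeTempTSV(
    c("gene\tS1\tS1", "G1\t2\t3"))), "duplicate sample")
  expect_error(readExpression(writeTempTSV(
    c("gene\tS1\tS2", "G1\t2\toops"))), "G1.*S2")
  expect_error(readExpression(writeTempTSV(
    c("gene\tS1", "G1\t-4"))), "negative")
})

test_that("clinical reader drops incomplete rows and maps enums", {
  tf <- writeTempTSV(c(
    "sample_id\ttime_days\tevent\tgender\tstage\tgrade\tage",
    "A\t100\t1\tMale\tStage II\tG3\t61",
    "B\t\t1\tfemale\tI\tG1\t70",
    "C\t250\t0\tNA\tStage IV\tNA\tNA"))
  expect_message(clin <- readClinical(tf), "1 clinical row")
  expect_equal(nrow(clin), 2L)
  expect_equal(attr(clin, "nDropped"), 1L)
  expect_equal(clin$stage, c("II", "IV"))
  expect_equal(clin$gender, c("male", "unknown"))
  expect_equal(clin$grade, c("G3", "unknown"))

  expect_error(readClinical(writeTempTSV(
    c("sample_id\ttime_days\tevent", "A\t-5\t1"))), "positive")
  expect_error(readClinical(writeTempTSV(
    c("sample_id\ttime_days\tevent", "A\t10\t2"))), "event")
  expect_warning(empty <- readClinical(writeTempTSV(
    c("sample_id\ttime_days\tevent", "A\t\t1"))), "no valid")
  expect_equal(nrow(empty), 0L)
})

test_that("cohort assembly intersects samples and validates the object", {
  expr <- matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"),
                                            c("A", "B", "C")))
  clin <- data.frame(sample_id = c("B", "C", "D"),
                     time = c(10, 20, 30), event = c(1, 0, 1))
  expect_message(coh <- assembleCohort(expr, clin), "dropping 1.*1")
  expect_equal(colnames(coh), c("B", "C"))
  expect_equal(survivalTime(coh), c(10, 20))
  expect_equal(eventStatus(coh), c(1, 0))

  clin2 <- data.frame(sample_id = c("X", "Y"), time = 1:2, event = c(1, 1))
  expect_error(assembleCohort(expr, clin2), "share no sample")

  # validity: zero events rejected
  clin3 <- data.frame(sample_id = c("A", "B", "C"),
                      time = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(SurvivalCohort(expr, clin3), "at least one event")
  # negative expression rejected
  expr.bad <- expr; expr.bad[1, 1] <- -1
  clin4 <- data.frame(sample_id = c("A", "B", "C"),
                      time = c(1, 2, 3), event = c(1, 0, 0))
  expect_error(SurvivalCohort(expr.bad, clin4), ">= 0")
})

test_that("prevalence filter keeps genes nonzero in at least half and is idempotent", {
  expr <- rbind(G1 = c(1, 2, 0, 0),   # 2 of 4 -> kept (2 >= 2)
                G2 = c(1, 0, 0, 0),   # 1 of 4 -> removed
                G3 = c(1, 1, 1, 1))   # all -> kept
  colnames(expr) <- paste0("S", 1:4)
  coh <- makeToyCohort(expr, time = c(5, 6, 7, 8), event = c(1, 1, 0, 0))
  f1 <- filterLowExpression(coh)
  expect_setequal(rownames(f1), c("G1", "G3"))
  expect_equal(attr(f1, "nRetained"), 2L)
  f2 <- filterLowExpression(f1)
  expect_equal(rownames(f2), rownames(f1))
  expect_equal(exprValues(f2), exprValues(f1))

  all.zero <- makeToyCohort(rbind(G1 = c(1, 0, 0, 0)),
                            time = c(5, 6, 7, 8), event = c(1, 1, 0, 0))
  expect_error(filterLowExpression(all.zero), "every gene")
})

test_that("cohort split is a seeded partition with round(n*f) sizing", {
  coh <- simulateCohort(nSamples = 10, nGenes = 5, plantedGenes = 1,
                        plantedBetas = 0.5, seed = 2)
  sp <- splitCohort(coh, 0.5, seed = 11)
  expect_equal(ncol(sp$train), 5L)
  expect_equal(ncol(sp$validation), 5L)
  expect_length(intersect(colnames(sp$train), colnames(sp$validation)), 0)
  expect_setequal(c(colnames(sp$train), colnames(sp$validation)),
                  colnames(coh))

  sp2 <- splitCohort(coh, 0.5, seed = 11)
  expect_identical(colnames(sp2$train), colnames(sp$train))
  sp3 <- splitCohort(coh, 0.5, seed = 12)
  expect_false(identical(colnames(sp3$train), colnames(sp$train)))

  # round(n*f) rule: 370 samples at f = 0.5 give 185/185
  big <- simulateCohort(nSamples = 370, nGenes = 2, plantedGenes = 1,
                        plantedBetas = 0.5, seed = 3)
  spb <- splitCohort(big, 0.5, seed = 1)
  expect_equal(ncol(spb$train), 185L)
  expect_equal(ncol(spb$validation), 185L)

  expect_error(splitCohort(coh, 1.2), "between 0 and 1")
  tiny <- coh[, 1:2]
  expect_error(splitCohort(tiny, 0.01), "empty")
})

test_that("cohorts round-trip through the TSV writers", {
  coh <- simulateCohort(nSamples = 15, nGenes = 6, plantedGenes = 1,
                        plantedBetas = 1, seed = 4)
  ef <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  writeCohort(coh, ef, cf)
  back <- assembleCohort(readExpression(ef, alreadyLog = TRUE),
                         readClinical(cf))
  expect_equal(exprValues(back), exprValues(coh))
  expect_equal(survivalTime(back), survivalTime(coh))
  expect_equal(eventStatus(back), eventStatus(coh))
})
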