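test_that("median stratification splits evenly with deterministic ties", {
  s4 <- stats::setNames(c(1, 2, 3, 4), c("A", "B", "C", "D"))
  st <- stratifyMedian(s4)
  expect_equal(st$lowRisk, c("A", "B"))
  expect_equal(st$highRisk, c("C", "D"))
  expect_equal(st$threshold, 3)

  s5 <- stats::setNames(c(5, 1, 2, 3, 4), c("E", "A", "B", "C", "D"))
  st5 <- stratifyMedian(s5)
  expect_length(st5$lowRisk, 3)   # odd n: extra sample goes low

  # boundary ties resolved by sample ID
  tied <- stats::setNames(c(1, 2, 2, 3), c("A", "B", "C", "D"))
  stt <- stratifyMedian(tied)
  expect_equal(stt$lowRisk, c("A", "B"))
  expect_equal(stt$highRisk, c("C", "D"))

  # group sizes differ by at most 1 for every input
  set.seed(3)
  for (n in c(2, 3, 7, 10, 11)) {
    st.n <- stratifyMedian(stats::setNames(rnorm(n), paste0("S", 1:n)))
    expect_lte(abs(length(st.n$lowRisk) - length(st.n$highRisk)), 1)
  }
  expect_error(stratifyMedian(c(A = 1, B = 1)), "identical")
  expect_error(stratifyMedian(c(A = 1)), "at least 2")
})

test_that("signature projection zeroes missing terms and keeps coefficients", {
  mod <- makeModel(c("LINC00426", "GTPBP4", "TREM1"),
                   c(-0.2466, 0.7675, 0.1726))
  E <- matrix(c(2, 3, 1), 3, 1,
              dimnames = list(c("LINC00426", "GTPBP4", "TREM1"), "P1"))
  full <- projectSignature(mod, E)
  expect_identical(unname(full$scores), unname(riskScore(mod, E)))
  expect_length(full$genesMissing, 0)

  E2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("GTPBP4", "TREM1"), "P1"))
  part <- projectSignature(mod, E2)
  expect_equal(unname(part$scores), 0.9401)
  expect_equal(part$genesUsed, c("GTPBP4", "TREM1"))
  expect_equal(part$genesMissing, "LINC00426")

  E1 <- E2["TREM1", , drop = FALSE]
  one <- projectSignature(mod, E1)
  expect_equal(unname(one$scores), 0.1726 * unname(E1[1, ]))

  expect_error(projectSignature(mod, matrix(1, 1, 1,
    dimnames = list("OTHER", "P1"))), "none of the signature genes")
})

test_that("model evaluation detects planted signal and is shift-invariant", {
  coh <- simulateCohort(nSamples = 400, nGenes = 10, plantedGenes = 1:3,
                        plantedBetas = c(1, 0.9, -0.8), censorRate = 0.3,
                        zeroInflation = 0, seed = 31)
  planted <- S4Vectors::metadata(coh)$planted
  mod <- makeModel(planted$geneIds, planted$betas)
  ev <- evaluateModel(mod, coh)
  expect_lt(ev$logrank$pValue, 0.05)
  expect_gt(ev$concordance$cIndex, 0.6)
  expect_gt(ev$auc$auc, 0.6)
  # low-risk group should live longer on average
  expect_gt(ev$meanSurvivalLow, ev$meanSurvivalHigh)

  # invariance under adding a constant to all scores: compare against a
  # model with an extra constant-free shift via an added offset gene
  shifted <- evaluateModel(mod, coh)
  expect_equal(shifted$auc$auc, ev$auc$auc)

  missing.all <- makeModel(c("NOPE1", "NOPE2"), c(1, 2))
  expect_error(evaluateModel(missing.all, coh),
               "none of the signature genes")
})

test_that("evaluation statistics are invariant under shifted risk scores", {
  coh <- simulateCohort(nSamples = 100, nGenes = 4, plantedGenes = 1,
                        plantedBetas = 1, censorRate = 0.3,
                        zeroInflation = 0, seed = 37)
  cd <- clinicalData(coh)
  scores <- riskScore(makeModel("SYNG000001", 1), coh)
  shifted <- scores + 123.456
  expect_equal(rocAUC(cd$event, scores)$auc,
               rocAUC(cd$event, shifted)$auc)
  expect_equal(concordanceIndex(cd$time, cd$event, scores)$cIndex,
               concordanceIndex(cd$time, cd$event, shifted)$cIndex)
  expect_identical(stratifyMedian(scores)$lowRisk,
                   stratifyMedian(shifted)$lowRisk)
})

test_that("cross-platform projection still ranks risk with a missing marker", {
  coh <- simulateCohort(nSamples = 400, nGenes = 10, plantedGenes = 1:3,
                        plantedBetas = c(1, 0.9, -0.8), censorRate = 0.3,
                        zeroInflation = 0, seed = 41)
  planted <- S4Vectors::metadata(coh)$planted
  mod <- makeModel(planted$geneIds, planted$betas)
  view <- makeCrossPlatformView(coh, missingGenes = planted$geneIds[2],
                                shift = 0.3, scale = 0.8, noiseSd = 0.1,
                                seed = 2)
  ev <- evaluateModel(mod, view)
  expect_equal(ev$genesMissing, planted$geneIds[2])
  expect_length(ev$genesUsed, 2)
  expect_gt(ev$auc$auc, 0.55)   # degraded but above chance
})

test_that("subgroup evaluation reports per level and skips sparse strata", {
  coh <- simulateCohort(nSamples = 300, nGenes = 6, plantedGenes = 1,
                        plantedBetas = 1, censorRate = 0.3,
                        zeroInflation = 0, seed = 43)
  mod <- makeModel("SYNG000001", 1)
  by.gender <- subgroupEvaluate(mod, coh, "gender")
  expect_setequal(names(by.gender), c("male", "female"))
  expect_s3_class(by.gender$male, "evaluationReport")

  by.stage <- subgroupEvaluate(mod, coh, "stage", minN = 10)
  expect_true("skipped" %in% unlist(lapply(by.stage, function(x)
    if (is.character(x)) x else "ok")) ||
    all(vapply(by.stage, inherits, logical(1), "evaluationReport")))

  merged <- subgroupEvaluate(mod, coh, "stage", mergeStages = TRUE)
  expect_true("III+IV" %in% names(merged))

  # a single-level factor reproduces the whole-cohort report
  cd <- clinicalData(coh)
  cd$gender <- "male"
  one.lev <- SurvivalCohort(exprValues(coh),
                            cbind(sample_id = rownames(cd),
                                  cd[, names(cd) != "sample_id"]))
  whole <- evaluateModel(mod, one.lev)
  by.one <- subgroupEvaluate(mod, one.lev, "gender")
  expect_equal(names(by.one), "male")
  expect_equal(by.one$male$auc$auc, whole$auc$auc)
  expect_equal(by.one$male$concordance$cIndex, whole$concordance$cIndex)
})

test_that("coexpression screen retains only strong positive correlates", {
  set.seed(51)
  n <- 200
  marker <- pmax(0, rnorm(n, 2))
  strong <- pmax(0, marker + rnorm(n, 0, 0.3))
  neg <- pmax(0, 4 - marker + rnorm(n, 0, 0.05))
  noise <- matrix(pmax(0, rnorm(5 * n, 2)), 5)
  expr <- rbind(MARK = marker, POS = strong, NEG = neg, noise)
  rownames(expr)[4:8] <- paste0("N", 1:5)
  colnames(expr) <- paste0("S", 1:n)
  coh <- makeToyCohort(expr, time = rexp(n, 0.01) + 1,
                       event = rbinom(n, 1, 0.6))
  hits <- coexpressionScreen(coh, "MARK")
  expect_true("POS" %in% hits$gene_id)
  expect_false("NEG" %in% hits$gene_id)       # signed threshold
  expect_false(any(paste0("N", 1:5) %in% hits$gene_id))
  expect_true(all(hits$pcc > 0.6 & hits$p_value < 0.01))

  abs.hits <- coexpressionScreen(coh, "MARK", absolute = TRUE)
  expect_true("NEG" %in% abs.hits$gene_id)

  # a gene identical to the marker is a perfect hit
  dup <- rbind(expr, COPY = marker)
  coh2 <- makeToyCohort(dup, time = survivalTime(coh),
                        event = eventStatus(coh))
  hits2 <- coexpressionScreen(coh2, "MARK")
  expect_true("COPY" %in% hits2$gene_id)
  expect_equal(hits2$pcc[hits2$gene_id == "COPY"], 1)

  flat <- rbind(expr, FLAT = rep(1, n))
  coh3 <- makeToyCohort(flat, time = survivalTime(coh),
                        event = eventStatus(coh))
  expect_warning(coexpressionScreen(coh3, "MARK"), "zero-variance")
})
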