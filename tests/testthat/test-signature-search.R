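test_that("combination enumeration is complete, ordered and chunkable", {
  expect_equal(combinationCount(4, 3), 14)
  expect_equal(combinationCount(415, 3), 11912575)
  expect_equal(combinationCount(1, 3), 1)

  cand <- c("A", "B", "C", "D")
  all.combos <- enumerateCombinations(cand, 3)
  expect_length(all.combos, 14)
  expect_equal(anyDuplicated(vapply(all.combos, paste, character(1),
                                    collapse = "+")), 0L)
  # size-major, lexicographic within size
  expect_equal(all.combos[[1]], "A")
  expect_equal(all.combos[[5]], c("A", "B"))
  expect_equal(all.combos[[14]], c("B", "C", "D"))

  # chunks concatenate to the full stream for several chunk counts
  for (w in c(2, 3, 5, 14)) {
    parts <- unlist(lapply(seq_len(w), function(i)
      enumerateCombinations(cand, 3, chunk = c(i, w))),
      recursive = FALSE)
    expect_identical(parts, all.combos)
  }

  expect_warning(capped <- enumerateCombinations(c("A", "B"), 5), "capped")
  expect_length(capped, 3)
  expect_length(suppressWarnings(enumerateCombinations("A", 3)), 1)
})

test_that("univariate screen keeps planted signal and respects the threshold", {
  coh <- simulateCohort(nSamples = 500, nGenes = 40, plantedGenes = 1,
                        plantedBetas = 1, censorRate = 0.3,
                        zeroInflation = 0, seed = 12)
  sc <- univariateScreen(coh, 0.001)
  expect_true("SYNG000001" %in% sc@candidates)
  expect_true(all(sc@waldP < 0.001))
  expect_equal(sc@nTested, 40L)

  # threshold 1 retains every convergent gene
  all.sc <- univariateScreen(coh, 1)
  expect_equal(length(all.sc@candidates) + all.sc@nNonConverged, 40L)

  # stable input order
  expect_identical(sc@candidates,
                   intersect(rownames(coh), sc@candidates))
  expect_error(univariateScreen(coh, 0), "pThreshold")
  expect_error(univariateScreen(coh, 1e-300), "looser threshold")
})

test_that("risk scores implement the linear predictor", {
  mod <- makeModel(c("LINC00426", "GTPBP4", "TREM1"),
                   c(-0.2466, 0.7675, 0.1726))
  E <- matrix(c(2, 3, 1), 3, 1,
              dimnames = list(c("LINC00426", "GTPBP4", "TREM1"), "P1"))
  expect_equal(unname(riskScore(mod, E)), 1.9819)
  expect_equal(unname(riskScore(mod, E * 0)), 0)
  mod2 <- makeModel(signatureGenes(mod), 2 * signatureCoefficients(mod))
  expect_equal(riskScore(mod2, E), 2 * riskScore(mod, E))
  expect_error(riskScore(mod, E[1:2, , drop = FALSE]),
               "projectSignature")
})

test_that("combination evaluation scores convergent fits and skips separation", {
  coh <- simulateCohort(nSamples = 200, nGenes = 6, plantedGenes = 1,
                        plantedBetas = 1, censorRate = 0.3,
                        zeroInflation = 0, seed = 13)
  ev <- evaluateCombination(coh, "SYNG000001")
  expect_gt(ev$auc, 0.5)
  expect_true(ev$fit@converged)

  # separation-degenerate toy cohort yields the skip marker
  sep <- makeToyCohort(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE),
                       time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  expect_null(evaluateCombination(sep[1, ], "G01"))
})

test_that("exhaustive search equals the naive re-evaluation oracle", {
  coh <- simulateCohort(nSamples = 150, nGenes = 10, plantedGenes = 1:2,
                        plantedBetas = c(0.9, -0.7), censorRate = 0.3,
                        zeroInflation = 0, seed = 19)
  cand <- rownames(coh)
  res <- exhaustiveSearch(coh, cand, maxSize = 3)
  expect_equal(res@nEnumerated, combinationCount(10, 3))
  orc <- oracleSearch(coh, cand, 3)
  expect_setequal(res@best@geneIds, orc$genes)
  expect_equal(res@best@trainingAUC, orc$auc, tolerance = 1e-9)
  # best dominates every per-size best
  for (m in res@perSizeBest)
    expect_lte(m@trainingAUC, res@best@trainingAUC)
})

test_that("search is deterministic across workers, chunking and candidate order", {
  coh <- simulateCohort(nSamples = 120, nGenes = 9, plantedGenes = 1:2,
                        plantedBetas = c(0.8, -0.6), censorRate = 0.3,
                        zeroInflation = 0, seed = 23)
  cand <- rownames(coh)
  serial <- exhaustiveSearch(coh, cand, maxSize = 3, workers = 1)
  quad <- exhaustiveSearch(coh, cand, maxSize = 3, workers = 4)
  expect_identical(serial@best@geneIds, quad@best@geneIds)
  expect_identical(serial@best@trainingAUC, quad@best@trainingAUC)
  expect_identical(serial@nEnumerated, quad@nEnumerated)

  chunks <- lapply(1:5, function(i)
    exhaustiveSearch(coh, cand, maxSize = 3, chunk = c(i, 5)))
  merged <- mergeSearchResults(chunks)
  expect_identical(merged@best@geneIds, serial@best@geneIds)
  expect_identical(merged@best@trainingAUC, serial@best@trainingAUC)
  expect_identical(merged@nEnumerated, serial@nEnumerated)
  expect_identical(merged@nSkippedNonConverged,
                   serial@nSkippedNonConverged)

  # single candidate: the trivial best
  single <- suppressWarnings(exhaustiveSearch(coh, cand[1], maxSize = 3))
  expect_identical(single@best@geneIds, cand[1])
})
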