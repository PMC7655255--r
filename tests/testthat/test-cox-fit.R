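test_that("interleaved binary covariate reproduces the grid-oracle estimate", {
  # deaths alternate between groups: x=1 at t=1,3; x=0 at t=2,4
  time <- c(1, 3, 2, 4)
  status <- c(1, 1, 1, 1)
  x <- c(1, 1, 0, 0)
  orc <- oracleGridCoxBeta(time, status, x, ties = "breslow")
  expect_false(orc$boundary)
  expect_equal(round(orc$beta, 2), 0.94)

  coh <- makeToyCohort(matrix(x, 1), time, status)
  fit <- fitCox(coh, "G01", ties = "breslow")
  expect_true(fit@converged)
  expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-3)
  # tie-free data: Efron and Breslow must coincide
  fit.e <- fitCox(coh, "G01", ties = "efron")
  expect_equal(coef(fit.e), coef(fit), tolerance = 1e-6)
})

test_that("perfect separation is flagged as monotone likelihood", {
  # all x=1 deaths precede all x=0 deaths: score 3*u + 4 = 0 has no
  # positive root, the likelihood is monotone in beta
  coh <- makeToyCohort(matrix(c(1, 1, 0, 0), 1),
                       time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  fit <- fitCox(coh, "G01")
  expect_false(fit@converged)
})

test_that("degenerate covariates are handled", {
  coh <- makeToyCohort(matrix(0, 1, 5),
                       time = 1:5, event = c(1, 1, 0, 1, 0))
  fit <- fitCox(coh, "G01")
  expect_true(fit@converged)
  expect_equal(unname(coef(fit)), 0)
  # log-likelihood equals the null model's
  null.ll <- oracleCoxPLL(0, 1:5, c(1, 1, 0, 1, 0), rep(0, 5))
  expect_equal(fit@logLik, null.ll)

  no.event <- matrix(1:4, 1)
  colnames(no.event) <- paste0("S", 1:4)
  expect_error(
    SurvivalCohort(no.event, data.frame(sample_id = paste0("S", 1:4),
                                        time = 1:4, event = rep(0, 4))),
    "at least one event")
  expect_error(fitCox(coh, "NOPE"), "not in cohort")
  expect_error(fitCox(coh, rep("G01", 2)), "n/5|too many|duplicate")
})

test_that("fits agree with survival::coxph on multivariate tied data", {
  coh <- simulateCohort(nSamples = 150, nGenes = 8, plantedGenes = 1:3,
                        plantedBetas = c(0.8, -0.5, 0.3),
                        censorRate = 0.4, seed = 17)
  # force tied death days to exercise the Efron correction
  cd <- clinicalData(coh)
  cd$time <- ceiling(cd$time / 50)
  tied <- SurvivalCohort(exprValues(coh),
                         cbind(sample_id = rownames(cd),
                               cd[, names(cd) != "sample_id"]))
  genes <- rownames(coh)[1:3]
  for (ties in c("efron", "breslow")) {
    fit <- fitCox(tied, genes, ties = ties)
    X <- t(exprValues(tied)[genes, ])
    ref <- survival::coxph(
      survival::Surv(survivalTime(tied), eventStatus(tied)) ~ X,
      ties = ties)
    expect_equal(unname(coef(fit)), unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit@se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(fit@logLik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
  }
})

test_that("Wald statistics satisfy their defining identities", {
  coh <- simulateCohort(nSamples = 100, nGenes = 4, plantedGenes = 1,
                        plantedBetas = 0.7, censorRate = 0.3, seed = 8)
  fit <- fitCox(coh, rownames(coh)[1:2])
  expect_equal(fit@waldZ, fit@coefficients / fit@se)
  expect_equal(fit@waldP, 2 * pnorm(-abs(fit@waldZ)))
  expect_true(all(fit@waldP >= 0 & fit@waldP <= 1))
})
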