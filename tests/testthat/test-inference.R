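uniformSFS <- function(values) {
  # 1-population spectrum with 3 unmasked cells (shape 5 x 1 x 1)
  JointSFS(array(c(0, values, 0), dim = c(5, 1, 1)),
           sampleSizes = c(4L, 0L, 0L))
}

test_that("composite log-likelihood matches hand arithmetic and Gibbs", {
  obs <- uniformSFS(c(1, 1, 1))
  expected <- uniformSFS(c(7, 7, 7))
  expect_equal(compositeLogLik(obs, expected), 3 * log(1 / 3),
               tolerance = 1e-12)

  # proportional expected maximizes the likelihood (Gibbs inequality)
  set.seed(1)
  obs2 <- uniformSFS(c(5, 2, 9))
  llBest <- compositeLogLik(obs2, uniformSFS(c(5, 2, 9)))
  for (i in 1:100) {
    alt <- uniformSFS(runif(3, 0.01, 1))
    expect_gte(llBest, compositeLogLik(obs2, alt))
  }

  # zero expected cell with observed sites stays finite via the floor
  degenerate <- uniformSFS(c(1, 0, 1))
  ll <- compositeLogLik(obs2, degenerate)
  expect_true(is.finite(ll))

  # scaling the expected spectrum leaves the likelihood unchanged
  expect_equal(compositeLogLik(obs2, uniformSFS(c(10, 4, 18))),
               compositeLogLik(obs2, uniformSFS(c(5, 2, 9))),
               tolerance = 1e-12)

  expect_error(
    compositeLogLik(obs2, JointSFS(array(1, c(3, 1, 1)),
                                   sampleSizes = c(2L, 0L, 0L))),
    "shape")
})

test_that("AIC bookkeeping, degenerate fits and reproducibility hold", {
  model <- getModel("ISO")
  truth <- quickIsoParams()
  cfg <- sampleConfig(4, 4, 2)
  obs <- simulateSFS(model, truth, cfg, nSnps = 2000, seed = 51,
                     nReps = 1500)

  tiny <- fitSettings(nPriorDraws = 1, nRefine = 0, nStarts = 1,
                      nChains = 1, nmEvals = 0, finalNmEvals = 0,
                      repsPerEval = 400, finalFactor = 2)
  fit <- suppressWarnings(fitModel(obs, model, settings = tiny, seed = 7))
  expect_equal(fit$aic, 2 * 6 - 2 * fit$loglik, tolerance = 1e-12)
  expect_equal(fit$k, 6)

  fit2 <- suppressWarnings(fitModel(obs, model, settings = tiny, seed = 7))
  expect_identical(fit$mleNatural, fit2$mleNatural)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("model comparison applies the 2.0/10.0 support thresholds", {
  mk <- function(id, aic) structure(list(modelId = id, k = 7,
                                         loglik = (2 * 7 - aic) / 2,
                                         aic = aic), class = "FitResult")
  tab <- selectModel(list(mk("ISO", 100), mk("SYM", 104)))
  expect_equal(tab$delta_aic, c(0, 4))
  expect_equal(tab$label, c("best", "significant"))

  tab2 <- selectModel(list(mk("ISO", 100), mk("SYM", 101)))
  expect_equal(tab2$label[2], "not_significant")

  tab3 <- selectModel(list(mk("ISO", 100), mk("SYM", 111)))
  expect_equal(tab3$label[2], "highly_significant")

  expect_error(selectModel(list(mk("ISO", 1), mk("ISO", 2))), "duplicate")
  expect_error(selectModel(list(mk("ISO", 1))), "at least two")
})

test_that("ISO parameters are recovered within a factor of two", {
  model <- getModel("ISO")
  truth <- parameterVector(model, NeS = 150000, NeC = 450000, NeO = 200000,
                           NeD = 300000, NeA = 200000, TD = 8e5)
  cfg <- sampleConfig(8, 8, 2)
  light <- fitSettings(nPriorDraws = 60, nRefine = 6, repsPerEval = 1000,
                       nStarts = 2, nChains = 1, nmEvals = 80, nmFactor = 4,
                       nmRestarts = 2, finalNmEvals = 40, finalFactor = 8)
  okAll <- logical(2)
  for (s in 1:2) {
    obs <- simulateSFS(model, truth, cfg, nSnps = 15000, seed = 60 + s,
                       nReps = 3000)
    fit <- suppressWarnings(fitModel(obs, model, settings = light,
                                     seed = 70 + s))
    ratios <- c(fit$mle$NeS / truth$NeS, fit$mle$NeC / truth$NeC,
                fit$mle$TD / truth$TD)
    okAll[s] <- all(ratios > 0.5 & ratios < 2)
  }
  expect_gte(sum(okAll), 1)
})

test_that("the asymmetric model never fits worse than nested isolation", {
  iso <- getModel("ISO")
  asym <- getModel("ASYM")
  light <- fitSettings(nPriorDraws = 60, nRefine = 6, repsPerEval = 1000,
                       nStarts = 2, nChains = 1, nmEvals = 80, nmFactor = 4,
                       nmRestarts = 2, finalNmEvals = 40, finalFactor = 8)
  truth <- quickIsoParams(80000, 150000, 90000)
  obs <- simulateSFS(iso, truth, sampleConfig(6, 6, 2), nSnps = 8000,
                     seed = 81, nReps = 3000)
  fIso <- suppressWarnings(fitModel(obs, iso, settings = light, seed = 91))
  fAsym <- suppressWarnings(fitModel(obs, asym, settings = light, seed = 91))
  expect_gte(fAsym$loglik, fIso$loglik - 10)  # Monte-Carlo tolerance
})

test_that("bootstrap percentiles and summary behave as defined", {
  model <- getModel("ISO")
  truth <- quickIsoParams(80000, 120000, 90000)
  tiny <- fitSettings(nPriorDraws = 12, nRefine = 3, repsPerEval = 500,
                      nStarts = 1, nChains = 1, nmEvals = 40, nmFactor = 2,
                      nmRestarts = 1, finalNmEvals = 0, finalFactor = 4)
  bs <- suppressWarnings(
    parametricBootstrap(model, truth, sampleConfig(6, 6, 2), B = 2,
                        nSnps = 2000, seed = 31, settings = tiny))
  expect_equal(bs$B, 2)
  # B = 2: the percentile interval spans the two replicate estimates
  for (j in seq_len(ncol(bs$replicates))) {
    expect_equal(bs$table$ci_low[j], min(bs$replicates[, j]))
    expect_equal(bs$table$ci_high[j], max(bs$replicates[, j]))
  }
  expect_true(all(bs$table$ci_low <= bs$table$mean + 1e-9))
})

test_that("bootstrap intervals cover the generating truth", {
  model <- getModel("ISO")
  truth <- parameterVector(model, NeS = 120000, NeC = 300000, NeO = 150000,
                           NeD = 250000, NeA = 180000, TD = 8e5)
  light <- fitSettings(nPriorDraws = 30, nRefine = 5, repsPerEval = 600,
                       nStarts = 1, nChains = 1, nmEvals = 60, nmFactor = 3,
                       nmRestarts = 1, finalNmEvals = 0, finalFactor = 6)
  bs <- suppressWarnings(
    parametricBootstrap(model, truth, sampleConfig(6, 6, 2), B = 25,
                        nSnps = 6000, seed = 131, settings = light))
  tr <- unlist(truth[c("NeS", "NeC", "NeO", "NeD", "NeA", "TD")])
  tab <- bs$table[match(names(tr), bs$table$parameter), ]
  covered <- tr >= tab$ci_low & tr <= tab$ci_high
  expect_gte(sum(covered[c("NeS", "NeC", "TD", "NeD", "NeA")]), 4)
})
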