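test_that("eligibility filters mirror the modeling rules", {
  obs <- observationMatrix(lapply(1:6, function(i)
    list(sites = 1:5, states = rep(1L, 5))))
  expect_false(regionEligible(9, obs)$pass)
  expect_equal(regionEligible(9, obs)$reason, "min_sites")
  # 12 CpGs, only 7 observed -> 7/12 < 2/3
  obs2 <- observationMatrix(lapply(1:10, function(i)
    list(sites = 1:7, states = rep(0L, 7))))
  e2 <- regionEligible(12, obs2)
  expect_equal(e2$reason, "coverage_fraction")
  # 12 CpGs, 29 total site observations -> 29/12 < 2.5
  obs3 <- observationMatrix(c(
    lapply(1:2, function(i) list(sites = 1:12, states = rep(1L, 12))),
    list(list(sites = 1:5, states = rep(0L, 5)))))
  e3 <- regionEligible(12, obs3)
  expect_equal(e3$reason, "depth")
  obs4 <- observationMatrix(lapply(1:3, function(i)
    list(sites = 1:12, states = rep(1L, 12))))
  expect_true(regionEligible(12, obs4)$pass)
})

test_that("average marginal log-likelihood averages per-read marginals", {
  sl <- uniformSlice(R = 2, spacing = 15)
  # theta chosen so a = 0 and c_2 = ln 2
  theta <- c(0, 0, 0, 0, log(2) * 15)
  obs1 <- observationMatrix(list(list(sites = 1:2, states = c(1L, 1L))))
  expect_equal(averageMarginalLogLik(theta, sl, obs1), log(0.4))
  obs2 <- observationMatrix(rep(list(list(sites = 1:2,
                                          states = c(1L, 1L))), 2))
  expect_equal(averageMarginalLogLik(theta, sl, obs2), log(0.4))
  obs3 <- observationMatrix(list(list(sites = 1L, states = 1L)))
  expect_equal(averageMarginalLogLik(theta, sl, obs3), log(0.5))
})

test_that("estimation is invariant to read order", {
  sl <- uniformSlice(R = 12, spacing = 15)
  m <- buildPotentials(c(0.2, 0.1, -0.1, 1, 2), sl$rho, sl$dist)
  s <- sampleStates(m, 60, seed = 5)
  reads <- lapply(1:60, function(i) {
    sites <- sort(sample(1:12, 6))
    list(sites = sites, states = s[i, sites])
  })
  f1 <- estimateRegionParams(sl, observationMatrix(reads), seed = 2)
  f2 <- estimateRegionParams(sl, observationMatrix(rev(reads)), seed = 2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("saturated data drives the fitted marginals to 1", {
  sl <- uniformSlice(R = 12, spacing = 15)
  obs <- fullReadObs(matrix(1L, nrow = 40, ncol = 12))
  fit <- estimateRegionParams(sl, obs, seed = 1)
  expect_equal(fit$status, "fitted")
  expect_true(all(siteMarginals(fit$model) >= 0.99))
})

test_that("parameters are recovered in distribution space", {
  sl <- uniformSlice(R = 20, spacing = 15)
  thetaStar <- c(0, 0, 0, 2, 1)
  mStar <- buildPotentials(thetaStar, sl$rho, sl$dist)
  obs <- fullReadObs(sampleStates(mStar, 400, seed = 9))
  fit <- estimateRegionParams(sl, obs, seed = 3)
  expect_equal(fit$status, "fitted")
  # likelihood at the optimum is at least the likelihood at the truth
  expect_gte(fit$loglik, averageMarginalLogLik(thetaStar, sl, obs) - 1e-8)
  expect_lt(max(abs(siteMarginals(fit$model) - siteMarginals(mStar))),
            0.05)
  corOf <- function(m) {
    s <- sampleStates(m, 4e4, seed = 11)
    vapply(1:19, function(j) cor(s[, j], s[, j + 1]), numeric(1))
  }
  expect_lt(max(abs(corOf(fit$model) - corOf(mStar))), 0.05)
})

test_that("likelihood at the truth dominates perturbed parameters", {
  sl <- uniformSlice(R = 15, spacing = 15)
  thetaStar <- c(0.5, 0.5, 0.5, 0, 3)
  mStar <- buildPotentials(thetaStar, sl$rho, sl$dist)
  obs <- fullReadObs(sampleStates(mStar, 200, seed = 23))
  llStar <- averageMarginalLogLik(thetaStar, sl, obs)
  set.seed(31)
  worse <- 0L
  for (i in 1:10) {
    pert <- thetaStar + rnorm(5, 0, c(1, 1, 1, 5, 1.5))
    if (averageMarginalLogLik(pert, sl, obs) <= llStar + 0.05)
      worse <- worse + 1L
  }
  expect_gte(worse, 8L)
})

test_that("the general Ising fit nests the constrained one", {
  sl <- uniformSlice(R = 8, spacing = 15)
  m <- buildPotentials(c(0, 0.3, 0, -3, 2), sl$rho, sl$dist)
  obs <- fullReadObs(sampleStates(m, 80, seed = 2))
  fitC <- estimateRegionParams(sl, obs, seed = 4)
  fitG <- fitGeneralIsing(sl, obs, init = fitC)
  expect_equal(fitG$nParams, 2L * 8L - 1L)
  expect_gte(fitG$loglik, fitC$loglik - 1e-8)
  expect_equal(fitGeneralIsing(sl, obs, maxR = 5)$status,
               "skipped(too_large)")
})

test_that("R = 2 general fit matches the saturated empirical distribution", {
  sl <- uniformSlice(R = 2, spacing = 10)
  # empirical counts over the 4 states determine the saturated fit
  states <- rbind(matrix(rep(c(0L, 0L), 40), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1L, 1L), 35), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0L, 1L), 15), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1L, 0L), 10), ncol = 2, byrow = TRUE))
  obs <- fullReadObs(states)
  fitG <- fitGeneralIsing(sl, obs, maxit = 5000)
  emp <- c(40, 10, 15, 35) / 100 # order (0,0),(1,0),(0,1),(1,1)
  fitted <- vapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(x)
    stateProbability(fitG$model, x), numeric(1))
  expect_equal(fitted, emp, tolerance = 0.01)
  # achieved likelihood approaches the entropy bound of the empirical PMF
  expect_equal(fitG$loglik, sum(emp * log(emp)), tolerance = 1e-3)
})

test_that("AIC probabilities follow the two-model comparison formula", {
  obs <- observationMatrix(lapply(1:10, function(i)
    list(sites = 1:3, states = c(1L, 0L, 1L))))
  f1 <- list(loglik = -2, nParams = 5L)
  f2 <- list(loglik = -2 + 10 / 10, nParams = 25L)
  # equal AIC by construction: -2*10*(-2)+10 = 50 vs -2*10*(-1)+50 = 70
  cmpEq <- aicCompare(list(loglik = -2, nParams = 5L),
                      list(loglik = -2, nParams = 5L), obs)
  expect_equal(cmpEq$pi, 0.5)
  cmp <- aicCompare(f1, f2, obs)
  expect_equal(cmp$aic1, 50)
  expect_equal(cmp$aic2, 70)
  # AIC1 = AIC2 - 20 gives pi = 1/(1 + exp(-10))
  expect_equal(cmp$pi, 1 / (1 + exp(-10)), tolerance = 1e-12)
  # monotone: improving model 1 raises pi
  better <- aicCompare(list(loglik = -1.9, nParams = 5L), f2, obs)
  expect_gt(better$pi, cmp$pi)
})
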