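test_that("bandwidth 50-kb implies a kernel sigma of about 18.5-kb", {
  expect_equal(kernelSigma(50000), 0.25 * 50000 / qnorm(0.75))
  expect_equal(kernelSigma(50000) / 1000, 18.5, tolerance = 0.01)
})

test_that("smoothing is a local convex combination", {
  x <- seq(0, 1e5, by = 1000)
  expect_equal(smoothJSD(x, rep(0.3, length(x)), 50000),
               rep(0.3, length(x)))
  # symmetric neighbors average exactly
  y <- smoothJSD(c(0, 1000, 2000), c(0, 0.5, 1), 5000)
  expect_equal(y[2], 0.5, tolerance = 1e-9)
  set.seed(6)
  v <- runif(101)
  s <- smoothJSD(x, v, 30000)
  expect_true(all(s >= min(v) - 1e-12 & s <= max(v) + 1e-12))
  expect_error(smoothJSD(c(3, 1, 2), c(1, 2, 3)), "sorted")
})

test_that("empirical null p-values use the plus-one rank formula", {
  null <- empiricalNull(seq_len(999) / 1000)
  expect_equal(nullPValues(null, 2), 1 / 1000)
  expect_equal(nullPValues(null, 0), 1)
  # ties count as exceedances
  expect_equal(nullPValues(null, 0.999), 2 / 1000)
  obs <- runif(50)
  p <- nullPValues(null, obs)
  expect_true(all(diff(p[order(obs)]) <= 0))
  expect_error(empiricalNull(numeric()), "empty")
})

test_that("logit-normal mixture null recovers a simulated mixture", {
  set.seed(12)
  n <- 1e4
  comp <- rbinom(n, 1, 0.5)
  y <- rnorm(n, ifelse(comp == 1, -1, -3), 0.5)
  x <- 1 / (1 + exp(-y))
  null <- fitLogitNormalNull(x, seed = 5)
  expect_equal(null$kind, "logit_normal")
  expect_equal(null$mu, -3, tolerance = 0.1)
  expect_equal(null$mu, min(null$mixture$mu1, null$mixture$mu2))
  # the density integrates to one on (0, 1)
  dens <- integrate(function(z) logitNormalDensity(z, null), 1e-8,
                    1 - 1e-8, rel.tol = 1e-8)
  expect_equal(dens$value, 1, tolerance = 1e-6)
  # single-component data still yields the min-mean rule
  x1 <- 1 / (1 + exp(-rnorm(5e3, -2, 0.4)))
  n1 <- fitLogitNormalNull(x1, seed = 7)
  expect_equal(n1$mu, -2, tolerance = 0.2)
})

test_that("BY adjustment, SQS and the FDR flag follow the formulas", {
  # m = 100 equal p-values: q = p * c(100), c(100) = sum(1/i)
  p <- rep(0.001, 100)
  tt <- testGUs(p, fdrLevel = 0.01)
  cm <- sum(1 / (1:100))
  expect_equal(tt$q, rep(0.001 * cm, 100), tolerance = 1e-12)
  expect_true(all(tt$isDM))
  expect_equal(testGUs(c(0.01, 0.01))$sqs,
               -10 * log10(p.adjust(c(0.01, 0.01), "BY")),
               tolerance = 1e-9)
  # SQS of q = 0.01 is 20
  expect_equal(-10 * log10(0.01), 20)
  expect_true(all(testGUs(c(0, 0.5))$sqs <= 300))
})

test_that("BY at 0.01 controls the false discovery proportion", {
  set.seed(71)
  fdp <- replicate(30, {
    p <- c(runif(1800), rbeta(200, 0.05, 1))
    isNull <- c(rep(TRUE, 1800), rep(FALSE, 200))
    tt <- testGUs(p, fdrLevel = 0.01)
    if (sum(tt$isDM) == 0) 0 else sum(tt$isDM & isNull) / sum(tt$isDM)
  })
  expect_lte(mean(fdp), 0.01)
})

test_that("morphological closing merges sub-bandwidth gaps and scores DMRs", {
  # two significant runs separated by a 40-kb gap, closing 50-kb
  guStart <- as.integer(c(seq(1, by = 150, length.out = 4),
                          seq(40601, by = 150, length.out = 4)))
  guEnd <- guStart + 149L
  isDM <- rep(TRUE, 8)
  sqs <- c(rep(20, 4), rep(35.5, 4))
  one <- closeAndScore(guStart, guEnd, isDM, sqs, closingSize = 50000)
  expect_equal(nrow(one), 1L)
  expect_equal(one$score, 4 * 20 + 4 * 35.5)
  expect_equal(one$nGUs, 8L)
  # a 60-kb gap exceeds the structuring element
  guStart2 <- as.integer(c(seq(1, by = 150, length.out = 4),
                           seq(60601, by = 150, length.out = 4)))
  two <- closeAndScore(guStart2, guStart2 + 149L, isDM, sqs,
                       closingSize = 50000)
  expect_equal(nrow(two), 2L)
  expect_equal(two$rank, 1:2)
  expect_gte(two$score[1], two$score[2]) # ranked by score, descending
  expect_equal(sort(two$score), sort(c(80, 142)))
  none <- closeAndScore(guStart, guEnd, rep(FALSE, 8), sqs, 50000)
  expect_equal(nrow(none), 0L)
})

test_that("p-values from a correct empirical null are uniform", {
  set.seed(55)
  pvals <- replicate(20, {
    null <- empiricalNull(rnorm(2000))
    mean(nullPValues(null, rnorm(500)) <= 0.5)
  })
  # exceedance p-values of draws from the null itself are uniform:
  # the fraction below 0.5 concentrates near 0.5
  expect_equal(mean(pvals), 0.5, tolerance = 0.05)
  # empirical p-values are discrete, so ties are expected; the KS statistic
  # is still a valid goodness indicator here
  ks <- suppressWarnings(
    stats::ks.test(nullPValues(empiricalNull(rnorm(5000)),
                               rnorm(2000)), "punif"))
  expect_gt(ks$p.value, 0.001)
})
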