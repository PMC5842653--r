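test_that("potentials follow the five-parameter region parameterization", {
  sl <- uniformSlice(R = 5, spacing = 2)
  m0 <- buildPotentials(c(0, 0, 0, 0, 0), sl$rho, sl$dist)
  expect_equal(m0@a, rep(0, 5))
  expect_equal(m0@c[-1], rep(0, 4))
  m1 <- buildPotentials(c(0, 0, 0, 0, 1), sl$rho, sl$dist)
  expect_equal(m1@c[2], 0.5) # gamma / d with d = 2
  m2 <- buildPotentials(c(0, 0, 0, 10, 0), rho = c(0.05, 0.067, 0.05),
                        dist = c(NA, 15, 15))
  expect_equal(m2@a[2], 0.67) # beta * rho in the interior
  # boundary intrinsics replace alpha at the region ends
  m3 <- buildPotentials(c(1, 2, 3, 0, 0), sl$rho, sl$dist)
  expect_equal(m3@a, c(1, 2, 2, 2, 3))
  expect_error(buildPotentials(c(0, 0, 0, 0, 1), c(0.1, 0.1), c(NA, 0)),
               "positive")
})

test_that("partition function matches closed forms and enumeration", {
  expect_equal(logPartitionFunction(regionModel(a = 0, R = 1)), log(2))
  expect_equal(logPartitionFunction(regionModel(a = 0, c = 0, R = 2)),
               log(4))
  expect_equal(logPartitionFunction(regionModel(a = 0, c = log(2), R = 2)),
               log(5))
  set.seed(21)
  for (R in c(3, 7, 12)) {
    m <- randomModel(R)
    b <- bruteIsing(m@a, m@c[-1])
    expect_equal(logPartitionFunction(m), log(b$Z), tolerance = 1e-10)
  }
})

test_that("state probabilities are exact and normalized", {
  m <- regionModel(a = 0, c = log(2), R = 2)
  expect_equal(stateProbability(m, c(1, 1)), 0.4)
  expect_equal(stateProbability(m, c(0, 1)), 0.1)
  expect_error(stateProbability(m, c(2, 0)), "binary")
  set.seed(8)
  m3 <- randomModel(4)
  states <- as.matrix(expand.grid(rep(list(0:1), 4)))
  tot <- sum(apply(states, 1, function(x) stateProbability(m3, x)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("site marginals: symmetry, saturation and enumeration", {
  expect_equal(siteMarginals(regionModel(a = 0, c = 1.3, R = 6)),
               rep(0.5, 6))
  expect_true(all(siteMarginals(regionModel(a = 20, c = 0.5, R = 5)) >
                  0.999999))
  m <- regionModel(a = c(0.3, -0.2, 0.1), c = c(0.4, 0.7), R = 3)
  b <- bruteIsing(m@a, m@c[-1])
  expect_equal(siteMarginals(m), bruteMarginals(b), tolerance = 1e-10)
})

test_that("spin-flip symmetry: negating fields swaps the marginals", {
  set.seed(5)
  for (i in 1:5) {
    R <- sample(2:10, 1)
    a <- rnorm(R); cc <- rnorm(R - 1)
    p <- siteMarginals(regionModel(a = a, c = cc, R = R))
    q <- siteMarginals(regionModel(a = -a, c = cc, R = R))
    expect_equal(p, 1 - q, tolerance = 1e-12)
  }
})

test_that("zero coupling factorizes into independent Bernoullis", {
  set.seed(3)
  a <- rnorm(6)
  m <- regionModel(a = a, c = 0, R = 6)
  marg <- siteMarginals(m)
  expect_equal(marg, exp(a) / (exp(a) + exp(-a)), tolerance = 1e-12)
  x <- c(1, 0, 1, 1, 0, 0)
  expect_equal(stateProbability(m, x),
               prod(ifelse(x == 1, marg, 1 - marg)), tolerance = 1e-12)
})

test_that("mode behavior: sign of the field selects the extreme state", {
  b <- bruteIsing(rep(-0.8, 5), rep(0.5, 4))
  expect_equal(which.max(b$p), which(rowSums(b$states) == 0))
  b <- bruteIsing(rep(0.8, 5), rep(0.5, 4))
  expect_equal(which.max(b$p), which(rowSums(b$states) == 5))
  b <- bruteIsing(rep(0, 5), rep(1, 4))
  top2 <- order(b$p, decreasing = TRUE)[1:2]
  expect_setequal(rowSums(b$states)[top2], c(0, 5))
})

test_that("block marginal likelihood matches enumeration, runs multiply", {
  m <- regionModel(a = 0, c = log(2), R = 2)
  expect_equal(blockMarginalLikelihood(m, 1, 1), 0.5)
  expect_equal(blockMarginalLikelihood(m, c(1, 2), c(1, 1)), 0.4)
  # independence makes the run product exact
  m3 <- regionModel(a = 0, c = 0, R = 3)
  expect_equal(blockMarginalLikelihood(m3, c(1, 3), c(1, 0)), 0.25)
  # empty observation has probability 1 by convention
  expect_equal(blockMarginalLikelihood(m3, integer(), integer()), 1)
  # contiguous blocks with flanks, random models
  set.seed(13)
  for (i in 1:5) {
    R <- sample(4:10, 1)
    m <- randomModel(R)
    b <- bruteIsing(m@a, m@c[-1])
    i0 <- sample(R - 2, 1); j0 <- i0 + sample(0:2, 1)
    st <- sample(0:1, j0 - i0 + 1, replace = TRUE)
    expect_equal(blockMarginalLikelihood(m, i0:j0, st),
                 bruteBlockMarginal(b, i0:j0, st), tolerance = 1e-10)
  }
})

test_that("marginalization is consistent: completions sum to one", {
  set.seed(17)
  m <- randomModel(6)
  # conditional over completions of sites 3:4 given nothing: the block
  # marginals over all 4 patterns must sum to 1
  pats <- as.matrix(expand.grid(0:1, 0:1))
  tot <- sum(apply(pats, 1, function(st)
    blockMarginalLikelihood(m, 3:4, st)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("level PMF matches enumeration and saturates correctly", {
  expect_equal(pmfProbs(levelPMF(regionModel(a = 0, c = 0, R = 2), 1:2)),
               c(0.25, 0.5, 0.25))
  expect_equal(pmfProbs(levelPMF(regionModel(a = 0, c = log(2), R = 2),
                                 1:2)),
               c(0.4, 0.2, 0.4))
  psat <- pmfProbs(levelPMF(regionModel(a = 20, c = 0, R = 4), 1:4))
  expect_gt(psat[5], 1 - 1e-9)
  set.seed(29)
  for (i in 1:6) {
    R <- sample(3:12, 1)
    m <- randomModel(R)
    b <- bruteIsing(m@a, m@c[-1])
    lo <- sample(R, 1); hi <- lo + sample.int(R - lo + 1, 1) - 1L
    expect_equal(pmfProbs(levelPMF(m, lo:hi)), bruteLevelPMF(b, lo:hi),
                 tolerance = 1e-10)
  }
})

test_that("exact sampling reproduces the joint distribution", {
  m <- regionModel(a = c(0.4, -0.3, 0.2), c = c(0.5, -0.4), R = 3)
  set.seed(101)
  s <- sampleStates(m, 1e5)
  # per-site frequency within binomial tolerance
  expect_equal(colMeans(s), siteMarginals(m), tolerance = 0.01)
  # chi-squared GOF against exact state probabilities
  b <- bruteIsing(m@a, m@c[-1])
  code <- s[, 1] + 2 * s[, 2] + 4 * s[, 3]
  obs <- tabulate(code + 1, 8)
  gof <- suppressWarnings(chisq.test(obs, p = b$p))
  expect_gt(gof$p.value, 0.001)
  # strong positive coupling concentrates mass on the extreme states
  s2 <- sampleStates(regionModel(a = 0, c = 5, R = 8), 2000, seed = 7)
  frac <- mean(rowSums(s2) %in% c(0, 8))
  expect_gt(frac, 0.95)
  # reproducible under seed
  expect_identical(sampleStates(m, 50, seed = 3), sampleStates(m, 50, seed = 3))
})

test_that("distinct parameters give distinct distributions (identifiability)", {
  sl <- uniformSlice(R = 6, spacing = 20)
  set.seed(41)
  thetas <- cbind(runif(6, -1, 1), runif(6, -1, 1), runif(6, -1, 1),
                  runif(6, -20, 20), runif(6, -5, 5))
  states <- as.matrix(expand.grid(rep(list(0:1), 6)))
  probs <- apply(thetas, 1, function(th) {
    m <- buildPotentials(th, sl$rho, sl$dist)
    apply(states, 1, function(x) stateProbability(m, x))
  })
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(abs(probs[, i] - probs[, j])), 1e-6)
  }
})
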