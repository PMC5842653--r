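pmfOf <- function(p) new("LevelPMF", K = length(p) - 1L, p = p)

test_that("differential level PMF is the cross-convolution", {
  d0 <- diffLevelPMF(pmfOf(c(0, 1, 0)), pmfOf(c(0, 1, 0)))
  expect_equal(d0$support[d0$p > 0], 0)
  d1 <- diffLevelPMF(pmfOf(c(0.5, 0.5)), pmfOf(c(1, 0)))
  expect_equal(d1$support[d1$p > 0], c(0, 1))
  expect_equal(d1$p[d1$p > 0], c(0.5, 0.5))
  # mean of D_L equals the MML difference (linearity), unequal K
  set.seed(2)
  for (i in 1:5) {
    pt <- pmfOf(prop.table(runif(sample(3:8, 1))))
    pr <- pmfOf(prop.table(runif(sample(3:8, 1))))
    d <- diffLevelPMF(pt, pr)
    expect_equal(sum(d$support * d$p), computeMML(pt) - computeMML(pr),
                 tolerance = 1e-12)
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
  }
})

test_that("KL divergence handles zeros and known values", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(klDivergence(c(0.75, 0.25), c(0.25, 0.75)),
               0.5 * log2(3), tolerance = 1e-12)
  expect_equal(klDivergence(c(1, 0), c(0, 1)), Inf)
  expect_gte(klDivergence(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2)), 0)
})

test_that("JSD identities: zero iff equal, one iff disjoint", {
  p <- pmfOf(c(0.2, 0.3, 0.5))
  expect_equal(jsDistance(p, p), 0)
  # disjoint supports across different K embeddings
  pt <- pmfOf(c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  pr <- pmfOf(c(0, 0, 0, 0, 0, 0, 0.5, 0.5))
  expect_equal(jsDistance(pt, pr), 1)
  expect_equal(jsDistance(c(1, 0), c(0.5, 0.5)), 0.5579, tolerance = 1e-4)
})

test_that("JSD is a normalized metric on random PMF triples", {
  set.seed(33)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    p1 <- prop.table(runif(K + 1)); p2 <- prop.table(runif(K + 1))
    p3 <- prop.table(runif(K + 1))
    d12 <- jsDistance(p1, p2); d21 <- jsDistance(p2, p1)
    expect_identical(d12, d21)
    expect_true(d12 >= 0 && d12 <= 1)
    d13 <- jsDistance(p1, p3); d23 <- jsDistance(p2, p3)
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("swapping test and reference negates the differences", {
  set.seed(44)
  pt <- pmfOf(prop.table(runif(6))); pr <- pmfOf(prop.table(runif(6)))
  df <- diffLevelPMF(pt, pr); dr <- diffLevelPMF(pr, pt)
  expect_equal(df$support, -rev(dr$support))
  expect_equal(df$p, rev(dr$p))
})

test_that("disjoint symmetric PMFs give max JSD with zero dMML and dNME", {
  # equal-entropy, equal-mean PMFs on disjoint supports (K = 4)
  pt <- pmfOf(c(0.5, 0, 0, 0, 0.5))   # mass at levels 0 and 1
  pr <- pmfOf(c(0, 0.5, 0, 0.5, 0))   # mass at levels 1/4 and 3/4
  expect_equal(jsDistance(pt, pr), 1)
  expect_equal(computeMML(pt) - computeMML(pr), 0)
  expect_equal(computeNME(pt) - computeNME(pr), 0)
})

test_that("differential level classes follow the tail-mass rules", {
  degen <- function(v, p = 1) list(support = v, p = rep(p, length(v)))
  expect_equal(classifyDiffLevel(degen(0)), "isomethylated")
  expect_equal(classifyDiffLevel(degen(-0.85)), "strongly_hypomethylated")
  expect_equal(classifyDiffLevel(degen(0.3)), "moderately_hypermethylated")
  expect_equal(classifyDiffLevel(list(support = c(-0.3, 0.1),
                                      p = c(0.55, 0.45))),
               "weakly_hypomethylated")
})

test_that("differential entropy classes are symmetric ordered bins", {
  expect_equal(classifyDiffEntropy(0), "isoentropic")
  expect_equal(classifyDiffEntropy(-1), "strongly_hypoentropic")
  expect_equal(classifyDiffEntropy(0.3), "moderately_hyperentropic")
  expect_equal(classifyDiffEntropy(-0.3), "moderately_hypoentropic")
  expect_equal(classifyDiffEntropy(0.1), "weakly_hyperentropic")
  expect_equal(classifyDiffEntropy(1), "strongly_hyperentropic")
})
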