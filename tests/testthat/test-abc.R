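# ABC engine: reference tables, rejection, model choice, local-linear
# adjustment, validation machinery.

test_that("reference tables have the requested composition and are reproducible", {
  spec <- sampleSpec(nDiploid = 6, nSnpLoci = 20)
  tab <- buildReferenceTable(nSimsPerModel = 100, spec = spec, seed = 1)
  expect_identical(as.integer(table(modelId(tab))), c(100L, 100L, 100L))
  expect_identical(dim(refStats(tab)), c(300L, 4L))
  tab2 <- buildReferenceTable(nSimsPerModel = 100, spec = spec, seed = 1)
  expect_identical(refStats(tab), refStats(tab2))
  expect_identical(refParams(tab), refParams(tab2))
  # expansion rows carry expansion parameters, constant rows carry Nc
  expect_true(all(is.na(refParams(tab)[modelId(tab) == "constant", "Texp"])))
  expect_true(all(is.finite(refParams(tab)[modelId(tab) == "lgm", "Texp"])))
  expect_error(buildReferenceTable(nSimsPerModel = 10, spec = spec,
    priors = list(constant = list(Nc = c(5, 5)),
                  lgm = defaultPriors()$lgm,
                  interglacial = defaultPriors()$interglacial)),
    "degenerate prior")
})

test_that("prior draws are uniform over the stated bounds", {
  spec <- sampleSpec(nDiploid = 4, nSnpLoci = 2)
  tab <- buildReferenceTable("lgm", spec = spec, nSimsPerModel = 10000,
                             seed = 2)
  b <- defaultPriors()$lgm
  for (p in c("Nanc", "Npost", "Texp")) {
    ks <- stats::ks.test(refParams(tab)[, p], "punif",
                         b[[p]][1], b[[p]][2])
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("rejection returns the provably closest rows", {
  set.seed(3)
  stats10 <- matrix(stats::rnorm(20), 10, 2)
  tab <- ref_fix(rep("constant", 10),
                 matrix(stats::runif(10, 10, 30), dimnames = list(NULL, "Nc")),
                 stats10, list(constant = list(Nc = c(10, 30))))
  sObs <- stats10[4, ]
  names(sObs) <- colnames(refStats(tab))
  one <- abcReject(tab, sObs, 1)
  expect_identical(one$indices, 4L)
  expect_equal(one$distances, 0)
  all10 <- abcReject(tab, sObs, 10)
  expect_identical(sort(all10$indices), 1:10)
  # brute-force sort oracle
  sd2 <- apply(stats10, 2, stats::sd)
  dist_oracle <- sqrt(colSums(((t(stats10) - sObs) / sd2)^2))
  k5 <- abcReject(tab, sObs, 5)
  expect_identical(k5$indices, order(dist_oracle)[1:5])
  expect_error(abcReject(tab, sObs, 11), "exceeds")
})

test_that("model choice is symmetric for indistinguishable models and degenerate for one", {
  set.seed(4)
  n <- 4000
  stats3 <- matrix(stats::rnorm(2 * 3 * n), ncol = 2)
  ids <- rep(c("constant", "lgm", "interglacial"), each = n)
  pri <- list(constant = list(Nc = c(10, 30)),
              lgm = list(Nanc = c(10, 30), Npost = c(10, 30),
                         Texp = c(10, 30)),
              interglacial = list(Nanc = c(10, 30), Npost = c(10, 30),
                                  Texp = c(10, 30)))
  pm <- matrix(stats::runif(3 * n, 10, 30), dimnames = list(NULL, "Nc"))
  tab <- ref_fix(ids, pm, stats3, pri)
  mc <- modelChoice(tab, c(s1 = 0, s2 = 0), nAccept = 1500)
  expect_equal(sum(mc@rejection), 1, tolerance = 1e-9)
  expect_equal(sum(mc@logistic), 1, tolerance = 1e-9)
  expect_true(all(abs(mc@rejection - 1 / 3) < 0.05))
  expect_true(all(abs(mc@logistic - 1 / 3) < 0.10))
  # all-accepted-one-model: probability 1 for it
  tab1 <- ref_fix(rep("lgm", 50),
                  matrix(stats::runif(150, 10, 30), ncol = 3,
                         dimnames = list(NULL, c("Nanc", "Npost", "Texp"))),
                  matrix(stats::rnorm(100), 50, 2), pri["lgm"])
  mc1 <- modelChoice(tab1, c(s1 = 0, s2 = 0), nAccept = 20)
  expect_equal(unname(mc1@rejection["lgm"]), 1)
  expect_equal(unname(mc1@logistic["lgm"]), 1)
})

test_that("well-separated truth gives the expansion model by both methods", {
  spec <- sampleSpec(nDiploid = 10, nSnpLoci = 300)
  tab <- buildReferenceTable(c("constant", "lgm"), spec = spec,
                             nSimsPerModel = 3000, seed = 5)
  set.seed(6)
  obs <- simulateDataset(demographicScenario("lgm", Nanc = 1e4, Npost = 1e5,
                                             Texp = 28000), spec)
  mc <- modelChoice(tab, abcStats(obs$genotypes), nAccept = 300)
  expect_identical(names(which.max(mc@rejection)), "lgm")
  expect_identical(names(which.max(mc@logistic)), "lgm")
  expect_gt(mc@rejection["lgm"], 0.8)
  expect_gt(mc@logistic["lgm"], 0.8)
})

test_that("constant-statistic acceptance makes the adjustment an identity", {
  pri <- list(constant = list(Nc = c(10, 30)))
  theta <- c(seq(11, 29, length.out = 50), rep(15, 10))
  # 50 rows sit exactly at s_obs; 10 decoys far away keep the table sd > 0
  svec <- c(rep(1, 50), rep(5, 10))
  tab <- ref_fix(rep("constant", 60),
                 matrix(theta, dimnames = list(NULL, "Nc")),
                 matrix(svec, ncol = 1), pri)
  post <- estimateParams(tab, c(s1 = 1), "constant", nAccept = 50)
  expect_true("regression_fallback" %in% post@flags)
  expect_equal(sort(unname(post@adjusted[, "Nc"])), sort(theta[1:50]),
               tolerance = 1e-6)
  expect_equal(unname(posteriorQuantiles(post)["Nc", "median"]),
               stats::median(theta[1:50]), tolerance = 0.5)
})

test_that("ABC posterior matches the analytic posterior on a conjugate toy problem", {
  # theta ~ U(10, 30); one observation x ~ N(theta, 1); statistic = x.
  # With s_obs = 20 the posterior is N(20, 1) (truncation negligible).
  set.seed(7)
  nref <- 50000
  theta <- stats::runif(nref, 10, 30)
  x <- theta + stats::rnorm(nref)
  tab <- ref_fix(rep("constant", nref),
                 matrix(theta, dimnames = list(NULL, "Nc")),
                 matrix(x, ncol = 1), list(constant = list(Nc = c(10, 30))))
  post <- estimateParams(tab, c(s1 = 20), "constant", nAccept = 500)
  m <- sum(post@adjusted[, 1] * post@weights) / sum(post@weights)
  expect_lt(abs(m - 20), 0.1)
  qs <- posteriorQuantiles(post)
  expect_lt(abs(qs["Nc", "median"] - 20), 0.15)
  expect_lt(abs(qs["Nc", "q95"] - (20 + 1.645)), 0.35)
  expect_lt(abs(qs["Nc", "q5"] - (20 - 1.645)), 0.35)
  # adjusted draws never exit the prior bounds
  expect_true(all(post@adjusted >= 10 & post@adjusted <= 30))
})

test_that("adjusted draws respect prior bounds under strong extrapolation", {
  set.seed(8)
  spec <- sampleSpec(nDiploid = 8, nSnpLoci = 100)
  tab <- buildReferenceTable("lgm", spec = spec, nSimsPerModel = 2000,
                             seed = 9)
  obs <- simulateDataset(demographicScenario("lgm", Nanc = 200,
                                             Npost = 195000, Texp = 39000),
                         spec)
  post <- estimateParams(tab, abcStats(obs$genotypes), "lgm", 400)
  b <- defaultPriors()$lgm
  for (p in colnames(post@adjusted)) {
    expect_true(all(post@adjusted[, p] >= b[[p]][1]))
    expect_true(all(post@adjusted[, p] <= b[[p]][2]))
  }
})

test_that("posterior medians are invariant to statistic order and affine rescaling", {
  spec <- sampleSpec(nDiploid = 8, nSnpLoci = 150)
  tab <- buildReferenceTable("lgm", spec = spec, nSimsPerModel = 1500,
                             seed = 10)
  set.seed(11)
  obs <- simulateDataset(demographicScenario("lgm", Nanc = 5000, Npost = 8e4,
                                             Texp = 20000), spec)
  sObs <- abcStats(obs$genotypes)
  q1 <- posteriorQuantiles(estimateParams(tab, sObs, "lgm", 300))
  # permute statistic columns
  perm <- c(3, 1, 4, 2)
  tabP <- new("ReferenceTable", modelId = modelId(tab),
              params = refParams(tab),
              stats = refStats(tab)[, perm], statSd = tab@statSd[perm],
              priors = tab@priors, spec = tab@spec)
  q2 <- posteriorQuantiles(estimateParams(tabP, sObs[perm], "lgm", 300))
  expect_equal(q1, q2, tolerance = 1e-8)
  # affine rescaling of one statistic (and of s_obs to match)
  sc <- c(1, 1000, 1, 1)
  sh <- c(0, 3, 0, 0)
  stats_r <- sweep(sweep(refStats(tab), 2, sc, "*"), 2, sh, "+")
  tabR <- new("ReferenceTable", modelId = modelId(tab),
              params = refParams(tab), stats = stats_r,
              statSd = apply(stats_r, 2, stats::sd),
              priors = tab@priors, spec = tab@spec)
  q3 <- posteriorQuantiles(estimateParams(tabR, sObs * sc + sh, "lgm", 300))
  expect_equal(q1, q3, tolerance = 1e-6)
})

test_that("posterior-predictive check is deterministic and flags misfit", {
  spec <- sampleSpec(nDiploid = 8, nSnpLoci = 100)
  tab <- buildReferenceTable("lgm", spec = spec, nSimsPerModel = 1000,
                             seed = 12)
  set.seed(13)
  obs <- simulateDataset(demographicScenario("lgm", Nanc = 8000, Npost = 9e4,
                                             Texp = 25000), spec)
  sObs <- abcStats(obs$genotypes)
  post <- estimateParams(tab, sObs, "lgm", 200)
  p1 <- ppcCheck(post, spec, sObs, nDraws = 150, seed = 14)
  p2 <- ppcCheck(post, spec, sObs, nDraws = 150, seed = 14)
  expect_identical(p1$percentiles, p2$percentiles)
  expect_true(all(p1$percentiles >= 0 & p1$percentiles <= 100))
  # statistics far outside the posterior cloud fail the check
  sFar <- sObs
  sFar["meanH"] <- 10
  pf <- ppcCheck(post, spec, sFar, nDraws = 150, seed = 15)
  expect_identical(unname(pf$percentiles["meanH"]), 100)
  expect_false(pf$within)
})

test_that("posterior error rate is ~0.5 for identical models and validates inputs", {
  set.seed(16)
  n <- 3000
  stats2 <- matrix(stats::rnorm(2 * 2 * n), ncol = 2)
  ids <- rep(c("constant", "lgm"), each = n)
  pri <- list(constant = list(Nc = c(10, 30)),
              lgm = list(Nanc = c(10, 30), Npost = c(10, 30),
                         Texp = c(10, 30)))
  tab <- ref_fix(ids, matrix(stats::runif(2 * n, 10, 30),
                             dimnames = list(NULL, "Nc")), stats2, pri)
  per <- posteriorErrorRate(tab, c(s1 = 0, s2 = 0), nPseudo = 300,
                            nAccept = 200, resimulate = FALSE, seed = 17)
  expect_lt(abs(per$errorRate - 0.5), 0.1)
  expect_error(posteriorErrorRate(tab, c(s1 = 0, s2 = 0), nPseudo = 0),
               "nPseudo")
})

test_that("bias and precision are zero when truth is degenerate and estimation exact", {
  pri <- list(constant = list(Nc = c(10, 30)))
  post <- new("ABCPosterior", model = "constant",
              accepted = matrix(20, 50, 1, dimnames = list(NULL, "Nc")),
              adjusted = matrix(20, 50, 1, dimnames = list(NULL, "Nc")),
              weights = rep(1, 50), distances = rep(0, 50), threshold = 0,
              quantiles = matrix(20, 1, 3,
                                 dimnames = list("Nc",
                                                 c("q5", "median", "q95"))),
              priors = pri$constant, flags = character(0))
  tab <- ref_fix(rep("constant", 20),
                 matrix(stats::runif(20, 10, 30),
                        dimnames = list(NULL, "Nc")),
                 matrix(stats::rnorm(40), 20, 2), pri,
                 spec = sampleSpec(nDiploid = 4, nSnpLoci = 5))
  bp <- biasPrecision(post, tab, nDatasets = 20,
                      estimator = function(s) c(Nc = 20), seed = 18)
  expect_equal(unname(bp$relativeBias["Nc"]), 0)
  expect_equal(unname(bp$relativeRmse["Nc"]), 0)
})

test_that("abcFit wires model choice and estimation together", {
  spec <- sampleSpec(nDiploid = 8, nSnpLoci = 150)
  tab <- buildReferenceTable(c("constant", "lgm"), spec = spec,
                             nSimsPerModel = 1500, seed = 19)
  set.seed(20)
  obs <- simulateDataset(demographicScenario("lgm", Nanc = 5000, Npost = 1e5,
                                             Texp = 28000), spec)
  fit <- abcFit(tab, g = obs$genotypes, nAccept = 300)
  expect_s4_class(fit$modelChoice, "ModelChoiceResult")
  expect_s4_class(fit$posterior, "ABCPosterior")
  expect_identical(fit$posterior@model, fit$bestModel)
})
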