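# Coalescent simulator: analytic expectations, oracle equivalence,
# polymorphism guarantees, determinism.

test_that("pairwise TMRCA under constant size matches E[T2] = 2Nc", {
  Nc <- 1000
  reps <- 10000
  tm <- simulateTmrca(2, demographicScenario("constant", Nc = Nc), reps,
                      seed = 101)
  # T2 ~ Exp(mean 2Nc), so SE of the mean is 2Nc / sqrt(reps)
  se <- 2 * Nc / sqrt(reps)
  expect_lt(abs(mean(tm) - 2 * Nc), 3 * se)
  expect_lt(abs(stats::var(tm) - (2 * Nc)^2), 4 * (2 * Nc)^2 / sqrt(reps) * 3)
})

test_that("expansion with Texp beyond all coalescences reduces to constant", {
  N <- 2000
  exp_far <- demographicScenario("lgm", Nanc = 50, Npost = N, Texp = 1e12)
  cons <- demographicScenario("constant", Nc = N)
  t1 <- simulateTmrca(6, exp_far, 4000, seed = 11)
  t2 <- simulateTmrca(6, cons, 4000, seed = 12)
  expect_gt(stats::ks.test(t1, t2)$p.value, 0.01)
})

test_that("tree structure is a valid ultrametric-in-time genealogy", {
  sc <- demographicScenario("lgm", Nanc = 500, Npost = 5e4, Texp = 100)
  tr <- simulateTree(8, sc, seed = 3)
  expect_s3_class(tr, "phylo")
  expect_identical(ape::Ntip(tr), 8L)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  expect_equal(attr(tr, "total.length"), sum(tr$edge.length))
  # all tips equidistant in time from the root
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(diff(range(depths[1:8])), 0, tolerance = 1e-9)
})

test_that("TMRCA distribution matches a discrete Wright-Fisher oracle at tiny N", {
  # constant N = 40
  reps <- 4000
  set.seed(21)
  wf_const <- replicate(reps, oracle_wf_tmrca(6, function(t) 40))
  tm_const <- simulateTmrca(6, demographicScenario("constant", Nc = 40),
                            reps, seed = 22)
  expect_gt(suppressWarnings(stats::ks.test(tm_const, wf_const))$p.value, 0.01)
  # step change N = 50 -> 25 at generation 30 (backwards)
  set.seed(23)
  wf_step <- replicate(reps,
    oracle_wf_tmrca(6, function(t) if (t < 30) 50 else 25))
  sc <- demographicScenario("lgm", Nanc = 25, Npost = 50, Texp = 30)
  tm_step <- simulateTmrca(6, sc, reps, seed = 24)
  expect_gt(suppressWarnings(stats::ks.test(tm_step, wf_step))$p.value, 0.01)
})

test_that("single SNP mutation: 2-tip trees yield singletons; placement is branch-proportional", {
  sc <- demographicScenario("constant", Nc = 100)
  set.seed(31)
  for (r in 1:20) {
    tr <- simulateTree(2, sc)
    expect_identical(sum(simulateSnpLocus(tr)), 1L)
  }
  # star-like tree: one branch carries 97% of total length
  star <- structure(list(
    edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2, byrow = TRUE),
    edge.length = c(97, 1.5, 1.5),
    tip.label = c("h1", "h2", "h3"), Nnode = 1L),
    class = "phylo")
  set.seed(32)
  hits <- replicate(3000, simulateSnpLocus(star)[1] == 1L)
  expect_lt(abs(mean(hits) - 0.97), 0.02)
})

test_that("site-frequency spectrum matches the neutral 1/i law", {
  n <- 10
  counts <- simulateSnpCounts(n, demographicScenario("constant", Nc = 5000),
                              20000, seed = 41)
  expect_true(all(counts >= 1 & counts <= n - 1))
  obs <- tabulate(counts, nbins = n - 1)
  gof <- stats::chisq.test(obs, p = oracle_sfs_probs(n))
  expect_gt(gof$p.value, 0.01)
})

test_that("fast count sampler agrees with the length-weighted tree route", {
  # SNP loci are conditioned on being variable, which tilts the genealogy
  # measure by total branch length; the tree-route estimate therefore
  # weights each simulated genealogy by its total length.
  sc <- demographicScenario("lgm", Nanc = 300, Npost = 3e4, Texp = 2000)
  n <- 8
  fast <- simulateSnpCounts(n, sc, 40000, seed = 51)
  pf <- tabulate(fast, nbins = n - 1) / 40000
  set.seed(52)
  reps <- 6000
  cnt <- numeric(reps); wt <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- simulateTree(n, sc)
    cnt[r] <- sum(simulateSnpLocus(tr))
    wt[r] <- attr(tr, "total.length")
  }
  ps <- vapply(seq_len(n - 1), function(i) sum(wt[cnt == i]) / sum(wt),
               numeric(1))
  expect_lt(max(abs(pf - ps)), 0.025)
})

test_that("sequence loci: mu = 0 gives identical haplotypes; E[pi] = theta for n = 2", {
  sc <- demographicScenario("constant", Nc = 1000)
  tr <- simulateTree(5, sc, seed = 61)
  a0 <- simulateSequenceLocus(tr, 0, 100)
  expect_identical(length(unique(as.character(a0))), 1L)
  # n = 2: mean pairwise differences ~ theta = 4 Nc mu L
  mu <- 1e-6; L <- 500; Nc <- 1000
  theta <- 4 * Nc * mu * L
  set.seed(62)
  reps <- 2000
  diffs <- replicate(reps, {
    tr2 <- simulateTree(2, sc)
    m <- as.matrix(simulateSequenceLocus(tr2, mu, L))
    sum(m[1, ] != m[2, ])
  })
  # Var(pi) for n=2 is theta + theta^2 (mixture of Poisson over Exp branch)
  se <- sqrt(theta + theta^2) / sqrt(reps)
  expect_lt(abs(mean(diffs) - theta), 4 * se)
})

test_that("strong expansion leaves negative Tajima's D and excess singletons", {
  exp_sc <- demographicScenario("lgm", Nanc = 1000, Npost = 1e5, Texp = 1e4)
  con_sc <- demographicScenario("constant", Nc = 1e5)
  set.seed(71)
  ds <- replicate(60, {
    d <- simulateDataset(exp_sc, sampleSpec(nDiploid = 10, nSnpLoci = 5,
                                            nSeqLoci = 8,
                                            seqLocusLength = 140),
                         muPerSite = 1e-7)
    tajimasD(d$alignments)$pooled
  })
  ds <- ds[is.finite(ds)]
  expect_lt(mean(ds), 0)
  # singleton excess relative to constant at matched current size
  n <- 20
  ce <- simulateSnpCounts(n, exp_sc, 20000, seed = 72)
  cc <- simulateSnpCounts(n, con_sc, 20000, seed = 73)
  expect_gt(mean(ce == 1 | ce == n - 1), mean(cc == 1 | cc == n - 1))
})

test_that("simulated datasets have the requested shape, polymorphism and missingness", {
  sc <- demographicScenario("lgm", Nanc = 1e4, Npost = 1e5, Texp = 28000)
  d <- simulateDataset(sc, sampleSpec(nDiploid = 12, nSnpLoci = 500), seed = 81)
  g <- genotypes(d$genotypes)
  expect_identical(dim(g), c(12L, 500L))
  expect_false(anyNA(g))
  p <- colMeans(g) / 2
  expect_true(all(p > 0 & p < 1))  # polymorphic before missingness
  d2 <- simulateDataset(sc, sampleSpec(nDiploid = 12, nSnpLoci = 400,
                                       missingRate = 0.15), seed = 82)
  mr <- mean(is.na(genotypes(d2$genotypes)))
  expect_lt(abs(mr - 0.15), 0.02)
  expect_identical(d$truth, sc)
})

test_that("identical seeds give bit-identical simulations", {
  sc <- demographicScenario("interglacial", Nanc = 5000, Npost = 5e4,
                            Texp = 120000)
  spec <- sampleSpec(nDiploid = 8, nSnpLoci = 50, nSeqLoci = 2)
  d1 <- simulateDataset(sc, spec, seed = 91)
  d2 <- simulateDataset(sc, spec, seed = 91)
  expect_identical(genotypes(d1$genotypes), genotypes(d2$genotypes))
  expect_identical(as.character(alignments(d1$alignments)[[1]]),
                   as.character(alignments(d2$alignments)[[1]]))
})

test_that("invalid scenarios are rejected", {
  expect_error(demographicScenario("constant", Nc = 1),
               "finite and >= 2")
  expect_error(demographicScenario("lgm", Nanc = 100, Npost = 1000,
                                   Texp = -5), "Texp")
  expect_error(simulateTree(1, demographicScenario("constant", Nc = 10)),
               "nHaploid")
})
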