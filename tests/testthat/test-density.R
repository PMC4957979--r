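test_that("gaussianKernel matches its closed form and kernel axioms", {
  expect_identical(gaussianKernel(123, 123, 80), 1)
  expect_equal(gaussianKernel(100, 180, 80), exp(-1 / 2), tolerance = 1e-15)
  expect_equal(gaussianKernel(1, 241, 80), exp(-4.5), tolerance = 1e-15)
  # symmetric, strictly decreasing in |xi - xj|
  xi <- sample.int(3057, 25)
  xj <- sample.int(3057, 25)
  expect_equal(gaussianKernel(xi, xj, 80), gaussianKernel(xj, xi, 80))
  d <- 0:500
  expect_true(all(diff(gaussianKernel(0, d, 80)) < 0))
  expect_error(gaussianKernel(1, 2, 0), "positive")
  expect_error(gaussianKernel(1, 2, -3), "positive")
})

test_that("smoothDensity reproduces the literal double-sum", {
  set.seed(11)
  for (L in c(40, 151, 400)) {
    y <- rpois(L, 0.3)
    expect_equal(smoothDensity(y, b = 80), oracleSmooth(y, 80),
                 tolerance = 1e-13)
    expect_equal(smoothDensity(y, b = 7.5), oracleSmooth(y, 7.5),
                 tolerance = 1e-13)
  }
})

test_that("smoothing is a convex combination: identities and bracketing", {
  set.seed(12)
  # constant input is a fixed point
  expect_equal(smoothDensity(rep(3, 200), b = 80), rep(3, 200),
               tolerance = 1e-13)
  # a single count is smoothed symmetrically around its site
  y <- tabulate(250, 500)
  s <- smoothDensity(y, b = 30)
  expect_equal(which.max(s), 250L)
  d <- 1:100
  expect_equal(s[250 - d], s[250 + d], tolerance = 1e-9)
  # min(y) <= yHat <= max(y) everywhere
  y2 <- rpois(600, 2)
  s2 <- smoothDensity(y2, b = 80)
  expect_true(all(s2 >= min(y2) - 1e-12 & s2 <= max(y2) + 1e-12))
})

test_that("the smoother is linear in the counts", {
  set.seed(13)
  y1 <- rpois(300, 1)
  y2 <- rpois(300, 0.5)
  expect_equal(smoothDensity(3.7 * y1, 80), 3.7 * smoothDensity(y1, 80),
               tolerance = 1e-12)
  expect_equal(smoothDensity(y1 + y2, 80),
               smoothDensity(y1, 80) + smoothDensity(y2, 80),
               tolerance = 1e-12)
})

test_that("bandwidth limits: b -> Inf gives the mean, b -> 0 the data", {
  set.seed(14)
  y <- rpois(120, 1.5)
  expect_equal(smoothDensity(y, b = 1e7), rep(mean(y), 120),
               tolerance = 1e-6)
  expect_equal(smoothDensity(y, b = 0.05), y, tolerance = 1e-9)
})

test_that("truncated kernel support agrees with the full sum", {
  set.seed(15)
  y <- rpois(1500, 0.4)
  full <- smoothDensity(y, b = 80)
  expect_equal(smoothDensity(y, b = 80, cutoff = 6 * 80), full,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(smoothDensity(y, b = 80, cutoff = 80),
                                full, tolerance = 1e-9)))
})

test_that("countPerPosition separates classes and rejects silent/other", {
  rec <- rbind(
    makeRecords(12, "Missense_Mutation", "C1", "p.A12V"),
    makeRecords(12, "Missense_Mutation", "C2", "p.A12G"),
    makeRecords(5, "Nonsense_Mutation", "C3", "p.R5X"))
  cat <- classifyCatalog(rec, "tcga", L = 50)
  y <- countPerPosition(cat, "missense")
  expect_equal(length(y), 50L)
  expect_equal(y[12], 2L)       # two distinct uniques at one site
  expect_equal(sum(y), 2L)
  # truncating-only sites do not leak into the missense track
  expect_equal(countPerPosition(cat, "missense")[5], 0L)
  expect_equal(countPerPosition(cat, "truncating")[5], 1L)
  expect_error(countPerPosition(cat, "silent"))
  # empty catalog -> zero vector
  empty <- classifyCatalog(makeRecords(integer(0), character(0)), "tcga",
                           L = 50)
  expect_equal(countPerPosition(empty, "missense"), rep(0L, 50))
})

test_that("expectedRate: uniform model and its silent-calibrated limit", {
  cfg <- syntheticConfig(nNonsilent = 286, missenseFraction = 206 / 286,
                         silentRatio = 0, seed = 21)
  cat <- classifyCatalog(generateCatalog(cfg), "tcga")
  er <- expectedRate(cat, "missense")
  expect_equal(er$n, 206L)
  expect_equal(er$expected, rep(206 / 3057, 3057))
  expect_equal(er$expected[1], 0.06739, tolerance = 1e-3)
  # no silent records -> the calibrated model names the missing input
  expect_error(expectedRate(cat, "missense", mode = "silent_calibrated",
                            ratio = 2), "silent")
  # one silent mutation at every residue smooths to a constant, so the
  # calibrated model collapses to the uniform one
  L <- 60
  rec <- rbind(
    makeRecords(c(10, 40), "Missense_Mutation", c("C1", "C2"),
                c("p.A10V", "p.A40V")),
    makeRecords(seq_len(L), "Silent", sprintf("S%d", seq_len(L)),
                sprintf("p.L%dL", seq_len(L))))
  cat2 <- classifyCatalog(rec, "tcga", L = L)
  erU <- expectedRate(cat2, "missense", mode = "uniform")
  erS <- expectedRate(cat2, "missense", mode = "silent_calibrated",
                      ratio = 2, b = 10)
  expect_equal(erS$expected, erU$expected, tolerance = 1e-12)
  expect_equal(sum(erS$expected), erS$n, tolerance = 1e-12)
  expect_equal(erS$mode, "silent_calibrated")
})

test_that("Clopper-Pearson matches binom.test and the zero closed form", {
  # dual route: the qbeta construction against R's exact binomial test
  for (k in c(0L, 1L, 7L, 25L, 50L)) {
    ci <- clopperPearson(k, 50, alpha = 0.05)
    ref <- stats::binom.test(k, 50)$conf.int
    expect_equal(unname(ci[, "lower"]), ref[1], tolerance = 1e-10)
    expect_equal(unname(ci[, "upper"]), ref[2], tolerance = 1e-10)
  }
  # zero successes: upper bound has the closed form 1 - (a/2)^(1/n)
  for (n in c(10, 206, 3057)) {
    a <- 0.05 / 3057
    expect_equal(unname(clopperPearson(0, n, a)[, "upper"]),
                 1 - (a / 2)^(1 / n), tolerance = 1e-10)
  }
  expect_error(clopperPearson(3, 10, alpha = 1.2), "alpha")
  expect_error(clopperPearson(11, 10), "\\[0, n\\]")
})

test_that("foldProfile: null self-consistency and Bonferroni arithmetic", {
  L <- 3057
  n <- 206
  expected <- rep(n / L, L)
  fp <- foldProfile(expected, expected, n)
  expect_equal(fp$fold, rep(1, L))
  expect_true(all(fp$ciLow <= 1 & fp$ciHigh >= 1))
  expect_equal(fp$alphaAdjusted, 0.05 / 3057)
  expect_equal(fp$alphaAdjusted, 1.636e-5, tolerance = 1e-3)
  # expected 0 with signal -> infinity sentinel, flagged
  fp2 <- foldProfile(c(0.5, 0, 0), c(0, 0, 0.1), n = 10)
  expect_identical(fp2$fold[1], Inf)
  expect_true(is.na(fp2$fold[2]))
  expect_setequal(fp2$flagged, 1:2)
  expect_error(foldProfile(expected, expected, n, alpha = 0), "alpha")
  expect_error(foldProfile(expected, expected, n = 0), "n")
})

test_that("densityProfile assembles a consistent per-residue profile", {
  cfg <- syntheticConfig(nNonsilent = 286, seed = 22)
  cat <- classifyCatalog(generateCatalog(cfg), "tcga")
  pr <- densityProfile(cat, "missense")
  expect_s4_class(pr, "DensityProfile")
  df <- as.data.frame(pr)
  expect_equal(nrow(df), 3057L)
  expect_equal(sum(df$y), 206)
  expect_equal(sum(df$y), pr@n)
  # convex-combination bracketing survives the pipeline
  expect_true(all(df$yHat >= 0 & df$yHat <= max(df$y)))
  # band brackets the estimate wherever defined
  ok <- is.finite(df$fold)
  expect_true(all(df$ciLow[ok] <= df$fold[ok] + 1e-9))
  expect_true(all(df$ciHigh[ok] >= df$fold[ok] - 1e-9))
  # enrichment is visible where it was simulated
  expect_gt(mean(df$fold[2711:2962]), mean(df$fold[1:2700]))
  expect_error(densityProfile(cat, "missense", alpha = 2), "alpha")
  # class with no mutations -> explicit error
  noTrunc <- classifyCatalog(
    makeRecords(10, "Missense_Mutation", "C1", "p.A10V"), "tcga", L = 100)
  expect_error(densityProfile(noTrunc, "truncating"), "no unique")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDensityProfile(pr, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(names(back),
               c("position", "y", "yHat", "expected", "fold",
                 "ciLow", "ciHigh"))
  expect_equal(back$yHat, signif(df$yHat, 6))
})
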