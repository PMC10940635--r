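# per-week association scans, LOD conversion, top SNP, effect summaries

test_that("LOD conversion is -log10(p) with domain checks", {
  expect_equal(lodFromP(1), 0)
  expect_equal(lodFromP(1e-7), 7)
  expect_equal(round(lodFromP(0.05 / 849), 1), 4.2)
  expect_error(lodFromP(0), "0, 1")
  expect_error(lodFromP(-0.1), "0, 1")
  expect_error(lodFromP(1.1), "0, 1")
})

test_that("ANOVA scan agrees with stats::lm on hand-built and random data", {
  g <- rep(0:2, each = 3)
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  res <- associationTest(g, y, min_class_n = 2)
  orc <- anovaOracle(y, g)
  expect_equal(res$p_value, orc$p)
  expect_equal(res$r_squared, orc$r2)
  expect_equal(res$mean_S2S2, 2)
  expect_equal(res$mean_S1S1, 4)

  set.seed(101)
  for (i in 1:25) {
    n <- sample(30:80, 1)
    g <- sample(0:2, n, TRUE)
    y <- rnorm(n, mean = g * runif(1, 0, 1), sd = 1)
    res <- associationTest(g, y, min_class_n = 2)
    orc <- anovaOracle(y, g)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_equal(res$r_squared, orc$r2, tolerance = 1e-10)
  }
})

test_that("regression model matches stats::lm slope test", {
  set.seed(202)
  for (i in 1:10) {
    n <- 60
    g <- sample(0:2, n, TRUE)
    y <- rnorm(n, g * 0.4)
    res <- associationTest(g, y, model = "regression", min_class_n = 2)
    fit <- summary(stats::lm(y ~ g))
    expect_equal(res$p_value, fit$coefficients["g", 4], tolerance = 1e-10)
    expect_equal(res$r_squared, fit$r.squared, tolerance = 1e-10)
  }
})

test_that("ANOVA r_squared equals regression r_squared with two classes", {
  set.seed(33)
  g <- rep(c(0L, 2L), each = 15)
  y <- rnorm(30, g)
  a <- associationTest(g, y, model = "anova")
  r <- associationTest(g, y, model = "regression")
  expect_equal(a$r_squared, r$r_squared, tolerance = 1e-12)
  expect_equal(a$p_value, r$p_value, tolerance = 1e-10)
})

test_that("degenerate and invariance cases behave", {
  # identical class means -> F = 0, p = 1, lod = 0
  g <- rep(0:2, each = 5)
  y <- rep(c(2, 2, 2), each = 5)
  res <- associationTest(g, y)
  expect_equal(res$p_value, 1)
  expect_equal(res$lod, 0)

  # permuting animal order leaves the p-value unchanged
  set.seed(5)
  g <- sample(0:2, 40, TRUE)
  y <- rnorm(40, g)
  perm <- sample(40)
  expect_equal(associationTest(g, y, min_class_n = 2)$p_value,
               associationTest(g[perm], y[perm], min_class_n = 2)$p_value)

  # fewer than two usable classes: untested, p undefined
  res2 <- associationTest(rep(2L, 20), rnorm(20, 30))
  expect_false(res2$tested)
  expect_true(is.na(res2$p_value))

  # a class below min_class_n is excluded from the test
  g3 <- c(rep(0L, 10), rep(2L, 10), 1L)
  y3 <- rnorm(21, g3)
  res3 <- associationTest(g3, y3, min_class_n = 5)
  expect_equal(res3$n_used, 20)
})

test_that("scanTimeseries has scan shape, skips empty weeks, matches single tests", {
  set.seed(61)
  n <- 60
  geno <- makeGeno(matrix(sample(0:2, 8 * n, TRUE), 8, n))
  w <- matrix(rnorm(n * 4, 30, 3), n, 4)
  w[, 3] <- NA   # an all-missing week
  pheno <- makePheno(w, weeks = c(3L, 4L, 5L, 6L))
  expect_warning(scan <- scanTimeseries(geno, pheno), "week 5")
  expect_equal(nrow(scan), 8 * 3)
  expect_equal(sort(unique(scan$week)), c(3L, 4L, 6L))
  # per-row agreement with the scalar interface
  row <- scan[scan$marker_id == "m004" & scan$week == 4, ]
  single <- associationTest(genotypeCalls(geno)["m004", ], w[, 2])
  expect_equal(row$p_value, single$p_value)
  expect_equal(row$mean_H, single$mean_H)

  # disjoint animal sets error
  pheno2 <- makePheno(matrix(30, 2, 1,
                             dimnames = list(c("zz1", "zz2"), "3")))
  expect_error(scanTimeseries(geno, pheno2), "no animals shared")
})

test_that("two-stage scan shows the sample-size discontinuity at targeted markers", {
  set.seed(71)
  cfg <- testSimConfig(seed = 71, n_animals = 120, n_markers = 40,
                       n_chrom = 1)
  sim <- simulateAilGenotypes(cfg)
  ph <- simulateWeightSeries(sim, cfg)
  extremes <- selectExtremes(ph$phenotypes, 20, 60)
  others <- setdiff(animalIds(sim$genotypes), extremes)
  top_mk <- sim$truth$qtl$marker_id
  merged <- mergeTwoStage(sim$genotypes[, extremes],
                          sim$genotypes[top_mk, others])
  scan <- scanTimeseries(merged, ph$phenotypes, weeks = 20)
  expect_true(all(scan$n_used[scan$marker_id == top_mk] > 100))
  expect_true(all(scan$n_used[scan$marker_id != top_mk] <= 60))
})

test_that("null p-values are approximately uniform (seeded)", {
  # AIL genotypes, phenotype pure noise; markers spread over many
  # chromosomes so between-test correlation stays modest
  cfg <- testSimConfig(seed = 99, n_animals = 400, n_markers = 200,
                       n_chrom = 20, additive_g = 0)
  sim <- simulateAilGenotypes(cfg)
  set.seed(1234)
  ps <- unlist(lapply(1:5, function(i) {
    y <- rnorm(400, 35, 4)
    .subset2(ailqtl:::.scanCore(genotypeCalls(sim$genotypes), y), "p_value")
  }))
  expect_length(ps, 1000)
  d <- suppressWarnings(stats::ks.test(ps, "punif"))$statistic
  expect_lt(unname(d), 0.05)
})

test_that("top SNP obeys the tie-break order", {
  scan <- profileAsScan(c(3.0, 5.1, 5.1), positions = c(10, 20, 30))
  scan$n_used <- 50; scan$week <- 10L
  top <- topSnp(scan)
  expect_equal(top$marker_id, "m002")   # smaller bp wins the tie

  # across weeks: the global maximum, earlier week on ties
  multi <- rbind(profileAsScan(c(1, 2, 3), week = 10L),
                 profileAsScan(c(1, 6, 3), week = 12L),
                 profileAsScan(c(1, 6, 3), week = 11L))
  expect_equal(topSnp(multi)$week, 11L)

  none <- profileAsScan(c(1, 2, 3))
  none$tested <- FALSE
  expect_error(topSnp(none), "no tested marker")
})

test_that("effect summaries reproduce the published worked contrasts", {
  # chromosome-15 top SNP, week 20: class means 44.41 / 41.17 / 39.01 g
  e15 <- effectSummaryFromMeans(44.41, 41.17, 39.01)
  expect_equal(e15$diff_S1_S2_g, 5.40)
  expect_equal(round(e15$pct_S1_over_S2, 1), 13.8)
  expect_equal(e15$diff_S1_H_g, 3.24)
  expect_equal(round(e15$pct_S1_over_H, 1), 7.9)
  # chromosome-16 top SNP, week 18: 40.45 / 38.15 / 36.19 g
  e16 <- effectSummaryFromMeans(40.45, 38.15, 36.19)
  expect_equal(round(e16$pct_S1_over_S2, 1), 11.8)
  expect_equal(round(e16$pct_S1_over_H, 1), 6.0)
  # equal class means: all contrasts zero
  e0 <- effectSummaryFromMeans(40, 40, 40)
  expect_equal(unlist(e0), c(diff_S1_S2_g = 0, pct_S1_over_S2 = 0,
                             diff_S1_H_g = 0, pct_S1_over_H = 0))

  # from raw data: summary recomputes the class means it contrasts
  g <- rep(c(2L, 1L, 0L), each = 4)
  y <- rep(c(44, 41, 39), each = 4) + rep(c(-1, 1, 0, 0), 3)
  es <- effectSummary(g, y)
  expect_equal(es$mean_S1S1, 44)
  expect_equal(es$diff_S1_S2_g, 5)
  expect_equal(es$pct_S1_over_S2, 100 * 5 / 39)
})
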