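# synthetic AIL generator: genotypes, weights, selection, dataset emission

test_that("F1 is fully heterozygous; founders are opposite homozygotes", {
  cfg <- testSimConfig(seed = 41, n_animals = 50, n_markers = 30,
                       n_generations = 1)
  sim <- simulateAilGenotypes(cfg)
  expect_true(all(genotypeCalls(sim$genotypes) == 1L))
})

test_that("F10 genotype frequencies approach 1/4 : 1/2 : 1/4", {
  cfg <- testSimConfig(seed = 42, n_animals = 400, n_markers = 60, n_chrom = 3)
  sim <- simulateAilGenotypes(cfg)
  calls <- genotypeCalls(sim$genotypes)
  # per-marker heterozygosity within 3 binomial SE of 0.5 on average,
  # and the pooled frequencies close to the expectation
  het <- rowMeans(calls == 1L)
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(mean(het) - 0.5), 3 * se)
  freq <- tabulate(calls + 1L, 3) / length(calls)
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.05)
})

test_that("LD decays with map distance; chromosomes segregate independently", {
  cfg <- testSimConfig(seed = 43, n_animals = 400, n_markers = 80, n_chrom = 2)
  sim <- simulateAilGenotypes(cfg)
  calls <- genotypeCalls(sim$genotypes)
  map <- markerMap(sim$genotypes)
  on1 <- which(map$chromosome == "1")
  r_adj <- abs(cor(calls[on1[1], ], calls[on1[2], ]))       # ~2.5 Mb apart
  r_far <- abs(cor(calls[on1[1], ], calls[on1[length(on1)], ]))  # ~100 Mb
  expect_gt(r_adj, r_far)
  expect_gt(r_adj, 0.5)
  # different chromosomes: |r| below a 3/sqrt(n) sampling bound
  on2 <- which(map$chromosome == "2")
  r_x <- abs(cor(calls[on1[5], ], calls[on2[5], ]))
  expect_lt(r_x, 3 / sqrt(400))
})

test_that("every offspring call is Mendelian-consistent with its parents", {
  cfg <- testSimConfig(seed = 44, n_animals = 60, n_markers = 40,
                       n_generations = 5)
  sim <- simulateAilGenotypes(cfg, keep_history = TRUE)
  hist <- sim$truth$history
  expect_length(hist, 5)
  for (gen in 2:5) {
    prev <- hist[[gen - 1]]
    cur <- hist[[gen]]
    # no self matings; haplotype 1 descends from the sire, 2 from the dam
    expect_true(all(cur$sire != cur$dam))
    for (i in seq_along(cur$sire)) {
      s <- cur$sire[i]; d <- cur$dam[i]
      expect_true(all(cur$hap1[, i] == prev$hap1[, s] |
                        cur$hap1[, i] == prev$hap2[, s]))
      expect_true(all(cur$hap2[, i] == prev$hap1[, d] |
                        cur$hap2[, i] == prev$hap2[, d]))
    }
  }
  # full-sib avoidance from generation 3 on (all F1 are sibs by design)
  for (gen in 3:5) {
    cur <- hist[[gen]]; prev <- hist[[gen - 1]]
    sib <- prev$sire[cur$sire] == prev$sire[cur$dam] &
      prev$dam[cur$sire] == prev$dam[cur$dam]
    expect_false(any(sib, na.rm = TRUE))
  }
})

test_that("zero effects and zero noise reproduce the growth mean exactly", {
  cfg <- testSimConfig(seed = 45, n_animals = 20, n_markers = 10,
                       additive_g = 0)
  cfg$polygenic_sd_g <- 0
  cfg$residual_sd_g <- 0
  cfg$baseline_sd_g <- 0
  sim <- simulateAilGenotypes(cfg)
  ph <- simulateWeightSeries(sim, cfg)
  mu <- cfg$growth$asymptote_g /
    (1 + exp(-cfg$growth$rate * (cfg$weeks - cfg$growth$inflection_week)))
  for (i in 1:20)
    expect_equal(unname(weightMatrix(ph$phenotypes)[i, ]), mu)
})

test_that("attenuation window scales the genetic value in those weeks only", {
  cfg <- testSimConfig(seed = 46, n_animals = 50, n_markers = 10,
                       attenuation = list(multiplier = 0.2, weeks = 21:23))
  cfg$polygenic_sd_g <- 0
  sim <- simulateAilGenotypes(cfg)
  ph <- simulateWeightSeries(sim, cfg)
  g <- sim$truth$qtl_calls[1, ]
  gv <- ph$genetic_values
  wk <- cfg$weeks
  frac <- ailqtl:::.growthMean(wk, cfg$growth) / cfg$growth$asymptote_g
  hom <- which(g == 2)[1]
  expect_equal(unname(gv[hom, wk == 20]), 2.7 * frac[wk == 20])
  expect_equal(unname(gv[hom, wk == 22]), 0.2 * 2.7 * frac[wk == 22])
  expect_equal(unname(gv[hom, wk == 25]), 2.7 * frac[wk == 25])
})

test_that("extreme selection is deterministic with id tie-breaks", {
  w <- matrix(1:10, ncol = 1, dimnames = list(sprintf("a%02d", 1:10), "20"))
  p <- PhenotypeSeries(w)
  expect_equal(selectExtremes(p, 20, 4), c("a01", "a02", "a09", "a10"))
  expect_equal(selectExtremes(p, 20, 10), sprintf("a%02d", 1:10))
  # ties at the cutoff resolved by animal id
  wt <- matrix(c(5, 5, 5, 1, 9), ncol = 1,
               dimnames = list(c("c", "b", "a", "lo", "hi"), "20"))
  expect_equal(selectExtremes(PhenotypeSeries(wt), 20, 4),
               sort(c("lo", "a", "hi", "b")))
})

test_that("selective genotyping inflates the naive effect estimate", {
  set.seed(47)
  diffs <- vapply(1:10, function(rep) {
    cfg <- testSimConfig(seed = 400 + rep, n_animals = 300, n_markers = 20,
                         n_chrom = 1, additive_g = 1.5)
    sim <- simulateAilGenotypes(cfg)
    ph <- simulateWeightSeries(sim, cfg)
    qtl_mk <- sim$truth$qtl$marker_id
    g <- genotypeCalls(sim$genotypes)[qtl_mk, ]
    y <- weightMatrix(ph$phenotypes)[, "20"]
    full <- mean(y[g == 2]) - mean(y[g == 0])
    ext <- selectExtremes(ph$phenotypes, 20, 100)
    sub_est <- mean(y[ext][g[ext] == 2]) - mean(y[ext][g[ext] == 0])
    sub_est - full
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("dataset emission is byte-identical per seed and split correctly", {
  cfg <- testSimConfig(seed = 48, n_animals = 60, n_markers = 20)
  cfg$selective_n <- 30L
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  f1 <- emitDataset(cfg, d1)
  f2 <- emitDataset(cfg, d2)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  # targeted file holds exactly the unselected animals at the QTL markers
  trg <- readGenotypes(f1$targeted)
  expect_equal(nAnimals(trg), 30)
  arr <- readGenotypes(f1$genotypes)
  expect_equal(nAnimals(arr), 30)
  expect_equal(nMarkers(arr), 20)
  expect_length(intersect(animalIds(arr), animalIds(trg)), 0)
  # a different seed produces different genotypes
  cfg2 <- testSimConfig(seed = 49, n_animals = 60, n_markers = 20)
  cfg2$selective_n <- 30L
  f3 <- emitDataset(cfg2, file.path(tempfile(), "run3"))
  expect_false(identical(readLines(f1$genotypes), readLines(f3$genotypes)))
})
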