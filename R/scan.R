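# per-week single-marker association scans, LOD conversion, top-SNP
# selection and genotype-class effect summaries.

.P_FLOOR <- 1e-300   # keeps LOD finite when a p-value underflows

#' Convert a p-value to a LOD score
#'
#' The evidence scale used throughout: `LOD = -log10(p)`.
#'
#' @param p p-value(s) in (0, 1].
#' @return `-log10(p)`.
#' @examples
#' lodFromP(0.05 / 849)  # the genome-wide significance cutoff, ~4.23
#' @export
lodFromP <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    .stopf("p-values must lie in (0, 1]")
  -log10(p)
}

# vectorised one-way ANOVA / additive-regression scan over a marker matrix.
# G: markers x animals codes {0,1,2,NA}; y: phenotype vector (animals).
# Genotype classes with fewer than min_class_n animals are excluded from the
# test (their animals are dropped); a marker with < 2 remaining classes is
# flagged untested.  Returns one row per marker.
.scanCore <- function(G, y, model = c("anova", "regression"),
                      min_class_n = 5L) {
  model <- match.arg(model)
  ok <- !is.na(y)
  G <- G[, ok, drop = FALSE]
  y <- y[ok]
  m <- nrow(G)
  if (!length(y)) {
    return(data.frame(n_used = integer(m), p_value = NA_real_,
                      lod = NA_real_, r_squared = NA_real_,
                      mean_S2S2 = NA_real_, sd_S2S2 = NA_real_, n_S2S2 = 0L,
                      mean_H = NA_real_, sd_H = NA_real_, n_H = 0L,
                      mean_S1S1 = NA_real_, sd_S1S1 = NA_real_, n_S1S1 = 0L,
                      tested = FALSE))
  }
  y2 <- y * y
  ind <- lapply(0:2, function(cls) {
    M <- G == cls
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  n_c <- vapply(ind, rowSums, numeric(m))                    # m x 3
  s_c <- vapply(ind, function(M) as.vector(M %*% y), numeric(m))
  ss_c <- vapply(ind, function(M) as.vector(M %*% y2), numeric(m))
  if (m == 1) {  # vapply collapses to vectors for a single marker
    n_c <- matrix(n_c, 1); s_c <- matrix(s_c, 1); ss_c <- matrix(ss_c, 1)
  }
  keep <- n_c >= min_class_n
  k <- rowSums(keep)
  N <- rowSums(n_c * keep)
  S <- rowSums(s_c * keep)
  SS <- rowSums(ss_c * keep)
  tested <- k >= 2 & (N - k) >= 1
  SST <- SS - S^2 / pmax(N, 1)
  SSB <- rowSums((s_c^2 / pmax(n_c, 1)) * keep) - S^2 / pmax(N, 1)
  SSB <- pmax(SSB, 0)
  SSW <- pmax(SST - SSB, 0)
  p <- rep(NA_real_, m)
  r2 <- rep(NA_real_, m)
  if (model == "anova") {
    Fstat <- (SSB / pmax(k - 1, 1)) / (SSW / pmax(N - k, 1))
    Fstat[SSB <= 0] <- 0
    idx <- which(tested)
    p[idx] <- pf(Fstat[idx], k[idx] - 1, N[idx] - k[idx], lower.tail = FALSE)
    r2[idx] <- ifelse(SST[idx] > 0, SSB[idx] / SST[idx], 0)
  } else {
    # least-squares slope on the additive codes, two-sided t-test
    Sg <- rowSums(t(t(n_c * keep) * c(0, 1, 2)))
    Sg2 <- rowSums(t(t(n_c * keep) * c(0, 1, 4)))
    Sgy <- rowSums(t(t(s_c * keep) * c(0, 1, 2)))
    vg <- N * Sg2 - Sg^2
    vy <- N * SS - S^2
    tested <- tested & vg > 0 & N >= 3
    r <- (N * Sgy - Sg * S) / sqrt(pmax(vg * vy, .Machine$double.eps))
    r <- pmin(pmax(r, -1), 1)
    idx <- which(tested)
    tt <- r[idx] * sqrt((N[idx] - 2) / pmax(1 - r[idx]^2, .Machine$double.eps))
    p[idx] <- 2 * pt(-abs(tt), N[idx] - 2)
    r2[idx] <- r[idx]^2
  }
  p[tested] <- pmin(pmax(p[tested], .P_FLOOR), 1)
  mean_c <- s_c / n_c                                        # NaN where n=0
  var_c <- (ss_c - s_c^2 / pmax(n_c, 1)) / pmax(n_c - 1, 1)
  sd_c <- sqrt(pmax(var_c, 0))
  mean_c[n_c == 0] <- NA_real_
  sd_c[n_c < 2] <- NA_real_
  data.frame(
    n_used = as.integer(N),   # animals in the classes actually tested
    p_value = p,
    lod = ifelse(is.na(p), NA_real_, -log10(p)),
    r_squared = r2,
    mean_S2S2 = mean_c[, 1], sd_S2S2 = sd_c[, 1], n_S2S2 = as.integer(n_c[, 1]),
    mean_H = mean_c[, 2], sd_H = sd_c[, 2], n_H = as.integer(n_c[, 2]),
    mean_S1S1 = mean_c[, 3], sd_S1S1 = sd_c[, 3], n_S1S1 = as.integer(n_c[, 3]),
    tested = tested)
}

#' Single-marker association test
#'
#' Tests one marker against one week's phenotype.  The default model is a
#' one-way fixed-effects ANOVA with genotype as a (up to) three-level factor,
#' which directly yields the per-class means reported alongside; the
#' alternative is a least-squares regression on the additive codes 0/1/2
#' with a two-sided t-test on the slope.  Pairs with a missing genotype or
#' phenotype are dropped; genotype classes with fewer than `min_class_n`
#' animals are excluded, and a marker with fewer than two usable classes is
#' flagged untested (`tested = FALSE`, `p_value = NA`).
#'
#' @param geno_row numeric vector of genotype codes `{0,1,2,NA}`, named or
#'   aligned with `pheno_week`.
#' @param pheno_week numeric vector of phenotype values (same animals).
#' @param model `"anova"` (default) or `"regression"`.
#' @param min_class_n minimum animals per genotype class (default 5).
#' @return One-row `data.frame` with `p_value`, `lod`, `r_squared` (between-
#'   group over total sum of squares for the ANOVA, squared correlation for
#'   the regression), `n_used`, per-class means/sds/counts and `tested`.
#' @export
associationTest <- function(geno_row, pheno_week,
                            model = c("anova", "regression"),
                            min_class_n = 5L) {
  stopifnot(length(geno_row) == length(pheno_week))
  keep <- !is.na(geno_row)
  .scanCore(matrix(geno_row[keep], nrow = 1), pheno_week[keep],
            match.arg(model), min_class_n)
}

#' Per-week genome scan over a weight time series
#'
#' Runs [associationTest()] for every marker at every week.  Weeks are
#' scanned independently (no longitudinal covariance model).  Animals are
#' matched between genotypes and phenotypes by id; a week in which every
#' matched animal is missing is skipped with a warning.  On a merged
#' two-stage matrix the `n_used` column reflects the larger sample at the
#' targeted markers and the array-only sample elsewhere.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param pheno a [PhenotypeSeries-class].
#' @param model,min_class_n see [associationTest()].
#' @param weeks optional subset of weeks to scan.
#' @return `data.frame` with one row per (marker, week): `marker_id`,
#'   `chromosome`, `position_bp`, `week`, then the [associationTest()]
#'   columns.
#' @export
scanTimeseries <- function(geno, pheno, model = c("anova", "regression"),
                           min_class_n = 5L, weeks = NULL) {
  stopifnot(is(geno, "GenotypeMatrix"), is(pheno, "PhenotypeSeries"))
  model <- match.arg(model)
  animals <- intersect(animalIds(geno), animalIds(pheno))
  if (!length(animals))
    .stopf("no animals shared between genotypes and phenotypes")
  G <- genotypeCalls(geno)[, animals, drop = FALSE]
  W <- weightMatrix(pheno)[animals, , drop = FALSE]
  all_weeks <- phenoWeeks(pheno)
  if (is.null(weeks)) weeks <- all_weeks
  weeks <- intersect(weeks, all_weeks)
  map <- markerMap(geno)
  out <- vector("list", length(weeks))
  for (i in seq_along(weeks)) {
    y <- W[, match(weeks[i], all_weeks)]
    if (all(is.na(y))) {
      .warnf("week %d has no phenotype data; skipped", weeks[i])
      next
    }
    res <- .scanCore(G, y, model, min_class_n)
    out[[i]] <- cbind(map, week = weeks[i], res)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) .stopf("no week could be scanned")
  rownames(out) <- NULL
  out
}

#' Locate the top SNP of a region
#'
#' Returns the (marker, week) pair with the maximum LOD among tested markers,
#' optionally restricted to a chromosome, a bp window and/or a set of weeks.
#' Ties are broken by smaller p-value, then smaller bp position, then earlier
#' week.
#'
#' @param scan result of [scanTimeseries()].
#' @param chromosome,start_bp,end_bp optional region restriction.
#' @param weeks optional week restriction.
#' @return The winning row of `scan` (one-row `data.frame`).
#' @export
topSnp <- function(scan, chromosome = NULL, start_bp = NULL, end_bp = NULL,
                   weeks = NULL) {
  d <- scan[scan$tested & !is.na(scan$p_value), , drop = FALSE]
  if (!is.null(chromosome)) d <- d[d$chromosome %in% chromosome, , drop = FALSE]
  if (!is.null(start_bp)) d <- d[d$position_bp >= start_bp, , drop = FALSE]
  if (!is.null(end_bp)) d <- d[d$position_bp <= end_bp, , drop = FALSE]
  if (!is.null(weeks)) d <- d[d$week %in% weeks, , drop = FALSE]
  if (!nrow(d)) .stopf("no tested marker in the requested region")
  d[order(-d$lod, d$p_value, d$position_bp, d$week), , drop = FALSE][1, ]
}

#' Genotype-class effect summary
#'
#' Summarizes the phenotypic effect at a marker as class means (± sd) and the
#' founder-line contrasts: the S1/S1 minus S2/S2 difference in grams and as a
#' percentage of the S2/S2 mean, and likewise versus the heterozygotes.
#'
#' @param geno_row,pheno_week as in [associationTest()].
#' @param min_class_n minimum animals for a class mean to be reported
#'   (default 1; absent classes yield `NA` fields).
#' @return One-row `data.frame` with class statistics and the four contrast
#'   statistics (see [effectSummaryFromMeans()]).
#' @export
effectSummary <- function(geno_row, pheno_week, min_class_n = 1L) {
  stopifnot(length(geno_row) == length(pheno_week))
  st <- .scanCore(matrix(geno_row, nrow = 1), pheno_week,
                  model = "anova", min_class_n = min_class_n)
  eff <- effectSummaryFromMeans(st$mean_S1S1, st$mean_H, st$mean_S2S2)
  cbind(st[c("mean_S1S1", "sd_S1S1", "n_S1S1", "mean_H", "sd_H", "n_H",
             "mean_S2S2", "sd_S2S2", "n_S2S2", "r_squared")], eff)
}

#' Effect contrasts from genotype-class means
#'
#' The founder-line contrasts as reported in AIL studies: absolute difference
#' in grams and percent increase relative to the reference class
#' (`pct = 100 * (mean_S1S1 - mean_ref) / mean_ref`).
#'
#' @param mean_S1S1,mean_H,mean_S2S2 genotype-class means (grams).
#' @return One-row `data.frame` with `diff_S1_S2_g`, `pct_S1_over_S2`,
#'   `diff_S1_H_g`, `pct_S1_over_H`.
#' @examples
#' # class means 44.41 / 41.17 / 39.01 g give a 5.40 g (13.8%) contrast
#' effectSummaryFromMeans(44.41, 41.17, 39.01)
#' @export
effectSummaryFromMeans <- function(mean_S1S1, mean_H, mean_S2S2) {
  data.frame(
    diff_S1_S2_g = mean_S1S1 - mean_S2S2,
    pct_S1_over_S2 = 100 * (mean_S1S1 - mean_S2S2) / mean_S2S2,
    diff_S1_H_g = mean_S1S1 - mean_H,
    pct_S1_over_H = 100 * (mean_S1S1 - mean_H) / mean_H)
}
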