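# phenotype outlier removal, marker informativeness filtering, and the
# two-stage (array + targeted assay) genotype merge.

#' Remove per-week phenotype outliers
#'
#' An observation is an outlier if it deviates from that week's population
#' mean by strictly more than `k_sd` standard deviations.  Mean and sd are
#' computed once per week over the non-missing values (a single pass; the
#' rule is not iterated), so re-applying the function to its own output with
#' the original statistics removes nothing further.
#'
#' @param pheno a [PhenotypeSeries-class].
#' @param k_sd threshold in standard deviations (default 3).
#' @return A list with `phenotypes` (the filtered series) and `removed`
#'   (data.frame of `animal_id`, `week`, `weight_g` for each removed cell).
#'   A week with fewer than 2 observations is skipped with a warning.
#' @examples
#' w <- matrix(c(rep(10, 99), 25), ncol = 1,
#'             dimnames = list(sprintf("a%02d", 1:100), "5"))
#' removeOutliers(PhenotypeSeries(w))$removed
#' @export
removeOutliers <- function(pheno, k_sd = 3) {
  stopifnot(is(pheno, "PhenotypeSeries"), k_sd > 0)
  w <- weightMatrix(pheno)
  weeks <- phenoWeeks(pheno)
  removed <- list()
  for (j in seq_along(weeks)) {
    x <- w[, j]
    obs <- !is.na(x)
    if (sum(obs) < 2) {
      .warnf("week %d has fewer than 2 observations; outlier rule skipped",
             weeks[j])
      next
    }
    m <- mean(x[obs])
    s <- sd(x[obs])
    out <- obs & abs(x - m) > k_sd * s   # s == 0 makes the rule vacuous
    if (any(out)) {
      removed[[length(removed) + 1L]] <- data.frame(
        animal_id = rownames(w)[out], week = weeks[j], weight_g = x[out])
      w[out, j] <- NA_real_
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(animal_id = character(), week = integer(),
                             weight_g = numeric())
  rownames(removed) <- NULL
  list(phenotypes = PhenotypeSeries(w, weeks), removed = removed)
}

#' Drop uninformative markers
#'
#' Removes markers that are monomorphic among their non-missing calls (only
#' one genotype class observed) or whose missing rate exceeds `max_missing`.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param max_missing maximum tolerated fraction of missing calls
#'   (default 0.10).
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterInformative <- function(geno, max_missing = 0.10) {
  stopifnot(is(geno, "GenotypeMatrix"))
  m <- genotypeCalls(geno)
  miss <- rowMeans(is.na(m))
  n_classes <- vapply(seq_len(nrow(m)), function(i) {
    length(unique(m[i, !is.na(m[i, ])]))
  }, integer(1))
  keep <- n_classes >= 2L & miss <= max_missing
  geno[keep, ]
}

#' Merge array and targeted-assay genotypes
#'
#' Combines the genome-wide array genotypes of a selectively genotyped subset
#' with targeted-assay (e.g. KASP) calls at a few top markers for the
#' remaining animals.  The result covers the union of animals on the array's
#' marker map: at targeted markers most or all animals are non-missing, at
#' array-only markers the targeted-only animals are missing — the two sample
#' sizes the per-marker scan later reports.  Every non-missing input call is
#' preserved; a conflicting call for the same (marker, animal) is an error.
#'
#' @param array_geno [GenotypeMatrix-class] from the array stage.
#' @param targeted_geno [GenotypeMatrix-class] with calls at a subset of the
#'   array's markers (possibly for different animals).
#' @return Merged [GenotypeMatrix-class].
#' @export
mergeTwoStage <- function(array_geno, targeted_geno) {
  stopifnot(is(array_geno, "GenotypeMatrix"), is(targeted_geno, "GenotypeMatrix"))
  extra <- setdiff(markerIds(targeted_geno), markerIds(array_geno))
  if (length(extra))
    .stopf("targeted marker(s) absent from the array map: %s",
           paste(extra, collapse = ", "))
  a <- genotypeCalls(array_geno)
  t <- genotypeCalls(targeted_geno)
  animals <- union(colnames(a), colnames(t))
  out <- matrix(NA_integer_, nrow(a), length(animals),
                dimnames = list(rownames(a), animals))
  out[, colnames(a)] <- a
  for (mk in rownames(t)) {
    old <- out[mk, colnames(t)]
    new <- t[mk, ]
    conflict <- !is.na(old) & !is.na(new) & old != new
    if (any(conflict))
      .stopf("conflicting calls at marker '%s' for animal '%s'",
             mk, colnames(t)[which(conflict)[1]])
    out[mk, colnames(t)] <- ifelse(is.na(new), old, new)
  }
  GenotypeMatrix(out, markerMap(array_geno))
}
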