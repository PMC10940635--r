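# effective number of independent tests (simpleM) and Bonferroni LOD
# thresholds derived from it.

#' Effective number of independent tests (simpleM)
#'
#' Estimates the effective number of independent markers from the eigenvalue
#' spectrum of the between-marker genotype correlation.  Markers are
#' partitioned chromosome-wise into consecutive map-ordered windows of at
#' most `window_size` markers (windows never span chromosomes; a final short
#' window is kept as-is).  Within each window, missing calls are mean-imputed
#' per marker, the Pearson correlation matrix of the genotype codes is
#' eigendecomposed, eigenvalues below zero from numerical noise are clamped
#' to zero, and the window's count is the smallest k such that the top-k
#' eigenvalues reach a fraction `C` of the total eigenvalue sum.  The
#' estimate `m_eff` is the sum over windows.
#'
#' Zero-variance (monomorphic) markers carry no correlation information and
#' are excluded from their window's matrix with a warning.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param window_size maximum markers per window (default 820).
#' @param C fraction of eigenvalue variance to capture (default 0.995, the
#'   published simpleM choice).
#' @return An object of class `MeffEstimate`: a list with `m_eff`,
#'   `window_size`, `C` and a per-window `data.frame` `windows`
#'   (`chromosome`, `window`, `n_markers`, `n_used`, `count`).
#' @examples
#' g <- GenotypeMatrix(matrix(rep(c(0L, 1L, 2L, 1L), 3), nrow = 3,
#'                            byrow = TRUE),
#'                     data.frame(marker_id = c("m1", "m2", "m3"),
#'                                chromosome = "1",
#'                                position_bp = c(1, 2, 3) * 1e6))
#' meffSimpleM(g)$m_eff  # three identical markers -> 1
#' @export
meffSimpleM <- function(geno, window_size = 820L, C = 0.995) {
  stopifnot(is(geno, "GenotypeMatrix"), window_size >= 1, C > 0, C <= 1)
  map <- markerMap(geno)
  calls <- genotypeCalls(geno)
  if (!nrow(map)) .stopf("at least one marker is required")
  windows <- list()
  m_eff <- 0L
  for (chr in .chromLevels(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    starts <- seq(1L, length(idx), by = window_size)
    for (wi in seq_along(starts)) {
      take <- idx[starts[wi]:min(starts[wi] + window_size - 1L, length(idx))]
      X <- t(calls[take, , drop = FALSE]) * 1.0     # animals x markers
      for (j in seq_len(ncol(X))) {                 # per-marker mean imputation
        nas <- is.na(X[, j])
        if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
      }
      v <- apply(X, 2, stats::var)
      if (any(v == 0 | is.na(v))) {
        .warnf("window %s/%d: %d zero-variance marker(s) excluded",
               chr, wi, sum(v == 0 | is.na(v)))
        X <- X[, v > 0 & !is.na(v), drop = FALSE]
      }
      count <- if (ncol(X) == 0) {
        0L
      } else if (ncol(X) == 1) {
        1L
      } else {
        ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
        ev <- pmax(ev, 0)
        as.integer(which(cumsum(ev) >= C * sum(ev))[1])
      }
      windows[[length(windows) + 1L]] <- data.frame(
        chromosome = chr, window = wi, n_markers = length(take),
        n_used = ncol(X), count = count)
      m_eff <- m_eff + count
    }
  }
  structure(list(m_eff = m_eff, window_size = as.integer(window_size), C = C,
                 windows = do.call(rbind, windows)),
            class = "MeffEstimate")
}

#' @export
print.MeffEstimate <- function(x, ...) {
  cat(sprintf(
    "simpleM estimate: m_eff = %d over %d window(s) (window_size = %d, C = %g)\n",
    x$m_eff, nrow(x$windows), x$window_size, x$C))
  invisible(x)
}

#' Bonferroni LOD thresholds for an effective number of tests
#'
#' The genome-wide LOD cutoff at family-wise level `alpha` is
#' `-log10(alpha / m_eff)`.  With `m_eff = 849` the conventional 0.05 and
#' 0.01 levels give 4.23 and 4.93 (reported to one decimal as 4.2 and 4.9).
#'
#' @param m_eff effective number of independent tests (integer >= 1), or a
#'   `MeffEstimate`.
#' @param alphas family-wise error levels in (0, 1).
#' @return `data.frame` with columns `alpha` and `lod_threshold` (decreasing
#'   in `alpha`).
#' @examples
#' bonferroniLodThresholds(849)
#' @export
bonferroniLodThresholds <- function(m_eff, alphas = c(0.05, 0.01)) {
  if (inherits(m_eff, "MeffEstimate")) m_eff <- m_eff$m_eff
  stopifnot(length(m_eff) == 1, m_eff >= 1)
  if (any(alphas <= 0 | alphas >= 1))
    .stopf("alpha levels must lie in (0, 1)")
  data.frame(alpha = alphas, lod_threshold = -log10(alphas / m_eff))
}
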