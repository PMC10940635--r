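# independent oracles and small fixture builders shared across tests

# genotype matrix on one chromosome from a plain matrix of codes
makeGeno <- function(calls, chromosome = "1",
                     positions = seq_len(nrow(calls)) * 1e6) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("a%03d", seq_len(ncol(calls)))
  GenotypeMatrix(calls,
                 data.frame(marker_id = sprintf("m%03d", seq_len(nrow(calls))),
                            chromosome = chromosome,
                            position_bp = positions))
}

makePheno <- function(weights, weeks = seq_len(ncol(weights)) + 2L) {
  if (is.null(rownames(weights)))
    rownames(weights) <- sprintf("a%03d", seq_len(nrow(weights)))
  PhenotypeSeries(weights, weeks)
}

# one-way ANOVA via stats::lm/anova — the reference route for the scan's
# hand-vectorised sums-of-squares F-test
anovaOracle <- function(y, g) {
  fit <- stats::lm(y ~ factor(g))
  a <- stats::anova(fit)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       r2 = summary(fit)$r.squared)
}

# Benjamini-Hochberg step-up written out longhand
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  cummin(p[o] * m / (m:1))[ro]
}

# exhaustive-search version of the 1.5-LOD-drop interval: test every
# contiguous run containing the top marker instead of walking outward
lodDropOracle <- function(lods, positions, drop = 1.5) {
  stopifnot(!is.unsorted(positions, strictly = TRUE))
  top <- order(-lods, positions)[1]
  cut <- lods[top] - drop
  lo <- min(Filter(function(i) all(lods[i:top] >= cut), seq_len(top)))
  hi <- max(Filter(function(j) all(lods[top:j] >= cut),
                   top:length(lods)))
  list(top = top,
       start = positions[if (lo > 1) lo - 1 else 1],
       end = positions[if (hi < length(lods)) hi + 1 else length(lods)])
}

# wrap a bare LOD profile as a minimal scan data.frame
profileAsScan <- function(lods, positions = seq_along(lods) * 1e5,
                          week = 10L, chromosome = "1") {
  data.frame(marker_id = sprintf("m%03d", seq_along(lods)),
             chromosome = chromosome, position_bp = positions,
             week = week, p_value = 10^(-lods), lod = lods, tested = TRUE)
}

# random DNA of length n
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

revcompStr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# tiny AIL simulation configuration used across tests
testSimConfig <- function(seed = 1, n_animals = 200, n_markers = 100,
                          n_chrom = 2, chr_len = 1e8, n_generations = 10,
                          additive_g = 2.7, attenuation = NULL, qtl = NULL) {
  chrs <- simChromosomes(n_markers,
                         setNames(rep(chr_len, n_chrom),
                                  as.character(seq_len(n_chrom))))
  if (is.null(qtl))
    qtl <- list(list(chromosome = "1", position_bp = chr_len / 2,
                     additive_g = additive_g, dominance_g = 0,
                     attenuation = attenuation))
  simConfig(seed = seed, n_animals = n_animals, n_generations = n_generations,
            chromosomes = chrs, qtl = qtl,
            selective_n = min(200L, n_animals))
}
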