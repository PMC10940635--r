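# pedigree-based simulation of an advanced intercross line with known truth:
# genotypes by gamete dropping with Haldane recombination, weekly weights
# from a logistic growth mean plus QTL, polygenic and residual components.

# mm10 autosome lengths (Mb), used to spread markers over a realistic map
.MOUSE_AUTOSOME_MB <- c(195.5, 182.1, 160.0, 156.5, 151.8, 149.7, 145.4,
                        129.4, 124.6, 130.7, 122.1, 120.1, 120.4, 124.9,
                        104.0, 98.2, 95.0, 90.7, 61.4)

#' Chromosome layout for the simulator
#'
#' Distributes a marker total over chromosomes proportionally to length.
#' The default emulates the study design: 19 mouse autosomes carrying ~5,171
#' informative markers.
#'
#' @param n_markers total marker count (default 5171).
#' @param lengths_bp named numeric vector of chromosome lengths in bp
#'   (default: the 19 mouse autosomes).
#' @return `data.frame` with `chromosome`, `length_bp`, `n_markers`.
#' @export
simChromosomes <- function(n_markers = 5171L,
                           lengths_bp = setNames(.MOUSE_AUTOSOME_MB * 1e6,
                                                 as.character(1:19))) {
  frac <- lengths_bp / sum(lengths_bp)
  per <- pmax(1L, round(frac * n_markers))
  # adjust the largest chromosome so the total is exact
  per[which.max(per)] <- per[which.max(per)] + (n_markers - sum(per))
  data.frame(chromosome = names(lengths_bp), length_bp = unname(lengths_bp),
             n_markers = unname(as.integer(per)), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every free parameter of the AIL simulator.  The defaults emulate
#' the study population: an F10 advanced intercross of two opposite-
#' homozygous inbred founders (S1 male x S2 female, then random mating),
#' 397 males, ~5,171 informative markers over 19 autosomes, weekly weights
#' from week 3 to 25 following a logistic growth mean (asymptote 45 g,
#' inflection week 9), two additive QTLs whose homozygote contrasts match the
#' published adult effect sizes (5.4 g on chromosome 15, attenuated 0.2x
#' during the diet-switch window weeks 21-23; 4.2 g on chromosome 16), a
#' polygenic component and residual noise giving an adult within-class SD of
#' about 4 g, and selective genotyping of the 200 phenotypic extremes.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_animals population size (default 397).
#' @param n_generations intercross generation returned (default 10, i.e.
#'   F10; 1 returns the fully heterozygous F1).
#' @param chromosomes layout from [simChromosomes()].
#' @param cM_per_Mb genetic map density (default 0.5; Haldane map function).
#' @param qtl list of QTL specifications, each a list with `chromosome`,
#'   `position_bp`, `additive_g` (half the adult homozygote contrast),
#'   `dominance_g`, and optional `attenuation = list(multiplier, weeks)`
#'   scaling the effect inside a diet-switch window.
#' @param growth list `asymptote_g`, `rate`, `inflection_week` of the
#'   logistic growth mean.
#' @param weeks ages at which weight is recorded (default 3:25).
#' @param residual_sd_g residual SD at adult weight (scalar, interpolated
#'   towards `baseline_sd_g` at young ages) or one value per week.
#' @param baseline_sd_g residual SD floor at weaning age (default 1 g).
#' @param polygenic_sd_g SD of the per-animal polygenic value at adult
#'   weight (default 2.5 g).
#' @param selective_n animals chosen for array genotyping (default 200).
#' @param proxy_week week whose weight serves as the selection proxy
#'   (default 20, the last standard-diet week).
#' @param targeted_markers marker ids assayed in the remaining animals
#'   (default `NULL`: the markers nearest the true QTLs).
#' @param diet feeding schedule from [dietSchedule()].
#' @return List of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      n_animals = 397L,
                      n_generations = 10L,
                      chromosomes = simChromosomes(),
                      cM_per_Mb = 0.5,
                      qtl = list(
                        list(chromosome = "15", position_bp = 77.4e6,
                             additive_g = 2.7, dominance_g = 0,
                             attenuation = list(multiplier = 0.2,
                                                weeks = 21:23)),
                        list(chromosome = "16", position_bp = 17.0e6,
                             additive_g = 2.1, dominance_g = 0,
                             attenuation = NULL)),
                      growth = list(asymptote_g = 45, rate = 0.21,
                                    inflection_week = 9),
                      weeks = 3:25,
                      residual_sd_g = 3,
                      baseline_sd_g = 1,
                      polygenic_sd_g = 2.5,
                      selective_n = 200L,
                      proxy_week = 20L,
                      targeted_markers = NULL,
                      diet = dietSchedule()) {
  cfg <- list(seed = as.integer(seed), n_animals = as.integer(n_animals),
              n_generations = as.integer(n_generations),
              chromosomes = chromosomes, cM_per_Mb = cM_per_Mb, qtl = qtl,
              growth = growth, weeks = as.integer(weeks),
              residual_sd_g = residual_sd_g, baseline_sd_g = baseline_sd_g,
              polygenic_sd_g = polygenic_sd_g,
              selective_n = as.integer(selective_n),
              proxy_week = as.integer(proxy_week),
              targeted_markers = targeted_markers, diet = diet)
  stopifnot(cfg$n_animals >= 2, cfg$n_generations >= 1,
            cfg$selective_n <= cfg$n_animals, cfg$cM_per_Mb >= 0)
  for (q in cfg$qtl) {
    stopifnot(is.finite(q$additive_g), is.finite(q$dominance_g),
              q$chromosome %in% chromosomes$chromosome)
    if (!is.null(q$attenuation)) stopifnot(q$attenuation$multiplier >= 0)
  }
  structure(cfg, class = "SimConfig")
}

# marker map + per-interval recombination fractions (Haldane); the first
# marker of each chromosome gets r = 0.5, which makes chromosomes segregate
# independently in the vectorised gamete dropper.
.simMap <- function(cfg) {
  maps <- lapply(seq_len(nrow(cfg$chromosomes)), function(i) {
    chr <- cfg$chromosomes$chromosome[i]
    n <- cfg$chromosomes$n_markers[i]
    len <- cfg$chromosomes$length_bp[i]
    pos <- round(seq(len / (n + 1), len * n / (n + 1), length.out = n))
    data.frame(marker_id = sprintf("M%s_%04d", chr, seq_len(n)),
               chromosome = chr, position_bp = pos)
  })
  map <- do.call(rbind, maps)
  d_bp <- unlist(lapply(maps, function(m) c(NA, diff(m$position_bp))))
  d_morgan <- (d_bp / 1e6) * cfg$cM_per_Mb / 100
  r <- 0.5 * (1 - exp(-2 * d_morgan))
  r[is.na(r)] <- 0.5
  list(map = map, r = r)
}

# one generation of gametes: for each of n_off offspring and each parent in
# `par` (column index into hap1/hap2), draw a recombinant gamete.  `r` holds
# the switch probability ahead of each marker (0.5 at chromosome starts).
.dropGametes <- function(hap1, hap2, par, r) {
  m <- nrow(hap1)
  G <- length(par)
  switches <- matrix(runif(m * G) < r, m, G)      # r recycles down columns
  path <- apply(switches * 1L, 2, cumsum) %% 2
  if (m == 1) path <- matrix(path, 1)
  out <- hap1[, par, drop = FALSE]
  alt <- hap2[, par, drop = FALSE]
  out[path == 1] <- alt[path == 1]
  out
}

# random mating pairs avoiding self- and full-sib matings where possible
.matePairs <- function(n_off, n_parents, sires, dams) {
  s <- sample.int(n_parents, n_off, replace = TRUE)
  d <- sample.int(n_parents, n_off, replace = TRUE)
  for (try in 1:25) {
    full_sib <- !is.na(sires[s]) & sires[s] == sires[d] & dams[s] == dams[d]
    bad <- s == d | full_sib
    if (!any(bad)) break
    # allow full-sib matings only if the whole generation is one sibship
    if (all(!is.na(sires)) && length(unique(paste(sires, dams))) == 1)
      bad <- s == d
    if (!any(bad)) break
    s[bad] <- sample.int(n_parents, sum(bad), replace = TRUE)
    d[bad] <- sample.int(n_parents, sum(bad), replace = TRUE)
  }
  list(sire = s, dam = d)
}

#' Simulate advanced intercross genotypes
#'
#' Gamete-dropping simulation of an AIL: the two founders are opposite-
#' homozygous at every marker (all markers informative), the F1 is fully
#' heterozygous, and each later generation is produced by random mating with
#' self- and full-sib matings avoided whenever an alternative exists.
#' Recombination follows the Haldane map function on the cM distances implied
#' by `cM_per_Mb`; chromosomes segregate independently.
#'
#' @param config a [simConfig()].
#' @param keep_history keep per-generation haplotypes and pedigree (for
#'   Mendelian-consistency checks; default `FALSE`).
#' @return List of class `AilSimulation` with `genotypes` (a
#'   [GenotypeMatrix-class]), and `truth`: `qtl` (`data.frame` of true QTL
#'   positions, nearest markers and effects), `qtl_calls` (QTL-by-animal
#'   genotype codes), and optionally `history`.
#' @export
simulateAilGenotypes <- function(config, keep_history = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  mp <- .simMap(config)
  m <- nrow(mp$map)
  n <- config$n_animals
  # generation 1 = F1 of the S1 male x S2 female founder cross
  hap1 <- matrix(1L, m, n)   # S1-derived gamete
  hap2 <- matrix(0L, m, n)   # S2-derived gamete
  sires <- rep(NA_integer_, n)
  dams <- rep(NA_integer_, n)
  history <- if (keep_history)
    list(list(hap1 = hap1, hap2 = hap2, sire = sires, dam = dams)) else NULL
  if (config$n_generations >= 2) {
    for (gen in 2:config$n_generations) {
      pairs <- .matePairs(n, n, sires, dams)
      new1 <- .dropGametes(hap1, hap2, pairs$sire, mp$r)
      new2 <- .dropGametes(hap1, hap2, pairs$dam, mp$r)
      hap1 <- new1; hap2 <- new2
      sires <- pairs$sire; dams <- pairs$dam
      if (keep_history)
        history[[gen]] <- list(hap1 = hap1, hap2 = hap2,
                               sire = sires, dam = dams)
    }
  }
  calls <- hap1 + hap2
  ids <- sprintf("A%04d", seq_len(n))
  colnames(calls) <- ids
  geno <- GenotypeMatrix(calls, mp$map, animal_ids = ids)
  qtl <- do.call(rbind, lapply(config$qtl, function(q) {
    on_chr <- mp$map[mp$map$chromosome == q$chromosome, ]
    near <- on_chr[which.min(abs(on_chr$position_bp - q$position_bp)), ]
    data.frame(chromosome = q$chromosome, position_bp = q$position_bp,
               marker_id = near$marker_id, marker_bp = near$position_bp,
               additive_g = q$additive_g, dominance_g = q$dominance_g)
  }))
  qtl_calls <- genotypeCalls(geno)[qtl$marker_id, , drop = FALSE]
  structure(list(genotypes = geno,
                 truth = list(qtl = qtl, qtl_calls = qtl_calls,
                              history = history),
                 config = config),
            class = "AilSimulation")
}

.growthMean <- function(weeks, growth) {
  growth$asymptote_g /
    (1 + exp(-growth$rate * (weeks - growth$inflection_week)))
}

#' Simulate the weekly weight series
#'
#' Builds `weight(animal, week) = logistic growth mean + QTL effects +
#' polygenic value + residual noise`.  Each QTL contributes
#' `additive_g * (g - 1) + dominance_g * [g == 1]`, scaled by the growth
#' fraction (mean weight over asymptote) so effects mature with the animals,
#' and by the QTL's attenuation multiplier inside its diet-switch window.
#' The polygenic value is one normal draw per animal, also scaled by the
#' growth fraction; residual noise is independent per cell with an SD
#' interpolated from `baseline_sd_g` at weaning to `residual_sd_g` at adult
#' weight.
#'
#' @param sim result of [simulateAilGenotypes()].
#' @param config the same [simConfig()] (defaults to the one stored in
#'   `sim`).
#' @return List with `phenotypes` (a [PhenotypeSeries-class]) and
#'   `genetic_values` (animals x weeks matrix of the summed QTL + polygenic
#'   contributions).
#' @export
simulateWeightSeries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "AilSimulation"), inherits(config, "SimConfig"))
  set.seed(config$seed + 104729L)   # offset stream: noise, not meioses
  weeks <- config$weeks
  n <- ncol(sim$truth$qtl_calls)
  mu <- .growthMean(weeks, config$growth)
  frac <- mu / config$growth$asymptote_g
  genetic <- matrix(0, n, length(weeks))
  for (i in seq_along(config$qtl)) {
    q <- config$qtl[[i]]
    att <- rep(1, length(weeks))
    if (!is.null(q$attenuation))
      att[weeks %in% q$attenuation$weeks] <- q$attenuation$multiplier
    g <- sim$truth$qtl_calls[i, ]
    genetic <- genetic + outer(g - 1, q$additive_g * frac * att) +
      outer(as.numeric(g == 1), q$dominance_g * frac * att)
  }
  poly <- rnorm(n, 0, config$polygenic_sd_g)
  genetic <- genetic + outer(poly, frac)
  sd_w <- if (length(config$residual_sd_g) == length(weeks))
    config$residual_sd_g
  else config$baseline_sd_g * (1 - frac) + config$residual_sd_g * frac
  eps <- matrix(rnorm(n * length(weeks), 0,
                      rep(sd_w, each = n)), n, length(weeks))
  w <- matrix(mu, n, length(weeks), byrow = TRUE) + genetic + eps
  w <- pmax(w, 0.1)
  rownames(w) <- colnames(sim$truth$qtl_calls)
  colnames(w) <- as.character(weeks)
  rownames(genetic) <- rownames(w)
  list(phenotypes = PhenotypeSeries(w, weeks), genetic_values = genetic)
}

#' Select phenotypic extremes for array genotyping
#'
#' Deterministically picks the `n/2` lowest and `n/2` highest animals by a
#' proxy measurement, emulating selective genotyping of the phenotypic
#' extremes.  Ties at a cutoff are broken by animal id.
#'
#' @param pheno a [PhenotypeSeries-class].
#' @param week week whose weight is the selection proxy.
#' @param n total number of animals to select (split evenly between tails).
#' @return Character vector of selected animal ids.
#' @examples
#' w <- matrix(1:10, ncol = 1, dimnames = list(sprintf("a%02d", 1:10), "20"))
#' selectExtremes(PhenotypeSeries(w), 20, 4)
#' @export
selectExtremes <- function(pheno, week, n) {
  stopifnot(is(pheno, "PhenotypeSeries"), n <= nAnimals(pheno), n >= 2)
  wk <- match(week, phenoWeeks(pheno))
  if (is.na(wk)) .stopf("week %s not present in the phenotype series", week)
  v <- weightMatrix(pheno)[, wk]
  ids <- animalIds(pheno)
  keep <- !is.na(v)
  v <- v[keep]; ids <- ids[keep]
  stopifnot(n <= length(ids))
  n_low <- floor(n / 2)
  low <- ids[order(v, ids)][seq_len(n_low)]
  rest <- setdiff(ids, low)
  vr <- v[match(rest, ids)]
  high <- rest[order(-vr, rest)][seq_len(n - n_low)]
  sort(c(low, high))
}

#' Write a complete simulated dataset to disk
#'
#' Runs the genotype and phenotype simulators and emits the files a real
#' study would provide: the array-stage genotypes of the selected extremes
#' (all markers), targeted-assay genotypes of the remaining animals at the
#' top/targeted markers, the full weekly phenotype table, and a truth record.
#' Output is byte-identical across runs with the same configuration.
#'
#' @param config a [simConfig()].
#' @param out_dir output directory (created if needed).
#' @return Named list of file paths (`genotypes`, `targeted`, `phenotypes`,
#'   `truth`), invisibly.
#' @export
emitDataset <- function(config, out_dir) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateAilGenotypes(config)
  ph <- simulateWeightSeries(sim, config)
  extremes <- selectExtremes(ph$phenotypes, config$proxy_week,
                             config$selective_n)
  others <- setdiff(animalIds(sim$genotypes), extremes)
  targeted <- config$targeted_markers
  if (is.null(targeted)) targeted <- sim$truth$qtl$marker_id
  paths <- list(genotypes = file.path(out_dir, "genotypes_array.tsv"),
                targeted = file.path(out_dir, "genotypes_targeted.tsv"),
                phenotypes = file.path(out_dir, "phenotypes.csv"),
                truth = file.path(out_dir, "truth.json"))
  writeGenotypes(sim$genotypes[, extremes], paths$genotypes)
  writeGenotypes(sim$genotypes[targeted, others], paths$targeted)
  writePhenotypes(ph$phenotypes, paths$phenotypes, format = "long")
  truth <- list(seed = config$seed,
                qtl = sim$truth$qtl,
                targeted_markers = targeted,
                array_animals = extremes,
                n_animals = config$n_animals)
  write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
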