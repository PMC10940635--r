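# end-to-end orchestration: simulate/read -> preprocess -> scan -> m_eff ->
# thresholds -> intervals -> prioritize -> motif, into one run directory.

.pipelineDefaults <- function() {
  list(seed = 1L,
       outliers = list(k_sd = 3),
       filter = list(max_missing = 0.10),
       scan = list(model = "anova", min_class_n = 5L),
       meff = list(window_size = 820L, C = 0.995),
       alphas = c(0.05, 0.01),
       drop = 1.5,
       plots = TRUE)
}

#' Run the full QTL-mapping pipeline
#'
#' One reproducible run: data are either simulated (a `simulate` block with
#' [simConfig()] arguments; `two_stage = TRUE` additionally emulates the
#' selective-genotyping design) or read from files (an `inputs` block with
#' `genotypes`, optional `targeted`, and `phenotypes` paths).  Stages:
#' phenotype outlier removal, marker filtering, optional two-stage merge,
#' per-week scan, simpleM effective test count, Bonferroni LOD thresholds,
#' weekly 1.5-LOD-drop intervals and cross-week aggregation for every
#' chromosome reaching genome-wide significance, and optional candidate
#' prioritization (a `prioritize` block with `genes`, `consequences`,
#' `expression`, `kegg` paths) and ChoRE-motif scanning (a `motif` block with
#' `genome` and `genes` paths).  In a two-stage run, support intervals are
#' computed from a scan restricted to the array-genotyped animals, whose
#' uniform sample size keeps the LOD profile comparable along the map.
#'
#' All artifacts are written into `out_dir`; numeric outputs are
#' deterministic given the configuration (the seed governs simulation only).
#'
#' @param config named list, or path to a YAML file with the same structure.
#' @param out_dir output directory for this run (created; must be empty or
#'   nonexistent).
#' @return Invisibly, a list with the main in-memory results (`scan`,
#'   `meff`, `thresholds`, `qtl`, `spans`, `candidates`, `motif_hits`) and
#'   `out_dir`.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_yaml(config)
  cfg <- modifyList(.pipelineDefaults(), config)
  if (dir.exists(out_dir) && length(dir(out_dir)))
    .stopf("output directory '%s' is not empty", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log <<- c(log, line)
  }

  # ---- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    two_stage <- isTRUE(sim_args$two_stage)
    sim_args$two_stage <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(simConfig, sim_args)
    sim <- simulateAilGenotypes(scfg)
    ph <- simulateWeightSeries(sim, scfg)
    pheno <- ph$phenotypes
    if (two_stage) {
      extremes <- selectExtremes(pheno, scfg$proxy_week, scfg$selective_n)
      others <- setdiff(animalIds(sim$genotypes), extremes)
      targeted <- scfg$targeted_markers
      if (is.null(targeted)) targeted <- sim$truth$qtl$marker_id
      # informativeness QC belongs to the array stage, before the merge
      # adds animals that are missing everywhere off the targeted markers
      array_geno <- filterInformative(sim$genotypes[, extremes],
                                      cfg$filter$max_missing)
      targeted <- intersect(targeted, markerIds(array_geno))
      geno <- mergeTwoStage(array_geno, sim$genotypes[targeted, others])
      array_animals <- extremes
      say("simulated two-stage dataset: %d + %d animals, %d informative markers",
          length(extremes), length(others), nMarkers(geno))
    } else {
      geno <- filterInformative(sim$genotypes, cfg$filter$max_missing)
      array_animals <- animalIds(geno)
      say("simulated dataset: %d animals, %d informative markers",
          nAnimals(geno), nMarkers(geno))
    }
  } else if (!is.null(cfg$inputs)) {
    for (f in c("genotypes", "phenotypes"))
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]]))
        .stopf("input '%s' is missing", f)
    geno <- filterInformative(readGenotypes(cfg$inputs$genotypes),
                              cfg$filter$max_missing)
    pheno <- readPhenotypes(cfg$inputs$phenotypes)
    array_animals <- animalIds(geno)
    if (!is.null(cfg$inputs$targeted)) {
      trg <- readGenotypes(cfg$inputs$targeted)
      trg <- trg[intersect(markerIds(trg), markerIds(geno)), ]
      geno <- mergeTwoStage(geno, trg)
    }
    say("read %d informative markers; %d animals; %d phenotyped",
        nMarkers(geno), nAnimals(geno), nAnimals(pheno))
  } else .stopf("config needs a 'simulate' or 'inputs' block")

  # ---- preprocess ------------------------------------------------------
  outl <- removeOutliers(pheno, cfg$outliers$k_sd)
  pheno <- outl$phenotypes
  write.table(outl$removed, file.path(out_dir, "outliers_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("outlier rule (> %g SD): %d measurement(s) removed",
      cfg$outliers$k_sd, nrow(outl$removed))

  # ---- scan + thresholds ----------------------------------------------
  scan <- scanTimeseries(geno, pheno, model = cfg$scan$model,
                         min_class_n = cfg$scan$min_class_n)
  write.table(scan, file.path(out_dir, "scan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meff <- meffSimpleM(geno, cfg$meff$window_size, cfg$meff$C)
  thresholds <- bonferroniLodThresholds(meff, cfg$alphas)
  sig_lod <- max(thresholds$lod_threshold[thresholds$alpha == max(cfg$alphas)])
  write_json(list(m_eff = meff$m_eff, window_size = meff$window_size,
                  C = meff$C, per_window = meff$windows,
                  thresholds = thresholds),
             file.path(out_dir, "thresholds.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("m_eff = %d; LOD thresholds: %s", meff$m_eff,
      paste(sprintf("%.2f (alpha %g)", thresholds$lod_threshold,
                    thresholds$alpha), collapse = ", "))

  # ---- intervals -------------------------------------------------------
  # interval walk on the uniform-sample scan (array animals only) when the
  # merged matrix mixes two sample sizes
  interval_scan <- scan
  if (length(array_animals) < nAnimals(geno)) {
    interval_scan <- scanTimeseries(geno[, array_animals], pheno,
                                    model = cfg$scan$model,
                                    min_class_n = cfg$scan$min_class_n)
  }
  by_chr <- tapply(scan$lod[scan$tested], scan$chromosome[scan$tested],
                   max, na.rm = TRUE)
  sig_chr <- names(by_chr)[!is.na(by_chr) & by_chr >= sig_lod]
  qtl <- list(); spans <- list(); weekly_all <- list()
  for (chr in sig_chr) {
    top_weekly <- weeklyIntervals(scan, chr, drop = cfg$drop,
                                  threshold = sig_lod)
    wk <- weeklyIntervals(interval_scan, chr, drop = cfg$drop,
                          threshold = sig_lod)
    # significance judged on the full-sample scan, bounds on the uniform one
    wk$significant <- top_weekly$significant[match(wk$week, top_weekly$week)]
    wk$top_lod_full <- top_weekly$top_lod[match(wk$week, top_weekly$week)]
    weekly_all[[chr]] <- wk
    qtl[[chr]] <- aggregateIntervals(wk, only_significant = TRUE)
    sp <- significanceSpan(
      data.frame(week = top_weekly$week, top_lod = top_weekly$top_lod),
      sig_lod)
    if (nrow(sp)) sp$chromosome <- chr
    spans[[chr]] <- sp
    say("QTL on chromosome %s: %d-%d bp, top %s (LOD %.2f)",
        chr, qtl[[chr]]$final_start_bp, qtl[[chr]]$final_end_bp,
        qtl[[chr]]$top_marker, qtl[[chr]]$top_lod)
  }
  if (length(weekly_all)) {
    weekly_tab <- do.call(rbind, weekly_all)
    write.table(weekly_tab, file.path(out_dir, "intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    qtl_tab <- do.call(rbind, lapply(qtl, function(x)
      data.frame(chromosome = x$chromosome, start_bp = x$final_start_bp,
                 end_bp = x$final_end_bp, top_marker = x$top_marker,
                 top_week = x$top_week, top_lod = x$top_lod)))
    writeBed(qtl_tab, file.path(out_dir, "qtl_regions.bed"))
    write_json(lapply(qtl, unclass), file.path(out_dir, "qtl.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    spans_tab <- do.call(rbind, spans)
    write.table(spans_tab, file.path(out_dir, "significance_spans.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("no chromosome reached the genome-wide threshold")
    spans_tab <- NULL
  }

  # ---- optional: candidate prioritization ------------------------------
  candidates <- NULL
  if (!is.null(cfg$prioritize) && length(qtl)) {
    pz <- cfg$prioritize
    genes <- readGeneModels(pz$genes)
    cons <- readConsequences(pz$consequences)
    expr <- if (!is.null(pz$expression)) readExpression(pz$expression) else NULL
    kegg <- if (!is.null(pz$kegg))
      read.table(pz$kegg, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)$gene_id else character()
    candidates <- do.call(rbind, lapply(qtl, function(x) {
      g <- genesInInterval(genes, x)
      if (!length(g)) return(NULL)
      sc <- scoreGenes(g$gene_id, cons, expr, kegg,
                       p_adjusted = isTRUE(pz$p_adjusted))
      cbind(chromosome = x$chromosome, sc)
    }))
    if (!is.null(candidates))
      write.table(candidates, file.path(out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    say("prioritized %d candidate gene(s)",
        if (is.null(candidates)) 0L else nrow(candidates))
  }

  # ---- optional: motif scan -------------------------------------------
  motif_hits <- NULL
  if (!is.null(cfg$motif)) {
    mo <- cfg$motif
    genes <- readGeneModels(mo$genes)
    motif_hits <- scanGeneSet(genes, mo$genome,
                              upstream = if (is.null(mo$upstream)) 2000L
                                         else mo$upstream,
                              min_score = if (is.null(mo$min_score)) 0.90
                                          else mo$min_score)
    write.table(motif_hits, file.path(out_dir, "motif_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(motif_hits))
      writeBed(motif_hits, file.path(out_dir, "motif_hits.bed"))
    say("motif scan: %d hit(s) in %d gene(s)", nrow(motif_hits),
        length(unique(motif_hits$gene_id)))
  }

  # ---- plots, config echo, log ----------------------------------------
  if (isTRUE(cfg$plots)) {
    pdf(file.path(out_dir, "lod_curves.pdf"), width = 9, height = 5)
    plotLodCurves(scan, thresholds)
    dev.off()
  }
  echo <- file.path(out_dir, "config_echo.yaml")
  write_yaml(.yamlSafe(cfg), echo)
  say("config hash: %s", unname(md5sum(echo)))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(list(scan = scan, meff = meff, thresholds = thresholds,
                 qtl = qtl, spans = spans_tab, candidates = candidates,
                 motif_hits = motif_hits, out_dir = out_dir))
}

# yaml::write_yaml chokes on data.frame-bearing nested lists only rarely,
# but drop non-serialisable pieces defensively
.yamlSafe <- function(x) {
  rapply(x, function(e) {
    if (is.data.frame(e)) as.list(e) else e
  }, how = "replace")
}

#' Summarize a completed run as a Markdown report
#'
#' Reads the artifacts of a [runPipeline()] run directory and writes
#' `report.md`: the thresholds, a per-QTL table with interval, top SNP and
#' significance spans, a per-week LOD/class-means table at each QTL's top
#' SNP, the candidate ranking (with a notice when prioritization inputs were
#' not part of the run), and motif hits if present.
#'
#' @param run_dir directory produced by [runPipeline()].
#' @return Path of the report, invisibly.
#' @export
pipelineReport <- function(run_dir) {
  need <- c("scan.tsv", "thresholds.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    .stopf("incomplete run: missing artifact '%s'", missing[1])
  scan <- read.table(file.path(run_dir, "scan.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  th <- read_json(file.path(run_dir, "thresholds.json"), simplifyVector = TRUE)
  out <- c("# QTL mapping run report", "",
           sprintf("Effective number of tests (simpleM): **%d**", th$m_eff),
           "", "| alpha | LOD threshold |", "|---|---|",
           sprintf("| %g | %.2f |", th$thresholds$alpha,
                   th$thresholds$lod_threshold), "")
  qtl_path <- file.path(run_dir, "qtl.json")
  if (file.exists(qtl_path)) {
    qtl <- read_json(qtl_path, simplifyVector = TRUE)
    out <- c(out, "## QTL regions", "",
             "| chr | interval (bp) | top SNP | top week | top LOD | significant weeks |",
             "|---|---|---|---|---|---|")
    for (x in qtl) {
      out <- c(out, sprintf("| %s | %s-%s | %s | %s | %.2f | %s |",
                            x$chromosome,
                            format(x$final_start_bp, big.mark = ","),
                            format(x$final_end_bp, big.mark = ","),
                            x$top_marker, x$top_week, x$top_lod,
                            paste(x$significant_weeks, collapse = " ")))
    }
    out <- c(out, "")
    for (x in qtl) {
      d <- scan[scan$marker_id == x$top_marker, ]
      out <- c(out, sprintf("### Weekly effects at %s (chr %s)",
                            x$top_marker, x$chromosome), "",
               "| week | n | S1/S1 | H | S2/S2 | LOD |", "|---|---|---|---|---|---|",
               sprintf("| %d | %d | %.2f | %.2f | %.2f | %.2f |",
                       d$week, d$n_used, d$mean_S1S1, d$mean_H, d$mean_S2S2,
                       d$lod), "")
    }
  } else {
    out <- c(out, "No genome-wide significant QTL region.", "")
  }
  cand_path <- file.path(run_dir, "candidates.tsv")
  if (file.exists(cand_path)) {
    cand <- read.table(cand_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    out <- c(out, "## Candidate genes", "",
             "| chr | gene | score | rank |", "|---|---|---|---|",
             sprintf("| %s | %s | %g | %d |", cand$chromosome, cand$gene_id,
                     cand$score, cand$rank), "")
  } else {
    out <- c(out, "_No candidate prioritization inputs in this run._", "")
  }
  motif_path <- file.path(run_dir, "motif_hits.tsv")
  if (file.exists(motif_path)) {
    hits <- read.table(motif_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    out <- c(out, "## ChoRE motif hits", "",
             if (nrow(hits))
               c("| gene | motif | position | strand | score |", "|---|---|---|---|---|",
                 sprintf("| %s | %s | %s:%s-%s | %s | %.3f |", hits$gene_id,
                         hits$motif, hits$chromosome, hits$start_bp,
                         hits$end_bp, hits$strand, hits$score))
             else "No hits.", "")
  }
  path <- file.path(run_dir, "report.md")
  writeLines(out, path)
  invisible(path)
}

#' Plot per-week LOD curves
#'
#' One panel per chromosome: the per-week LOD curves in grey, their per-
#' marker maximum in black, and the genome-wide thresholds as dashed lines.
#'
#' @param scan result of [scanTimeseries()].
#' @param thresholds optional [bonferroniLodThresholds()] table.
#' @param chromosomes chromosomes to draw (default: all).
#' @return `NULL`, invisibly.
#' @export
plotLodCurves <- function(scan, thresholds = NULL, chromosomes = NULL) {
  d <- scan[scan$tested & !is.na(scan$lod), ]
  if (is.null(chromosomes)) chromosomes <- .chromLevels(d$chromosome)
  old <- par(mfrow = c(1, min(length(chromosomes), 4)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (chr in chromosomes) {
    dc <- d[d$chromosome == chr, ]
    if (!nrow(dc)) next
    ylim <- c(0, max(dc$lod,
                     if (!is.null(thresholds)) thresholds$lod_threshold) * 1.05)
    plot(NA, xlim = range(dc$position_bp) / 1e6, ylim = ylim,
         xlab = "position (Mb)", ylab = "LOD", main = paste("Chr", chr))
    for (w in unique(dc$week)) {
      dw <- dc[dc$week == w, ]
      lines(dw$position_bp / 1e6, dw$lod, col = "grey70")
    }
    env <- tapply(dc$lod, dc$position_bp, max)
    lines(as.numeric(names(env)) / 1e6, env, lwd = 2)
    if (!is.null(thresholds))
      abline(h = thresholds$lod_threshold, lty = 2, col = "firebrick")
  }
  invisible(NULL)
}
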