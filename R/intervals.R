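# 1.5-LOD-drop support intervals per week, marker-boundary snapping, and
# cross-week aggregation into a final QTL region.

#' Weekly 1.5-LOD-drop support interval
#'
#' Finds the chromosome's top marker for one week, walks outward along the
#' map while the LOD stays within `drop` of the top LOD (a contiguous run —
#' disjoint secondary peaks never extend the interval), and snaps the bounds
#' to the positions of the first markers *beyond* that run, or to the
#' chromosome's terminal markers if the run reaches an end.  Ties at the top
#' are broken by smaller p-value, then smaller bp position.
#'
#' Optionally the walk considers only a marker subset (e.g. the markers
#' genotyped on the array stage, excluding targeted follow-up markers whose
#' larger sample size distorts the LOD profile).
#'
#' @param scan result of [scanTimeseries()].
#' @param week week to evaluate.
#' @param chromosome chromosome to evaluate.
#' @param drop LOD-drop defining the support interval (default 1.5).
#' @param threshold optional genome-wide LOD threshold used to set the
#'   `significant` flag.
#' @param markers optional character vector restricting the walk to a marker
#'   subset.
#' @return One-row `data.frame`: `week`, `chromosome`, `top_marker`,
#'   `top_lod`, `start_bp`, `end_bp`, `significant`.
#' @export
lodDropInterval <- function(scan, week, chromosome, drop = 1.5,
                            threshold = NULL, markers = NULL) {
  d <- scan[scan$week == week & scan$chromosome == chromosome &
              scan$tested & !is.na(scan$lod), , drop = FALSE]
  if (!is.null(markers)) d <- d[d$marker_id %in% markers, , drop = FALSE]
  if (!nrow(d)) .stopf("no tested marker on chromosome %s in week %s",
                       chromosome, week)
  d <- d[order(d$position_bp), , drop = FALSE]
  i_top <- order(-d$lod, d$p_value, d$position_bp)[1]
  cut <- d$lod[i_top] - drop
  lo <- i_top
  while (lo > 1 && d$lod[lo - 1] >= cut) lo <- lo - 1
  hi <- i_top
  while (hi < nrow(d) && d$lod[hi + 1] >= cut) hi <- hi + 1
  start_bp <- if (lo > 1) d$position_bp[lo - 1] else d$position_bp[1]
  end_bp <- if (hi < nrow(d)) d$position_bp[hi + 1] else d$position_bp[nrow(d)]
  data.frame(week = week, chromosome = chromosome,
             top_marker = d$marker_id[i_top], top_lod = d$lod[i_top],
             start_bp = start_bp, end_bp = end_bp,
             significant = if (is.null(threshold)) NA
                           else d$lod[i_top] >= threshold)
}

#' Weekly intervals for every scanned week of a chromosome
#'
#' Convenience wrapper applying [lodDropInterval()] to each week present in
#' the scan.
#'
#' @inheritParams lodDropInterval
#' @return `data.frame` of weekly intervals (one row per week).
#' @export
weeklyIntervals <- function(scan, chromosome, drop = 1.5, threshold = NULL,
                            markers = NULL) {
  weeks <- sort(unique(scan$week))
  do.call(rbind, lapply(weeks, function(w)
    lodDropInterval(scan, w, chromosome, drop, threshold, markers)))
}

#' Aggregate weekly intervals into a final QTL region
#'
#' The final QTL interval takes the smallest start and the highest end across
#' the selected weeks.  By default only genome-wide significant weeks are
#' aggregated (a week with a flat LOD profile would otherwise inflate the
#' interval towards the whole chromosome); set `only_significant = FALSE` to
#' span all measured weeks.
#'
#' @param weekly `data.frame` from [weeklyIntervals()] (one chromosome).
#' @param only_significant aggregate significant weeks only (default `TRUE`;
#'   requires the `significant` flag to be set).
#' @return List of class `AggregateQtl`: `chromosome`, `final_start_bp`,
#'   `final_end_bp`, `top_marker`, `top_week`, `top_lod`,
#'   `significant_weeks`, and the `weekly` table used.
#' @export
aggregateIntervals <- function(weekly, only_significant = TRUE) {
  stopifnot(is.data.frame(weekly), nrow(weekly) >= 1)
  if (length(unique(weekly$chromosome)) != 1)
    .stopf("weekly intervals must come from a single chromosome")
  sel <- if (only_significant) {
    if (all(is.na(weekly$significant)))
      .stopf("only_significant=TRUE requires intervals built with a threshold")
    weekly[weekly$significant %in% TRUE, , drop = FALSE]
  } else weekly
  if (!nrow(sel)) .stopf("no week selected for aggregation")
  top <- sel[order(-sel$top_lod, sel$week), , drop = FALSE][1, ]
  structure(list(
    chromosome = weekly$chromosome[1],
    final_start_bp = min(sel$start_bp),
    final_end_bp = max(sel$end_bp),
    top_marker = top$top_marker,
    top_week = top$week,
    top_lod = top$top_lod,
    significant_weeks = weekly$week[weekly$significant %in% TRUE],
    weekly = weekly), class = "AggregateQtl")
}

#' @export
print.AggregateQtl <- function(x, ...) {
  cat(sprintf("QTL on chromosome %s: %s-%s bp\n", x$chromosome,
              format(x$final_start_bp, big.mark = ","),
              format(x$final_end_bp, big.mark = ",")))
  cat(sprintf("  top marker %s (week %d, LOD %.2f); significant weeks: %s\n",
              x$top_marker, x$top_week, x$top_lod,
              if (length(x$significant_weeks))
                paste(range(x$significant_weeks), collapse = "-") else "none"))
  invisible(x)
}

#' Runs of consecutive significant weeks
#'
#' Returns the maximal runs of consecutive weeks whose top LOD meets the
#' threshold — e.g. a QTL that is significant through the standard-diet
#' phase, loses significance across a diet switch and reappears afterwards
#' yields two runs.  A run breaks when a measured week falls below the
#' threshold or when the week sequence has a gap.
#'
#' @param weekly `data.frame` with columns `week` and `top_lod` (e.g. from
#'   [weeklyIntervals()]).
#' @param threshold genome-wide LOD threshold.
#' @return `data.frame` with columns `first_week`, `last_week` (zero rows if
#'   no week is significant).
#' @export
significanceSpan <- function(weekly, threshold) {
  stopifnot(is.data.frame(weekly), all(c("week", "top_lod") %in% names(weekly)))
  d <- weekly[order(weekly$week), , drop = FALSE]
  w <- d$week[!is.na(d$top_lod) & d$top_lod >= threshold]
  if (!length(w))
    return(data.frame(first_week = integer(), last_week = integer()))
  grp <- cumsum(c(1L, diff(w) != 1L))
  do.call(rbind, lapply(split(w, grp), function(ws)
    data.frame(first_week = min(ws), last_week = max(ws))))
}
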