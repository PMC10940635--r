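#' Diet-phase schedule
#'
#' The feeding protocol of the study population: standard chow from weaning
#' (week 3) until week 20, a high-fat/low-carbohydrate diet in weeks 21-22,
#' and a high-fat/high-carbohydrate diet in weeks 23-25.  Phases must be
#' non-overlapping and contiguous over the phenotyped range.
#'
#' @param phases `data.frame` with columns `week_start`, `week_end`,
#'   `phase` (one of `"standard"`, `"HF_LC"`, `"HF_HC"`).
#' @return The validated schedule `data.frame`.
#' @examples
#' dietSchedule()
#' @export
dietSchedule <- function(phases = data.frame(
                           week_start = c(3L, 21L, 23L),
                           week_end   = c(20L, 22L, 25L),
                           phase      = c("standard", "HF_LC", "HF_HC"))) {
  stopifnot(is.data.frame(phases),
            all(c("week_start", "week_end", "phase") %in% names(phases)))
  ok <- c("standard", "HF_LC", "HF_HC")
  if (!all(phases$phase %in% ok))
    .stopf("unknown diet phase label(s): %s",
           paste(setdiff(phases$phase, ok), collapse = ", "))
  phases <- phases[order(phases$week_start), , drop = FALSE]
  if (any(phases$week_end < phases$week_start))
    .stopf("phase with week_end < week_start")
  if (nrow(phases) > 1) {
    gaps <- phases$week_start[-1] - phases$week_end[-nrow(phases)]
    if (any(gaps != 1))
      .stopf("diet phases must be contiguous and non-overlapping")
  }
  rownames(phases) <- NULL
  phases
}

#' Look up the diet phase for each week
#'
#' @param weeks integer vector of ages in weeks.
#' @param schedule a schedule from [dietSchedule()].
#' @return Character vector of phase labels (`NA` outside the schedule).
#' @examples
#' dietPhase(c(3, 20, 21, 23, 25))
#' @export
dietPhase <- function(weeks, schedule = dietSchedule()) {
  out <- rep(NA_character_, length(weeks))
  for (i in seq_len(nrow(schedule))) {
    hit <- weeks >= schedule$week_start[i] & weeks <= schedule$week_end[i]
    out[hit] <- schedule$phase[i]
  }
  out
}
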