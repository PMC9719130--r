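#' Segment a patient's timepoints into therapy lines
#'
#' @param timepoints Data frame with at least `patient_id`, `date`
#'   (ISO-8601 or `Date`), `therapy_line`; marker and radiology columns are
#'   carried along. Duplicate (patient, date, line) rows raise an error.
#' @return Named list of date-sorted data frames, one per therapy line, in
#'   order of first sampling date.
#' @export
segment_therapy_lines <- function(timepoints) {
  tp <- as.data.frame(timepoints)
  tp$date <- as.Date(tp$date)
  if (anyNA(tp$date)) stop("unparseable sampling date", call. = FALSE)
  key <- paste(tp$patient_id, tp$date, tp$therapy_line)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, date, therapy line) row: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  lines <- split(tp, paste(tp$patient_id, tp$therapy_line, sep = ":"))
  lines <- lapply(lines, function(d) d[order(d$date), , drop = FALSE])
  starts <- vapply(lines, function(d) as.numeric(d$date[1]), numeric(1))
  lines[order(vapply(lines, function(d) d$patient_id[1], character(1)), starts)]
}

#' Paired comparison of marker values at therapy start versus progression
#'
#' For each qualifying therapy line — one with a radiologic progressive
#' disease (PD) timepoint and, when an `end_reason` column is present, an
#' end by therapy switch or death — the pair is (first timepoint of the
#' line, first radiologic-PD timepoint of the line). Differences
#' `delta = marker_PD - marker_start` are summarized by the two-sided
#' Wilcoxon signed-rank test (exact for small samples without ties).
#'
#' @param lines List of therapy-line data frames
#'   ([segment_therapy_lines()] output) with a `radiology` column
#'   (`"PD"`, `"SD"`, `"PR"`, `NA`).
#' @param marker Name of the marker column (default `"score_5mc"`).
#' @return List: `pairs` (data frame with start/PD values and `delta`),
#'   `n_pairs`, `n_increased`, `p_value`.
#' @export
paired_start_vs_pd <- function(lines, marker = "score_5mc") {
  rows <- lapply(lines, function(d) {
    if (!is.null(d$end_reason) &&
        !any(d$end_reason %in% c("switch", "death"))) return(NULL)
    pd <- which(!is.na(d$radiology) & d$radiology == "PD")
    if (!length(pd)) return(NULL)
    start_val <- d[[marker]][1]
    pd_val <- d[[marker]][pd[1]]
    if (is.na(start_val) || is.na(pd_val)) return(NULL)
    data.frame(patient_id = d$patient_id[1],
               therapy_line = d$therapy_line[1],
               start = start_val, pd = pd_val,
               delta = pd_val - start_val,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs)) {
    stop("no therapy line with both a start and a PD timepoint", call. = FALSE)
  }
  if (nrow(pairs) < 6L) {
    warning("fewer than 6 pairs; exact small-sample signed-rank p-value")
  }
  delta <- pairs$delta
  p <- if (all(delta == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(delta, exact = TRUE,
                                        alternative = "two.sided")$p.value)
  }
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_increased = sum(delta > 0), p_value = p)
}

#' Call molecular progression from the running therapy-line nadir
#'
#' Walking forward in time within one therapy line, the nadir is the
#' running minimum of the marker over strictly earlier timepoints; the call
#' is made at the first timepoint whose value reaches
#' `nadir * (1 + rise_frac)`. The rule is prospective: no information after
#' the call date is used. When the running nadir is 0, any later positive
#' value triggers a call (a rise from undetectable; the percent rise is
#' reported as `Inf`).
#'
#' @param line One therapy-line data frame (see [segment_therapy_lines()]).
#' @param marker Marker column name (default `"score_5mc"`).
#' @param rise_frac Fractional rise over the nadir that defines molecular
#'   progression (default 0.25).
#' @return List of class `progression_call`: `therapy_line`, `called`,
#'   `call_date`, `nadir`, `nadir_date`, `pct_rise`.
#' @export
call_molecular_progression <- function(line, marker = "score_5mc",
                                       rise_frac = 0.25) {
  d <- line[!is.na(line[[marker]]), , drop = FALSE]
  if (nrow(d) < 2L) {
    stop(">= 2 timepoints with the marker are required", call. = FALSE)
  }
  vals <- d[[marker]]
  dates <- as.Date(d$date)
  nadir <- vals[1]
  nadir_date <- dates[1]
  for (i in 2:length(vals)) {
    trigger <- if (nadir == 0) vals[i] > 0 else
      vals[i] >= nadir * (1 + rise_frac)
    if (trigger) {
      return(structure(list(therapy_line = d$therapy_line[1],
                            called = TRUE,
                            call_date = dates[i],
                            nadir = nadir, nadir_date = nadir_date,
                            pct_rise = if (nadir == 0) Inf else
                              100 * (vals[i] / nadir - 1)),
                       class = "progression_call"))
    }
    if (vals[i] < nadir) {
      nadir <- vals[i]
      nadir_date <- dates[i]
    }
  }
  structure(list(therapy_line = d$therapy_line[1], called = FALSE,
                 call_date = as.Date(NA), nadir = min(vals),
                 nadir_date = dates[which.min(vals)], pct_rise = NA_real_),
            class = "progression_call")
}

#' Lead time from a molecular progression call to radiologic progression
#'
#' @param call A `progression_call` (or a call date).
#' @param radiologic_pd_date Date of radiologic PD.
#' @return Non-negative calendar days, or `NA` (missed) when no call was
#'   made or the call came after radiologic PD.
#' @export
lead_time <- function(call, radiologic_pd_date) {
  call_date <- if (inherits(call, "progression_call")) call$call_date else
    as.Date(call)
  pd <- as.Date(radiologic_pd_date)
  if (is.na(call_date) || is.na(pd)) return(NA_real_)
  days <- as.numeric(pd - call_date)
  if (days < 0) NA_real_ else days
}

#' Cohort-level molecular progression summary
#'
#' Applies the nadir rule to every therapy line that reaches radiologic PD
#' and has at least two marker values before or at PD (so the molecular
#' call can only use information available up to the radiologic call), and
#' summarizes lead times.
#'
#' @param timepoints Cohort timepoint table (see
#'   [segment_therapy_lines()]).
#' @param marker Marker column (default `"score_5mc"`).
#' @param rise_frac Nadir-rise fraction (default 0.25).
#' @return List: `per_line` data frame (line, pd_date, call_date,
#'   lead_days, called_before_pd), `median_lead_days`,
#'   `fraction_called_before_pd`, `n_lines`.
#' @export
monitor_cohort <- function(timepoints, marker = "score_5mc",
                           rise_frac = 0.25) {
  lines <- segment_therapy_lines(timepoints)
  rows <- lapply(lines, function(d) {
    pd_idx <- which(!is.na(d$radiology) & d$radiology == "PD")
    if (!length(pd_idx)) return(NULL)
    pd_date <- as.Date(d$date[pd_idx[1]])
    upto <- d[as.Date(d$date) <= pd_date, , drop = FALSE]
    if (sum(!is.na(upto[[marker]])) < 2L) return(NULL)
    call <- call_molecular_progression(upto, marker, rise_frac)
    ld <- lead_time(call, pd_date)
    data.frame(patient_id = d$patient_id[1],
               therapy_line = d$therapy_line[1],
               pd_date = pd_date,
               call_date = call$call_date,
               lead_days = ld,
               called_before_pd = !is.na(ld),
               stringsAsFactors = FALSE)
  })
  per_line <- do.call(rbind, rows)
  if (is.null(per_line)) {
    stop("no evaluable therapy line reaching radiologic PD", call. = FALSE)
  }
  rownames(per_line) <- NULL
  list(per_line = per_line,
       median_lead_days = stats::median(per_line$lead_days, na.rm = TRUE),
       fraction_called_before_pd = mean(per_line$called_before_pd),
       n_lines = nrow(per_line))
}
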