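#' Segment a stimulation log into analysis episodes
#'
#' Each stimulation onset defines one episode: a `baseline_s`-second baseline
#' window immediately before the onset and a `stim_s`-second stimulation
#' window from the onset. Windows are half-open `[start, end)`. An episode
#' whose baseline overlaps a previous stimulation window (interior overlap;
#' shared boundaries are fine) is excluded and flagged, as is an episode
#' whose baseline would start before the recording.
#'
#' @param events data.frame with columns `onset_s` (strictly increasing) and
#'   `set_id`.
#' @param stim_s,baseline_s window lengths, s.
#' @return data.frame with columns `set_id, bl_start, bl_end, stim_start,
#'   stim_end, excluded, reason`.
#' @export
segment_episodes <- function(events, stim_s = 30, baseline_s = 30) {
  stopifnot(all(c("onset_s", "set_id") %in% names(events)))
  onsets <- events$onset_s
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("stimulation onsets must be strictly increasing")
  }
  ep <- data.frame(
    set_id = events$set_id,
    bl_start = onsets - baseline_s, bl_end = onsets,
    stim_start = onsets, stim_end = onsets + stim_s,
    excluded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(ep))) {
    if (ep$bl_start[k] < 0) {
      ep$excluded[k] <- TRUE
      ep$reason[k] <- "baseline precedes recording start"
      next
    }
    if (k > 1) {
      prev <- seq_len(k - 1)
      overlap <- ep$bl_start[k] < ep$stim_end[prev] &
        ep$stim_start[prev] < ep$bl_end[k]
      if (any(overlap)) {
        ep$excluded[k] <- TRUE
        ep$reason[k] <- "baseline overlaps earlier stimulation"
      }
    }
  }
  if (any(ep$excluded)) {
    warning(sum(ep$excluded), " episode(s) excluded: ",
            paste(unique(ep$reason[ep$excluded]), collapse = "; "))
  }
  ep
}

#' Relative heart rate reduction
#'
#' `delta_hr = (hr_bl - hr_stim) / hr_bl`; positive values mean slowing.
#'
#' @param hr_bl mean baseline heart rate, bpm (> 0).
#' @param hr_stim mean heart rate during stimulation, bpm.
#' @return relative reduction (fraction), vectorized.
#' @export
compute_delta_hr <- function(hr_bl, hr_stim) {
  if (any(hr_bl <= 0)) stop("hr_bl must be > 0")
  (hr_bl - hr_stim) / hr_bl
}

#' Stimulation charge of a burst
#'
#' `Q = I * PW * NP`, with intensity in mA and pulse width in us, so the
#' product is in nC; the result is reported in uC (factor 1e-3).
#'
#' @param params a design `data.frame` or list with `intensity_mA`,
#'   `pulse_width_us`, `num_pulses`.
#' @return charge in uC, vectorized.
#' @export
compute_charge <- function(params) {
  need <- c("intensity_mA", "pulse_width_us", "num_pulses")
  if (!all(need %in% names(params))) {
    stop("params must carry ", paste(need, collapse = ", "))
  }
  params$intensity_mA * params$pulse_width_us * params$num_pulses * 1e-3
}

#' Physiological threshold charge
#'
#' The minimal tested charge whose episode lowered the heart rate by at least
#' `min_drop_bpm` (absolute drop in bpm, not relative). Only tested
#' combinations are considered; no interpolation.
#'
#' @param records response records: data.frame with `hr_bl_bpm`,
#'   `hr_stim_bpm`, `charge_uC`.
#' @param min_drop_bpm drop criterion, bpm (default 5).
#' @return threshold charge, uC. Errors with condition class
#'   `vns_threshold_undefined` when no record meets the criterion.
#' @export
threshold_charge <- function(records, min_drop_bpm = 5) {
  stopifnot(nrow(records) >= 1)
  drop <- records$hr_bl_bpm - records$hr_stim_bpm
  hit <- drop >= min_drop_bpm
  if (!any(hit)) {
    stop(errorCondition(
      sprintf("threshold undefined: no tested charge dropped HR by >= %g bpm",
              min_drop_bpm),
      class = c("vns_threshold_undefined", "error")
    ))
  }
  min(records$charge_uC[hit])
}

#' Per-subject response summary
#'
#' Computes the subject-level markers: maximum relative heart rate reduction
#' `dhr_max`, the charge of the arg-max record `q_at_dhr_max` (ties resolved
#' to the smallest charge), the threshold charge `q_thr` and the normalized
#' charge `q_norm_at_dhr_max = q_at_dhr_max / q_thr`.
#'
#' @param subject_id,state identifiers copied into the summary.
#' @param records response records for this subject (data.frame with
#'   `delta_hr`, `charge_uC`, `hr_bl_bpm`, `hr_stim_bpm`).
#' @param q_thr optionally a precomputed threshold charge; default computes
#'   [threshold_charge()] on `records` (and propagates its undefined error).
#' @param min_drop_bpm drop criterion passed to [threshold_charge()].
#' @return one-row data.frame of class `subject_summary`.
#' @export
summarize_subject <- function(subject_id, state, records, q_thr = NULL,
                              min_drop_bpm = 5) {
  stopifnot(nrow(records) >= 1)
  if (is.null(q_thr)) q_thr <- threshold_charge(records, min_drop_bpm)
  dhr_max <- max(records$delta_hr)
  at_max <- records$charge_uC[records$delta_hr == dhr_max]
  q_at <- min(at_max)
  out <- data.frame(
    subject_id = subject_id, state = state,
    hr_bl_bpm = mean(records$hr_bl_bpm),
    hr_stim_bpm = mean(records$hr_stim_bpm),
    q_thr = q_thr, dhr_max = dhr_max, q_at_dhr_max = q_at,
    q_norm_at_dhr_max = q_at / q_thr,
    n_records = nrow(records),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_summary", "data.frame")
  out
}

#' Response records from a recording and a peak series
#'
#' Runs the marker extraction for one subject: segments the stimulation log,
#' measures windowed mean heart rates on the supplied peak series, and
#' assembles the canonical response-record table.
#'
#' @param peaks an `r_peak_series` (detected or truth).
#' @param events stimulation log (`onset_s`, `set_id`).
#' @param design the `vns_design` the events refer to.
#' @param subject_id,condition identifiers for the output rows.
#' @param stim_s,baseline_s episode window lengths, s.
#' @return response-record data.frame with the canonical database columns
#'   (see [simulate_response_table()] for the schema); excluded episodes are
#'   omitted.
#' @export
compute_responses <- function(peaks, events, design, subject_id = NA,
                              condition = NA, stim_s = 30, baseline_s = 30) {
  ep <- segment_episodes(events, stim_s = stim_s, baseline_s = baseline_s)
  ep <- ep[!ep$excluded, , drop = FALSE]
  if (!nrow(ep)) return(empty_response_table())
  d <- as.data.frame(design)
  rows <- lapply(seq_len(nrow(ep)), function(k) {
    prm <- d[d$set_id == ep$set_id[k], , drop = FALSE]
    if (nrow(prm) != 1) {
      stop("set_id ", ep$set_id[k], " not found (or duplicated) in design")
    }
    hr_bl <- mean_hr(peaks, ep$bl_start[k], ep$bl_end[k])
    hr_st <- mean_hr(peaks, ep$stim_start[k], ep$stim_end[k])
    data.frame(
      subject_id = subject_id, condition = condition,
      set_id = prm$set_id,
      intensity_mA = prm$intensity_mA, pulse_width_us = prm$pulse_width_us,
      num_pulses = prm$num_pulses, frequency_Hz = prm$frequency_Hz,
      delay_ms = prm$delay_ms,
      hr_bl_bpm = hr_bl, hr_stim_bpm = hr_st,
      delta_hr = compute_delta_hr(hr_bl, hr_st),
      charge_uC = compute_charge(prm),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

empty_response_table <- function() {
  data.frame(
    subject_id = character(0), condition = character(0),
    set_id = integer(0), intensity_mA = numeric(0),
    pulse_width_us = numeric(0), num_pulses = numeric(0),
    frequency_Hz = numeric(0), delay_ms = numeric(0),
    hr_bl_bpm = numeric(0), hr_stim_bpm = numeric(0),
    delta_hr = numeric(0), charge_uC = numeric(0),
    stringsAsFactors = FALSE
  )
}
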