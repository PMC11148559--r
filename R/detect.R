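#' Detector and trigger configuration
#'
#' Constants follow the Pan-Tompkins lineage; all are configurable.
#'
#' @param bandpass_hz QRS band-pass edges, Hz.
#' @param filter_order Butterworth order.
#' @param integrate_ms moving-window integration length, ms.
#' @param refractory_ms minimum spacing between detections/triggers, ms.
#' @param match_window_ms half-width of the window in which the trace maximum
#'   is located around an integrated-signal detection, ms.
#' @param theta online-trigger threshold as a fraction of the decayed running
#'   maximum of the filtered signal.
#' @param decay_s online-trigger running-maximum decay time constant, s.
#' @param min_threshold_mV online-trigger absolute threshold floor, mV; keeps
#'   the causal trigger from firing on baseline noise before the first beat.
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(bandpass_hz = c(5, 15), filter_order = 3,
                            integrate_ms = 150, refractory_ms = 200,
                            match_window_ms = 50, theta = 0.6,
                            decay_s = 2, min_threshold_mV = 0.1) {
  stopifnot(length(bandpass_hz) == 2, bandpass_hz[1] > 0,
            bandpass_hz[2] > bandpass_hz[1],
            integrate_ms > 0, refractory_ms > 0, theta > 0, theta < 1,
            decay_s > 0)
  structure(list(bandpass_hz = bandpass_hz, filter_order = filter_order,
                 integrate_ms = integrate_ms, refractory_ms = refractory_ms,
                 match_window_ms = match_window_ms, theta = theta,
                 decay_s = decay_s, min_threshold_mV = min_threshold_mV),
            class = "detector_config")
}

#' R-peak series
#'
#' @param times strictly increasing peak times, s.
#' @param fs sampling rate of the source recording, Hz.
#' @param source `"truth"`, `"detected"` or `"trigger"`.
#' @param refractory_s minimum admissible spacing, s.
#' @return object of class `r_peak_series` (numeric times with attributes).
#' @export
r_peak_series <- function(times, fs, source = c("detected", "truth",
                                                "trigger"),
                          refractory_s = 0.2) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) stop("R-peak times must be strictly increasing")
    if (any(d < 0.95 * refractory_s)) {
      stop("R-peak spacing below the ", refractory_s, " s refractory period")
    }
  }
  structure(times, fs = fs, source = source, class = "r_peak_series")
}

#' @export
print.r_peak_series <- function(x, ...) {
  cat(sprintf("r_peak_series (%s): %d peaks", attr(x, "source"), length(x)))
  if (length(x) > 1) {
    cat(sprintf(", mean HR %.1f bpm", 60 / mean(diff(unclass(x)))))
  }
  cat("\n")
  invisible(x)
}

#' Offline R-peak detection (energy-operator pipeline)
#'
#' Band-pass filter, differentiate, square, moving-window integrate, then
#' adaptive dual-threshold peak picking with a refractory period and
#' search-back, in the style of the classic QRS energy-operator detectors.
#' Detections are refined to the trace maximum within
#' `match_window_ms` of the integrated-signal peak.
#'
#' @param rec an `ecg_recording` (needs `fs >= 250` Hz and at least 5 s of
#'   signal).
#' @param config a [detector_config()].
#' @return an `r_peak_series` with `source = "detected"`; empty on a flat
#'   trace.
#' @export
detect_r_peaks <- function(rec, config = detector_config()) {
  fs <- rec$fs
  x <- rec$ecg_mV
  if (fs < 250) stop("sampling rate must be >= 250 Hz")
  if (length(x) < 5 * fs) stop("trace must be at least 5 s long")
  if (stats::sd(x) == 0) {
    return(r_peak_series(numeric(0), fs, "detected",
                         config$refractory_ms / 1000))
  }

  bp <- bandpass_filtfilt(x, fs, config)
  der <- stats::filter(bp, c(-1, -2, 0, 2, 1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(3L, round(config$integrate_ms / 1000 * fs))
  mwi <- centered_ma(sq, w)

  cand <- local_maxima(mwi)
  if (!length(cand)) {
    return(r_peak_series(numeric(0), fs, "detected",
                         config$refractory_ms / 1000))
  }
  # non-maximum suppression: one QRS can yield several integrated-signal
  # maxima (band-pass ringing side lobes); keep only maxima that are the
  # strongest within half a refractory span
  refr <- config$refractory_ms / 1000 * fs
  cand <- nonmax_suppress(cand, mwi[cand], refr / 2)

  # refine each surviving candidate to the trace maximum within the match
  # window, so the adaptive scan works on R-apex-aligned fiducials (the
  # integrated-signal maximum sits tens of ms off the R apex when beats are
  # close together)
  hw <- as.integer(round(config$match_window_ms / 1000 * fs))
  strength <- mwi[cand]
  apex <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i) - hw)
    hi <- min(length(x), as.integer(i) + hw)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  ord <- order(apex, -strength)
  apex <- apex[ord]
  strength <- strength[ord]
  keep <- !duplicated(apex)
  init <- seq_len(min(length(mwi), 2 * fs))
  det <- adaptive_pick(strength[keep], apex[keep], fs, config,
                       spk0 = 0.6 * max(mwi[init]),
                       npk0 = 0.5 * mean(mwi[init]))
  r_peak_series((det - 1) / fs, fs, "detected",
                config$refractory_ms / 1000)
}

# zero-phase band-pass with reflection padding to suppress edge transients
bandpass_filtfilt <- function(x, fs, config) {
  bf <- signal::butter(config$filter_order,
                       config$bandpass_hz / (fs / 2), type = "pass")
  pad <- min(length(x) - 1, 2 * fs)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] -
            x[(length(x) - 1):(length(x) - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + length(x))]
}

# centered moving average via cumulative sums (O(n))
centered_ma <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# keep only candidates that are the strongest within +/- win samples
# (pos must be sorted; ties resolved to the earliest)
nonmax_suppress <- function(pos, strength, win) {
  n <- length(pos)
  keep <- logical(n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (pos[lo] < pos[i] - win) lo <- lo + 1L
    while (hi < n && pos[hi + 1L] <= pos[i] + win) hi <- hi + 1L
    s <- strength[lo:hi]
    keep[i] <- (i - lo + 1L) == which.max(s)
  }
  pos[keep]
}

# Pan-Tompkins-style adaptive dual-threshold scan over apex-aligned
# candidates (positions `pos`, integrated-signal strengths `strength`),
# with refractory period and RR-based search-back
adaptive_pick <- function(strength, pos, fs, config, spk0, npk0) {
  # 2% slack absorbs fiducial jitter when the true RR sits exactly at the
  # refractory period
  refr <- 0.98 * config$refractory_ms / 1000 * fs
  spk <- spk0
  npk <- npk0
  accepted <- integer(0)
  last <- -Inf
  rr_buf <- numeric(0)
  pending <- integer(0)  # indices of skipped candidates (for search-back)

  i <- 1L
  n <- length(pos)
  while (i <= n) {
    p <- pos[i]
    th1 <- npk + 0.25 * (spk - npk)
    # search-back: if a beat is overdue, take the strongest skipped
    # candidate above the lower threshold
    if (length(rr_buf) >= 2 && is.finite(last) &&
        (p - last) > 1.66 * stats::median(rr_buf)) {
      ok <- pending[pos[pending] - last >= refr &
                      strength[pending] > 0.5 * th1]
      if (length(ok)) {
        j <- ok[which.max(strength[ok])]
        accepted <- c(accepted, pos[j])
        rr_buf <- c(rr_buf, pos[j] - last)
        if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
        last <- pos[j]
        spk <- 0.25 * strength[j] + 0.75 * spk
        pending <- pending[pos[pending] > pos[j]]
      }
    }
    if (p - last < refr) {
      pending <- c(pending, i)
      i <- i + 1L
      next
    }
    if (strength[i] > th1) {
      accepted <- c(accepted, p)
      if (is.finite(last)) {
        rr_buf <- c(rr_buf, p - last)
        if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
      }
      last <- p
      spk <- 0.125 * strength[i] + 0.875 * spk
      pending <- integer(0)
    } else {
      npk <- 0.125 * strength[i] + 0.875 * npk
      pending <- c(pending, i)
    }
    i <- i + 1L
  }
  sort(accepted)
}

#' Online cardiac-synchronization trigger
#'
#' Emulates the real-time trigger: a single causal pass over the band-pass
#' filtered signal in which the threshold is `theta` times the running signal
#' maximum with exponential decay (time constant `decay_s`). A trigger fires
#' at the first sample crossing the threshold and is followed by a refractory
#' period. A trigger at time `t` depends only on samples at or before `t`.
#'
#' @inheritParams detect_r_peaks
#' @return an `r_peak_series` with `source = "trigger"`.
#' @export
online_trigger <- function(rec, config = detector_config()) {
  fs <- rec$fs
  x <- rec$ecg_mV
  if (fs < 250) stop("sampling rate must be >= 250 Hz")
  if (stats::sd(x) == 0) {
    return(r_peak_series(numeric(0), fs, "trigger",
                         config$refractory_ms / 1000))
  }
  bf <- signal::butter(config$filter_order,
                       config$bandpass_hz / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, x))

  decay <- exp(-1 / (fs * config$decay_s))
  refr <- config$refractory_ms / 1000 * fs
  floor_th <- config$min_threshold_mV
  m <- 0
  last <- -Inf
  trig <- integer(0)
  for (i in seq_along(y)) {
    yi <- y[i]
    th <- max(config$theta * m, floor_th)
    if (yi > th && (i - last) >= refr) {
      trig <- c(trig, i)
      last <- i
    }
    if (yi > 0) m <- max(m * decay, yi) else m <- m * decay
  }
  r_peak_series((trig - 1) / fs, fs, "trigger", config$refractory_ms / 1000)
}

#' Windowed mean heart rate
#'
#' Mean heart rate over `[t0, t1)` defined as `60 / mean(RR)` over the RR
#' intervals whose both endpoints lie in the window; intervals straddling a
#' boundary are excluded. This definition is unbiased for partial windows,
#' unlike beat counting.
#'
#' @param peaks an `r_peak_series` or numeric vector of peak times, s.
#' @param t0,t1 window bounds, s (half-open `[t0, t1)`).
#' @return mean heart rate, bpm.
#' @export
mean_hr <- function(peaks, t0, t1) {
  times <- as.numeric(peaks)
  sel <- times >= t0 & times < t1
  if (sum(sel) < 2) {
    stop(errorCondition(
      sprintf("mean_hr undefined: %d peak(s) in [%g, %g)", sum(sel), t0, t1),
      class = c("vns_hr_undefined", "error")
    ))
  }
  60 / mean(diff(times[sel]))
}
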