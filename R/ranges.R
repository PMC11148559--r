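#' Stimulation parameter ranges
#'
#' A parameter-range table describes, for each of the five burst parameters
#' (intensity in mA, pulse width in us, frequency in Hz, number of pulses,
#' onset delay in ms), the interval from which Latin hypercube designs are
#' drawn. `num_pulses` is an integer parameter; all others are continuous.
#'
#' @param condition innervation condition whose published ranges to return:
#'   `"intact"` (sheep, n = 75 combinations), `"vagotomy"` (rabbit, n = 75) or
#'   `"isolated"` (Langendorff rabbit heart, n = 100).
#' @return a `data.frame` with columns `name`, `lo`, `hi`, `kind` and an
#'   attribute `default_n` (the number of combinations used in that
#'   condition's experiments).
#' @examples
#' parameter_ranges("vagotomy")
#' @export
parameter_ranges <- function(condition = c("intact", "vagotomy", "isolated")) {
  condition <- match.arg(condition)
  tab <- switch(condition,
    intact = list(
      intensity   = c(0.2, 1),
      pulse_width = c(50, 200),
      frequency   = c(21.3, 42.7),
      num_pulses  = c(1, 4),
      delay       = c(16, 156.2),
      n = 75L
    ),
    vagotomy = list(
      intensity   = c(0.2, 2),
      pulse_width = c(50, 200),
      frequency   = c(10, 40),
      num_pulses  = c(1, 6),
      delay       = c(0, 298.8),
      n = 75L
    ),
    isolated = list(
      intensity   = c(6, 9.7),
      pulse_width = c(25, 1000),
      frequency   = c(25, 38.5),
      num_pulses  = c(5, 14),
      delay       = c(0, 382),
      n = 100L
    )
  )
  ranges <- make_ranges(
    intensity = tab$intensity, pulse_width = tab$pulse_width,
    frequency = tab$frequency, num_pulses = tab$num_pulses,
    delay = tab$delay
  )
  attr(ranges, "condition") <- condition
  attr(ranges, "default_n") <- tab$n
  ranges
}

#' Build a parameter-range table from explicit bounds
#'
#' @param intensity,pulse_width,frequency,delay length-2 numeric `c(lo, hi)`
#'   bounds for the continuous parameters (mA, us, Hz, ms).
#' @param num_pulses length-2 bounds for the integer pulse count.
#' @return a validated range `data.frame` (see [parameter_ranges()]).
#' @export
make_ranges <- function(intensity, pulse_width, frequency, num_pulses, delay) {
  ranges <- data.frame(
    name = c("intensity", "pulse_width", "frequency", "num_pulses", "delay"),
    lo = c(intensity[1], pulse_width[1], frequency[1], num_pulses[1], delay[1]),
    hi = c(intensity[2], pulse_width[2], frequency[2], num_pulses[2], delay[2]),
    kind = c("continuous", "continuous", "continuous", "integer", "continuous"),
    stringsAsFactors = FALSE
  )
  validate_ranges(ranges)
  ranges
}

param_names <- c("intensity", "pulse_width", "frequency", "num_pulses", "delay")

# design column names, fixed CSV schema
design_cols <- c("intensity_mA", "pulse_width_us", "num_pulses",
                 "frequency_Hz", "delay_ms")

# maps a parameter name to its design/CSV column
param_col <- c(
  intensity = "intensity_mA", pulse_width = "pulse_width_us",
  num_pulses = "num_pulses", frequency = "frequency_Hz", delay = "delay_ms"
)

#' @keywords internal
validate_ranges <- function(ranges) {
  if (!is.data.frame(ranges) ||
      !all(c("name", "lo", "hi", "kind") %in% names(ranges))) {
    stop("ranges must be a data.frame with columns name, lo, hi, kind")
  }
  if (anyDuplicated(ranges$name)) {
    stop("duplicate parameter names in ranges: ",
         paste(ranges$name[duplicated(ranges$name)], collapse = ", "))
  }
  missing <- setdiff(param_names, ranges$name)
  extra <- setdiff(ranges$name, param_names)
  if (length(missing) || length(extra)) {
    stop("ranges must cover exactly the five parameters {",
         paste(param_names, collapse = ", "), "}; missing: [",
         paste(missing, collapse = ", "), "], unknown: [",
         paste(extra, collapse = ", "), "]")
  }
  if (any(ranges$lo >= ranges$hi)) {
    bad <- ranges$name[ranges$lo >= ranges$hi]
    stop("lo must be < hi for every parameter (violated: ",
         paste(bad, collapse = ", "), ")")
  }
  np <- ranges[ranges$name == "num_pulses", ]
  if (np$kind != "integer" || np$lo < 1) {
    stop("num_pulses must have kind 'integer' and lo >= 1")
  }
  cont <- ranges[ranges$name != "num_pulses", ]
  if (any(cont$kind != "continuous") || any(cont$lo < 0)) {
    stop("all parameters except num_pulses must be continuous with lo >= 0")
  }
  invisible(ranges)
}

#' Check that bursts fit within a cardiac-cycle budget
#'
#' The burst occupies `delay + (num_pulses - 1) / frequency` seconds after the
#' trigger; cardiac-synchronized stimulation assumes this stays inside one
#' cardiac cycle. Combinations exceeding the budget are reported with a
#' warning (not an error): published delay ranges run close to the cycle
#' length, so near-cycle bursts were evidently tolerated in practice.
#'
#' @param design a design `data.frame` (see [lhs_sample()]).
#' @param cycle_ms cycle budget in ms (e.g. `60000 / hr` for a given heart
#'   rate).
#' @param warn emit a warning listing offending `set_id`s (default `TRUE`).
#' @return logical vector, `TRUE` where the burst fits the budget.
#' @export
validate_burst_fit <- function(design, cycle_ms, warn = TRUE) {
  burst_ms <- design$delay_ms +
    (design$num_pulses - 1) / design$frequency_Hz * 1000
  ok <- burst_ms <= cycle_ms
  if (warn && any(!ok)) {
    warning(sum(!ok), " parameter set(s) exceed the ", cycle_ms,
            " ms cycle budget (set_id: ",
            paste(design$set_id[!ok], collapse = ", "), ")")
  }
  invisible(ok)
}
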