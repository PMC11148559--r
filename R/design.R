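#' Latin hypercube design of stimulation parameters
#'
#' Draws `n` burst parameter combinations by Latin hypercube sampling (LHS):
#' each parameter's `[lo, hi]` interval is split into `n` equal-width strata
#' and every stratum is used exactly once, with independent random pairing
#' across parameters. The integer parameter (`num_pulses`) is stratified on
#' the continuous scale, then rounded half-up and clamped to `[lo, hi]`.
#'
#' @param ranges a parameter-range table, e.g. from [parameter_ranges()].
#' @param n number of parameter sets (>= 1).
#' @param seed integer seed; identical `(ranges, n, seed, placement)` give an
#'   identical design.
#' @param placement `"uniform"` places each sample uniformly at random within
#'   its stratum (standard LHS practice); `"midpoint"` uses stratum centres,
#'   which is convenient for exact-reproducibility checks.
#' @return a `data.frame` of class `vns_design` with columns
#'   `set_id, intensity_mA, pulse_width_us, num_pulses, frequency_Hz,
#'   delay_ms`, plus attributes `seed`, `placement` and `ranges`.
#' @examples
#' d <- lhs_sample(parameter_ranges("vagotomy"), n = 10, seed = 1)
#' range(d$intensity_mA)
#' @export
lhs_sample <- function(ranges, n, seed,
                       placement = c("uniform", "midpoint")) {
  placement <- match.arg(placement)
  validate_ranges(ranges)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1")
  }
  n <- as.integer(n)
  seed <- as.integer(seed)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  # unit hypercube with one sample per stratum per column
  u <- if (placement == "uniform") {
    lhs::randomLHS(n, length(param_names))
  } else {
    vapply(seq_along(param_names),
           function(j) (sample.int(n) - 0.5) / n,
           numeric(n))
  }
  if (is.null(dim(u))) u <- matrix(u, nrow = n)

  out <- data.frame(set_id = seq_len(n))
  for (j in seq_along(param_names)) {
    p <- param_names[j]
    r <- ranges[ranges$name == p, ]
    x <- r$lo + u[, j] * (r$hi - r$lo)
    if (r$kind == "integer") {
      x <- pmin(pmax(floor(x + 0.5), r$lo), r$hi)
    }
    out[[param_col[[p]]]] <- x
  }
  out <- out[, c("set_id", design_cols)]
  attr(out, "seed") <- seed
  attr(out, "placement") <- placement
  attr(out, "ranges") <- ranges
  class(out) <- c("vns_design", "data.frame")
  out
}

#' Stratum index of design values
#'
#' Maps sampled values back to their LHS stratum `0..n-1`; used to check the
#' one-sample-per-stratum property.
#'
#' @param x numeric values in `[lo, hi]`.
#' @param lo,hi range bounds.
#' @param n number of strata.
#' @return integer vector of stratum indices.
#' @export
stratum_index <- function(x, lo, hi, n) {
  idx <- floor((x - lo) / (hi - lo) * n)
  as.integer(pmin(pmax(idx, 0), n - 1))
}

#' Write / read a design CSV
#'
#' The on-disk schema is
#' `set_id,intensity_mA,pulse_width_us,num_pulses,frequency_Hz,delay_ms`,
#' full precision.
#'
#' @param design a `vns_design`.
#' @param path file path.
#' @return `read_design()` returns a `vns_design`-classed `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(format_full(as.data.frame(design)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", design_cols)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- d[, need]
  d$num_pulses <- as.numeric(d$num_pulses)
  class(d) <- c("vns_design", "data.frame")
  d
}

# full-precision text rendering so CSV round-trips losslessly
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
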