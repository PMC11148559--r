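#' Pipeline configuration
#'
#' Bundles everything one reproducible run needs: the innervation conditions,
#' design sizes, protocol durations, detector settings and seeds. All
#' randomness in a run derives from `seed` (per-subject streams are small
#' deterministic offsets of it). The configuration round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param conditions innervation conditions to simulate.
#' @param n_sets named integer vector of design sizes per condition; defaults
#'   to each condition's published size (75/75/100).
#' @param seed master integer seed.
#' @param protocol list with `stim_s`, `pause_s`.
#' @param fs sampling rate, Hz.
#' @param trace_noise_sd_mV additive ECG noise, mV.
#' @param detector a [detector_config()].
#' @param hr_source `"detected"` runs the R-peak detector on the synthetic
#'   trace (the full pipeline); `"truth"` uses the generator's ground-truth
#'   beats (detector-free reference path).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = c("intact", "vagotomy", "isolated"),
                            n_sets = NULL, seed = 1,
                            protocol = list(stim_s = 30, pause_s = 30),
                            fs = 1000, trace_noise_sd_mV = 0.02,
                            detector = detector_config(),
                            hr_source = c("detected", "truth")) {
  hr_source <- match.arg(hr_source)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(n_sets)) {
    n_sets <- vapply(conditions,
                     function(cn) attr(parameter_ranges(cn), "default_n"),
                     integer(1))
  }
  n_sets <- n_sets[conditions]
  if (any(!is.finite(n_sets)) || any(n_sets < 1)) {
    stop("n_sets must be >= 1 for every condition")
  }
  structure(
    list(conditions = conditions, n_sets = n_sets, seed = as.integer(seed),
         protocol = protocol, fs = fs,
         trace_noise_sd_mV = trace_noise_sd_mV,
         detector = detector, hr_source = hr_source),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$detector <- unclass(obj$detector)
  obj$n_sets <- as.list(obj$n_sets)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pipeline_config(
    conditions = obj$conditions,
    n_sets = stats::setNames(as.integer(unlist(obj$n_sets)),
                             names(obj$n_sets)),
    seed = obj$seed, protocol = obj$protocol, fs = obj$fs,
    trace_noise_sd_mV = obj$trace_noise_sd_mV,
    detector = do.call(detector_config, obj$detector),
    hr_source = obj$hr_source
  )
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' design -> simulate -> detect -> markers -> stats, for every default
#' subject of every requested condition. Deterministic given the
#' configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the design per subject, the
#'   pooled response database, subject summaries, the group table, the
#'   correlation table and a JSON manifest are written there as CSV/JSON.
#' @param subjects optional named list (by condition) of [subject_model()]
#'   lists overriding [default_subject_models()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `vns_run` with `responses`, `subjects` (summary
#'   table), `group_table`, `correlations`, `designs`, `truth` and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, subjects = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  responses <- list()
  truths <- list()
  summaries <- list()
  designs <- list()

  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    models <- if (!is.null(subjects)) subjects[[cond]]
              else default_subject_models(cond)
    ranges <- parameter_ranges(cond)
    n <- config$n_sets[[cond]]
    for (si in seq_along(models)) {
      model <- models[[si]]
      sid <- model$subject_id
      seed_s <- config$seed + 1000L * ci + si
      say("[%s] subject %s: design (n=%d, seed=%d)", cond, sid, n, seed_s)
      design <- lhs_sample(ranges, n = n, seed = seed_s)
      designs[[sid]] <- design

      say("[%s] subject %s: simulate", cond, sid)
      ex <- simulate_experiment(model, design, protocol = config$protocol,
                                seed = seed_s + 1L, fs = config$fs,
                                trace_noise_sd_mV = config$trace_noise_sd_mV)
      peaks <- if (config$hr_source == "detected") {
        say("[%s] subject %s: detect R-peaks", cond, sid)
        detect_r_peaks(ex$recording, config$detector)
      } else {
        r_peak_series(ex$recording$truth$r_peaks, config$fs, "truth")
      }
      resp <- compute_responses(
        peaks, ex$recording$stim_events, design,
        subject_id = sid, condition = cond,
        stim_s = config$protocol$stim_s,
        baseline_s = config$protocol$pause_s
      )
      responses[[sid]] <- resp
      tr <- ex$truth
      tr$subject_id <- sid
      tr$condition <- cond
      truths[[sid]] <- tr
      summaries[[sid]] <- tryCatch(
        summarize_subject(sid, cond, resp),
        vns_threshold_undefined = function(e) {
          say("[%s] subject %s: threshold undefined, excluded from charge-normalized summaries",
              cond, sid)
          NULL
        }
      )
    }
  }

  responses <- do.call(rbind, c(responses, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truths, list(make.row.names = FALSE)))
  subj_tab <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  say("stats: group summary + correlation table")
  gt <- group_summary(subj_tab, responses)
  ct <- correlation_table(responses)

  run <- structure(
    list(responses = responses, subjects = subj_tab, group_table = gt,
         correlations = ct, designs = designs, truth = truth,
         config = config),
    class = "vns_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir, quiet = quiet)
  run
}

#' @export
print.vns_run <- function(x, ...) {
  cat(sprintf("vns_run: %d responses, %d subjects, conditions: %s\n",
              nrow(x$responses), nrow(x$subjects),
              paste(x$config$conditions, collapse = ", ")))
  invisible(x)
}

write_run <- function(run, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_response_db(run$responses, p("responses.csv"))
  utils::write.csv(format_full(as.data.frame(run$subjects)),
                   p("subjects.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(run$group_table, p("group_table.csv"), row.names = FALSE)
  utils::write.csv(run$correlations, p("correlations.csv"),
                   row.names = FALSE)
  for (sid in names(run$designs)) {
    write_design(run$designs[[sid]], p(sprintf("design_%s.csv", sid)))
  }
  manifest <- list(
    package = "vnschrono",
    version = as.character(utils::packageVersion("vnschrono")),
    seed = run$config$seed,
    conditions = run$config$conditions,
    n_sets = as.list(run$config$n_sets),
    hr_source = run$config$hr_source,
    files = list.files(out_dir),
    md5 = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE)))
  )
  names(manifest$md5) <- basename(names(manifest$md5))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (!quiet) message("wrote run to ", out_dir)
  invisible(out_dir)
}

#' Write / read the response database CSV
#'
#' Canonical schema:
#' `subject_id,condition,set_id,intensity_mA,pulse_width_us,num_pulses,
#' frequency_Hz,delay_ms,hr_bl_bpm,hr_stim_bpm,delta_hr,charge_uC`.
#' `read_response_db()` validates rows, recomputes a missing `charge_uC`
#' column from intensity, pulse width and pulse count (with a notice), and
#' rejects rows with non-positive baseline heart rate or non-numeric fields,
#' reporting their line numbers. Extra columns are preserved; a
#' `column_map` (named character vector `canonical = actual`) adapts foreign
#' headers.
#'
#' @param responses response-record data.frame.
#' @param path CSV path.
#' @param column_map optional header adapter.
#' @return `read_response_db()` returns the validated data.frame.
#' @export
write_response_db <- function(responses, path) {
  utils::write.csv(format_full(as.data.frame(responses)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_db
#' @export
read_response_db <- function(path, column_map = NULL) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      actual <- column_map[[canon]]
      if (!actual %in% names(db)) {
        stop("column_map refers to absent column '", actual, "'")
      }
      names(db)[names(db) == actual] <- canon
    }
  }
  required <- c("subject_id", "condition", "intensity_mA", "pulse_width_us",
                "num_pulses", "frequency_Hz", "delay_ms",
                "hr_bl_bpm", "hr_stim_bpm")
  miss <- setdiff(required, names(db))
  if (length(miss)) {
    stop("response database missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  num_cols <- c("intensity_mA", "pulse_width_us", "num_pulses",
                "frequency_Hz", "delay_ms", "hr_bl_bpm", "hr_stim_bpm")
  bad <- rep(FALSE, nrow(db))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(db[[cc]]))
    nb <- !is.finite(v)
    if (any(nb)) {
      message("non-numeric '", cc, "' in data line(s) ",
              paste(which(nb), collapse = ", "), "; row(s) rejected")
      bad <- bad | nb
    }
    db[[cc]] <- v
  }
  zb <- !bad & db$hr_bl_bpm <= 0
  if (any(zb)) {
    message("non-positive hr_bl_bpm in data line(s) ",
            paste(which(zb), collapse = ", "), "; row(s) rejected")
    bad <- bad | zb
  }
  db <- db[!bad, , drop = FALSE]
  if (!"charge_uC" %in% names(db)) {
    message("charge_uC absent; recomputed as intensity * pulse width * pulses")
    db$charge_uC <- compute_charge(db)
  }
  if (!"delta_hr" %in% names(db)) {
    db$delta_hr <- compute_delta_hr(db$hr_bl_bpm, db$hr_stim_bpm)
  }
  if (!"set_id" %in% names(db)) {
    db$set_id <- stats::ave(seq_len(nrow(db)), db$subject_id,
                            FUN = seq_along)
  }
  db
}

#' Subject summaries from a response database
#'
#' Groups a response database by subject and computes [summarize_subject()]
#' for each; subjects without a defined threshold charge are retained with
#' `NA` charge markers (they still contribute to heart-rate statistics).
#'
#' @param db validated response database (see [read_response_db()]).
#' @param min_drop_bpm threshold-charge criterion, bpm.
#' @return data.frame of subject summaries.
#' @export
summarize_response_db <- function(db, min_drop_bpm = 5) {
  out <- lapply(split(db, db$subject_id), function(rec) {
    s <- tryCatch(
      summarize_subject(rec$subject_id[1], rec$condition[1], rec,
                        min_drop_bpm = min_drop_bpm),
      vns_threshold_undefined = function(e) {
        message("subject ", rec$subject_id[1],
                ": threshold undefined; charge markers set to NA")
        s <- summarize_subject(rec$subject_id[1], rec$condition[1], rec,
                               q_thr = NA_real_)
        s
      }
    )
    s
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}
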