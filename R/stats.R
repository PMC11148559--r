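#' Descriptor with Shapiro-Wilk normality gating
#'
#' Computes the group descriptor used in the reporting layer: Shapiro-Wilk
#' normality at level `alpha` decides the dispersion measure - standard
#' deviation when normality is not rejected, interquartile range (Q3 - Q1,
#' linear-interpolation quantiles) otherwise. The centre is the mean in both
#' cases ("mean +/- IQR" for non-normal data is deliberate and unusual; it
#' mirrors the reporting convention this package reproduces).
#'
#' @param values numeric vector, at least 3 non-identical values.
#' @param alpha normality test level (default 0.05).
#' @return list with `center`, `dispersion`, `dispersion_kind` (`"sd"` or
#'   `"iqr"`) and `shapiro_p`.
#' @export
describe_variable <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(unique(values)) == 1) {
    stop("describe_variable needs >= 3 non-identical values")
  }
  sw <- stats::shapiro.test(values)
  normal <- sw$p.value >= alpha
  list(
    center = mean(values),
    dispersion = if (normal) stats::sd(values)
                 else unname(diff(stats::quantile(values, c(0.25, 0.75)))),
    dispersion_kind = if (normal) "sd" else "iqr",
    shapiro_p = sw$p.value
  )
}

#' Kruskal-Wallis comparison across innervation groups
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `H` (tie-corrected statistic), `df` and `p`.
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 values")
  }
  if (length(unique(unlist(groups))) == 1) {
    # fully tied data: the tie-corrected statistic degenerates to 0/0;
    # by convention there is no evidence against the null
    return(list(H = 0, df = length(groups) - 1, p = 1))
  }
  kw <- stats::kruskal.test(groups)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value)
}

#' Wilcoxon signed-rank test for paired heart rates
#'
#' Two-sided signed-rank test on paired differences (typically baseline vs
#' stimulated heart rate). Zero differences are dropped. The exact null
#' distribution is used up to `exact_max` informative pairs; beyond that the
#' normal approximation with continuity correction.
#'
#' @param x,y paired numeric vectors of equal length >= 5.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `W` (signed-rank statistic), `n` (informative pairs)
#'   and `p`.
#' @export
compare_paired <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  exact <- length(d) <= exact_max && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(W = unname(wt$statistic), n = length(d), p = wt$p.value)
}

#' Spearman correlation of stimulation predictors with the response
#'
#' For each innervation condition, rank-correlates each of the five burst
#' parameters plus the derived charge against the relative heart rate
#' reduction. Records are pooled across subjects within a condition. Ties get
#' average ranks; p-values use the t approximation, or a seeded permutation
#' test for very small samples.
#'
#' @param responses response-record data.frame (canonical columns; see
#'   [compute_responses()]). A missing `condition` column is treated as one
#'   condition `"all"`.
#' @param perm_min below this record count the p-value is computed by
#'   permutation instead of the t approximation.
#' @param perm_n number of permutations.
#' @param seed seed for the permutation test.
#' @return data.frame (`condition, predictor, r, p, n`), class
#'   `correlation_table`; a constant predictor yields `NA` r and p.
#' @export
correlation_table <- function(responses, perm_min = 10, perm_n = 10000,
                              seed = 1) {
  predictors <- c(intensity = "intensity_mA", pulse_width = "pulse_width_us",
                  num_pulses = "num_pulses", frequency = "frequency_Hz",
                  delay = "delay_ms", charge = "charge_uC")
  if (!"condition" %in% names(responses)) responses$condition <- "all"
  out <- list()
  for (cond in unique(responses$condition)) {
    rec <- responses[responses$condition == cond, , drop = FALSE]
    if (nrow(rec) < 5) {
      stop("need >= 5 records per condition (", cond, " has ", nrow(rec), ")")
    }
    for (pn in names(predictors)) {
      x <- rec[[predictors[[pn]]]]
      y <- rec$delta_hr
      if (length(unique(x)) == 1) {
        row <- data.frame(condition = cond, predictor = pn,
                          r = NA_real_, p = NA_real_, n = nrow(rec))
      } else {
        r <- stats::cor(x, y, method = "spearman")
        p <- if (nrow(rec) < perm_min) {
          spearman_perm_p(x, y, r, perm_n, seed)
        } else {
          suppressWarnings(
            stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
          )
        }
        row <- data.frame(condition = cond, predictor = pn,
                          r = r, p = p, n = nrow(rec))
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("correlation_table", "data.frame")
  res
}

spearman_perm_p <- function(x, y, r_obs, perm_n, seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  r_perm <- replicate(perm_n,
                      stats::cor(x, sample(y), method = "spearman"))
  (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (perm_n + 1)
}

#' Group summary table across innervation conditions
#'
#' Builds the per-variable group report: Shapiro-gated descriptors per
#' condition, Kruskal-Wallis comparison across conditions for the
#' subject-level markers (`hr_bl_bpm`, `hr_stim_bpm`, `dhr_max`, `q_thr`,
#' `q_at_dhr_max`, `q_norm_at_dhr_max`), and the within-condition Wilcoxon
#' signed-rank test of baseline vs stimulated heart rate on pooled episode
#' pairs.
#'
#' Descriptors and Kruskal-Wallis run on subject-level values (one value per
#' subject); the signed-rank test runs on per-episode pairs pooled within
#' each condition, where it has the power such reports quote.
#'
#' @param subjects data.frame of subject summaries (rows from
#'   [summarize_subject()]).
#' @param responses pooled response records (for the paired test); optional.
#' @param alpha Shapiro-Wilk level.
#' @return data.frame (`variable, condition, center, dispersion,
#'   dispersion_kind, shapiro_p, test, stat, p, n`), class `group_table`.
#' @export
group_summary <- function(subjects, responses = NULL, alpha = 0.05) {
  vars <- c("hr_bl_bpm", "hr_stim_bpm", "dhr_max", "q_thr",
            "q_at_dhr_max", "q_norm_at_dhr_max")
  conds <- unique(subjects$state)
  rows <- list()
  for (v in vars) {
    if (!v %in% names(subjects)) next
    by_cond <- split(subjects[[v]], subjects$state)
    by_cond <- lapply(by_cond, function(z) z[is.finite(z)])
    kw <- if (length(by_cond) >= 2 &&
              all(vapply(by_cond, length, integer(1)) >= 2)) {
      compare_groups(by_cond)
    } else {
      list(H = NA_real_, p = NA_real_)
    }
    for (cond in conds) {
      vals <- by_cond[[cond]]
      desc <- tryCatch(describe_variable(vals, alpha),
                       error = function(e) list(center = mean(vals),
                                                dispersion = NA_real_,
                                                dispersion_kind = NA_character_,
                                                shapiro_p = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, condition = cond,
        center = desc$center, dispersion = desc$dispersion,
        dispersion_kind = desc$dispersion_kind, shapiro_p = desc$shapiro_p,
        test = "kruskal-wallis", stat = kw$H, p = kw$p,
        n = length(vals), stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(responses)) {
    for (cond in unique(responses$condition)) {
      rec <- responses[responses$condition == cond, , drop = FALSE]
      wt <- compare_paired(rec$hr_bl_bpm, rec$hr_stim_bpm)
      rows[[length(rows) + 1]] <- data.frame(
        variable = "hr_bl_vs_hr_stim", condition = cond,
        center = mean(rec$hr_bl_bpm - rec$hr_stim_bpm),
        dispersion = NA_real_, dispersion_kind = NA_character_,
        shapiro_p = NA_real_,
        test = "wilcoxon-signed-rank", stat = wt$W, p = wt$p,
        n = wt$n, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("group_table", "data.frame")
  res
}
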