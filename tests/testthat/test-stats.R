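test_that("normality gating picks sd for normal and iqr for heavy tails", {
  set.seed(101)
  heavy <- rt(500, df = 1)
  d1 <- describe_variable(heavy)
  expect_identical(d1$dispersion_kind, "iqr")
  expect_lt(d1$shapiro_p, 0.05)
  expect_equal(d1$dispersion,
               unname(diff(quantile(heavy, c(0.25, 0.75)))))

  picks <- vapply(1:100, function(s) {
    set.seed(s)
    describe_variable(rnorm(100))$dispersion_kind
  }, character(1))
  expect_gte(mean(picks == "sd"), 0.90)

  expect_error(describe_variable(c(1, 1, 1)), "non-identical")
  expect_error(describe_variable(c(1, 2)), "non-identical")
})

test_that("group comparison reduces to chi-square rank behaviour", {
  same <- list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5))
  kw <- compare_groups(same)
  expect_equal(kw$H, 0, tolerance = 1e-12)
  expect_equal(kw$p, 1)

  set.seed(7)
  apart <- list(a = rnorm(20, 0), b = rnorm(20, 3), c = rnorm(20, 6))
  expect_lt(compare_groups(apart)$p, 0.001)

  expect_error(compare_groups(list(a = 1:3)), "at least 2 groups")
  expect_error(compare_groups(list(a = 1:3, b = numeric(0))), "at least 2")
})

test_that("paired signed-rank test detects a constant drop and rejects ties", {
  set.seed(8)
  bl <- rnorm(20, 180, 5)
  expect_lt(compare_paired(bl, bl - 10)$p, 0.001)
  expect_error(compare_paired(bl, bl), "zero")
  expect_error(compare_paired(1:4, 2:5), "at least 5")
})

test_that("rank-based tests hold their nominal size under the null", {
  # reduced-rep calibration; the acceptance suite runs the full version
  set.seed(9)
  rej_kw <- mean(replicate(300, {
    compare_groups(list(rnorm(10), rnorm(10), rnorm(10)))$p < 0.05
  }))
  expect_gt(rej_kw, 0.02)
  expect_lt(rej_kw, 0.09)
  rej_w <- mean(replicate(300, {
    x <- rnorm(20); y <- x + rnorm(20)
    compare_paired(x, y)$p < 0.05
  }))
  expect_gt(rej_w, 0.02)
  expect_lt(rej_w, 0.09)
})

test_that("correlation table recovers exact monotone association", {
  n <- 30
  resp <- data.frame(
    condition = "all", intensity_mA = runif(n, 0.2, 2),
    pulse_width_us = runif(n, 50, 200), num_pulses = sample(1:6, n, TRUE),
    frequency_Hz = runif(n, 10, 40), delay_ms = runif(n, 0, 300),
    charge_uC = sort(runif(n, 0.01, 2.4))
  )
  resp$delta_hr <- rank(resp$charge_uC) / n * 0.1  # strictly increasing
  ct <- correlation_table(resp)
  expect_equal(ct$r[ct$predictor == "charge"], 1)
  # sign flip is exact
  resp2 <- resp
  resp2$delta_hr <- -resp2$delta_hr
  ct2 <- correlation_table(resp2)
  expect_equal(ct2$r[ct2$predictor == "charge"], -1)
  expect_equal(ct2$r, -ct$r)
})

test_that("correlations are invariant to monotone predictor transforms", {
  set.seed(12)
  n <- 60
  resp <- data.frame(
    condition = "all", intensity_mA = runif(n, 0.2, 2),
    pulse_width_us = runif(n, 50, 200), num_pulses = sample(1:6, n, TRUE),
    frequency_Hz = runif(n, 10, 40), delay_ms = runif(n, 0, 300)
  )
  resp$charge_uC <- with(resp, intensity_mA * pulse_width_us * num_pulses) / 1e3
  resp$delta_hr <- plogis(resp$charge_uC + rnorm(n, 0, 0.3)) - 0.5
  ct <- correlation_table(resp)
  warped <- resp
  warped$charge_uC <- exp(3 * warped$charge_uC)   # strictly monotone
  warped$intensity_mA <- warped$intensity_mA^3
  ctw <- correlation_table(warped)
  expect_equal(ctw$r, ct$r)
})

test_that("constant predictors give missing correlations, not zero", {
  n <- 20
  resp <- data.frame(
    condition = "all", intensity_mA = runif(n, 0.2, 2),
    pulse_width_us = runif(n, 50, 200), num_pulses = sample(1:6, n, TRUE),
    frequency_Hz = 30, delay_ms = runif(n, 0, 300)
  )
  resp$charge_uC <- with(resp, intensity_mA * pulse_width_us * num_pulses) / 1e3
  resp$delta_hr <- resp$charge_uC / 3
  ct <- correlation_table(resp)
  expect_true(is.na(ct$r[ct$predictor == "frequency"]))
  expect_true(is.na(ct$p[ct$predictor == "frequency"]))
  expect_false(anyNA(ct$r[ct$predictor != "frequency"]))
})

test_that("too few records per condition is an error", {
  resp <- data.frame(condition = "x", intensity_mA = 1, pulse_width_us = 100,
                     num_pulses = 2, frequency_Hz = 30, delay_ms = 0,
                     charge_uC = 0.2, delta_hr = 0.1)
  expect_error(correlation_table(resp), ">= 5 records")
})

test_that("group summary gates dispersion and runs both test families", {
  set.seed(14)
  subj <- do.call(rbind, lapply(c("intact", "vagotomy", "isolated"),
    function(st) {
      data.frame(subject_id = paste0(st, 1:6), state = st,
                 hr_bl_bpm = rnorm(6, 160, 8),
                 hr_stim_bpm = rnorm(6, 140, 8),
                 dhr_max = runif(6, 0.1, 0.4), q_thr = runif(6, 0.1, 9),
                 q_at_dhr_max = runif(6, 0.5, 50),
                 q_norm_at_dhr_max = runif(6, 4, 10))
    }))
  resp <- data.frame(condition = rep("vagotomy", 40),
                     hr_bl_bpm = rnorm(40, 180, 4))
  resp$hr_stim_bpm <- resp$hr_bl_bpm - rnorm(40, 8, 1)
  gt <- group_summary(subj, resp)
  expect_s3_class(gt, "group_table")
  expect_true(all(c("variable", "condition", "center", "dispersion",
                    "dispersion_kind", "test", "stat", "p", "n")
                  %in% names(gt)))
  expect_true(all(gt$p[!is.na(gt$p)] >= 0 & gt$p[!is.na(gt$p)] <= 1))
  expect_true(all(gt$dispersion_kind[!is.na(gt$dispersion_kind)]
                  %in% c("sd", "iqr")))
  w <- gt[gt$test == "wilcoxon-signed-rank", ]
  expect_equal(nrow(w), 1)
  expect_lt(w$p, 0.001)
})
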