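test_that("dose-response limits behave: zero dose, saturation, half-effect", {
  m <- subject_model("isolated", hr_baseline = 155, q_thr_true = 9,
                     dhr_max_true = 0.385, np_ref = 9.5)
  ps <- function(i, pw, np) {
    data.frame(intensity_mA = i, pulse_width_us = pw, num_pulses = np,
               frequency_Hz = 30, delay_ms = 0)
  }
  # zero-dose limit
  expect_equal(chronotropic_response(ps(1e-9, 25, 5), m), 0,
               tolerance = 1e-12)
  # saturation limit is capped at dhr_max_true even with pulse gain
  expect_equal(chronotropic_response(ps(1e6, 1000, 14), m), m$dhr_max_true)
  # half-effect point: u = K at the reference pulse count
  q_half <- m$half_effect_qnorm * m$q_thr_true
  i_half <- q_half * 1e3 / (100 * 9.5)
  expect_equal(chronotropic_response(ps(i_half, 100, 9.5), m),
               m$dhr_max_true / 2, tolerance = 1e-9)
})

test_that("5-bpm alignment: a burst of charge q_thr_true drops HR by 5 bpm", {
  for (m in list(default_subject_models("intact")[[1]],
                 default_subject_models("isolated")[[1]])) {
    np <- m$np_ref
    pw <- 100
    i <- m$q_thr_true * 1e3 / (pw * np)
    p <- data.frame(intensity_mA = i, pulse_width_us = pw, num_pulses = np,
                    frequency_Hz = 30, delay_ms = 0)
    drop_bpm <- chronotropic_response(p, m) * m$hr_baseline
    expect_equal(drop_bpm, 5, tolerance = 1e-6)
  }
})

test_that("response is monotone in intensity, pulse width and pulse count", {
  m <- toy_model()
  set.seed(42)
  for (rep in 1:50) {
    base <- data.frame(
      intensity_mA = runif(1, 0.2, 2), pulse_width_us = runif(1, 50, 200),
      num_pulses = sample(1:6, 1), frequency_Hz = runif(1, 10, 40),
      delay_ms = runif(1, 0, 298)
    )
    for (col in c("intensity_mA", "pulse_width_us", "num_pulses")) {
      hi <- base
      hi[[col]] <- hi[[col]] * (1 + runif(1, 0.01, 2))
      expect_gte(chronotropic_response(hi, m),
                 chronotropic_response(base, m))
    }
  }
})

test_that("frequency and delay are response-neutral by construction", {
  m <- toy_model()
  d <- lhs_sample(parameter_ranges("vagotomy"), 30, seed = 8)
  base <- chronotropic_response(d, m)
  perm <- d
  set.seed(1)
  perm$frequency_Hz <- sample(perm$frequency_Hz)
  perm$delay_ms <- sample(perm$delay_ms)
  expect_identical(chronotropic_response(perm, m), base)
})

test_that("constant-rate synthesis yields the expected beats and spacing", {
  rec <- synthesize_ecg(60, 30, fs = 1000, noise_sd_mV = 0, seed = 1)
  tr <- rec$truth$r_peaks
  expect_true(length(tr) >= 29 && length(tr) <= 31)
  expect_equal(unique(round(diff(tr), 9)), 1)
  # isolated-heart baseline spacing
  rec2 <- synthesize_ecg(155, 30, fs = 1000, noise_sd_mV = 0, seed = 1)
  expect_equal(unique(round(diff(rec2$truth$r_peaks), 6)), round(60 / 155, 6))
})

test_that("a step heart-rate profile changes the truth beat intervals", {
  prof <- function(t) ifelse(t < 30, 180, 160)
  rec <- synthesize_ecg(prof, 60, noise_sd_mV = 0, seed = 2)
  tr <- rec$truth$r_peaks
  rr <- diff(tr)
  expect_equal(unique(round(rr[tr[-length(tr)] < 29.5], 6)), round(1 / 3, 6))
  expect_equal(unique(round(rr[tr[-length(tr)] > 30.5], 6)), 0.375)
})

test_that("truth beats reproduce the injected profile within 1 bpm", {
  for (hr in c(60, 155, 240)) {
    rec <- synthesize_ecg(hr, 30, noise_sd_mV = 0, hr_jitter_sd = 2,
                          seed = hr)
    expect_lt(abs(mean_hr(rec$truth$r_peaks, 0, 30) - hr), 1)
  }
})

test_that("profiles below 20 bpm are rejected", {
  expect_error(synthesize_ecg(15, 10, seed = 1), "above 20 bpm")
})

test_that("simulated experiments log one onset per episode, 60 s apart", {
  m <- toy_model(noise = 0)
  d <- lhs_sample(parameter_ranges("vagotomy"), 5, seed = 3)
  ex <- simulate_experiment(m, d, seed = 4)
  ev <- ex$recording$stim_events
  expect_equal(nrow(ev), 5)
  expect_equal(unique(diff(ev$onset_s)), 60)
  expect_equal(ex$recording$duration_s, 30 + 5 * 60)
  expect_error(simulate_experiment(m, d, protocol = list(stim_s = 0,
                                                         pause_s = 30)),
               "positive")
})

test_that("a saturating burst's truth response approaches dhr_max_true", {
  m <- subject_model("intact", 147, q_thr_true = 0.09, dhr_max_true = 0.402,
                     hr_noise_sd = 0, subject_id = "sat")
  d <- data.frame(set_id = 1L, intensity_mA = 50, pulse_width_us = 200,
                  num_pulses = 4, frequency_Hz = 30, delay_ms = 10)
  class(d) <- c("vns_design", "data.frame")
  ex <- simulate_experiment(m, d, seed = 5)
  expect_equal(ex$truth$delta_hr_true[1], 0.402, tolerance = 1e-6)
})

test_that("marker-level simulation matches the model plus sampling noise", {
  m <- toy_model(noise = 2)
  d <- lhs_sample(parameter_ranges("vagotomy"), 75, seed = 10)
  r <- simulate_response_table(m, d, seed = 11)
  expect_equal(nrow(r), 75)
  truth <- chronotropic_response(d, m)
  # window-mean SE is hr_noise_sd / sqrt(~90 beats) ~ 0.2 bpm
  expect_lt(max(abs(r$delta_hr - truth)), 4 * 2 / sqrt(60) / 180 * 3)
  expect_identical(r$charge_uC, compute_charge(d))
})

test_that("default cohorts carry the study innervation structure", {
  expect_length(default_subject_models("intact"), 6)
  expect_length(default_subject_models("vagotomy"), 5)
  expect_length(default_subject_models("isolated"), 4)
  hr <- vapply(default_subject_models("vagotomy"), `[[`, numeric(1),
               "hr_baseline")
  expect_equal(mean(hr), 180)
})
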