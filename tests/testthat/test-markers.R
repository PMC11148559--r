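test_that("relative heart rate reduction follows its defining ratio", {
  expect_equal(compute_delta_hr(147, 136), (147 - 136) / 147)
  expect_equal(round(compute_delta_hr(147, 136), 4), 0.0748)
  expect_equal(compute_delta_hr(155, 128), 27 / 155)
  expect_equal(round(compute_delta_hr(155, 128), 4), 0.1742)
  for (x in c(1, 60, 155.5)) expect_equal(compute_delta_hr(x, x), 0)
  expect_error(compute_delta_hr(0, 10), "hr_bl")
  expect_error(compute_delta_hr(-5, 10), "hr_bl")
})

test_that("burst charge is intensity x pulse width x pulses, in uC", {
  ps <- function(i, pw, np) {
    list(intensity_mA = i, pulse_width_us = pw, num_pulses = np)
  }
  expect_equal(compute_charge(ps(0.45, 100, 2)), 0.09)
  expect_equal(compute_charge(ps(9.0, 1000, 1)), 9.0)
  base <- compute_charge(ps(0.7, 120, 3))
  expect_equal(compute_charge(ps(1.4, 120, 3)), 2 * base)
  expect_equal(compute_charge(ps(0.7, 240, 3)), 2 * base)
  expect_equal(compute_charge(ps(0.7, 120, 6)), 2 * base)
  expect_error(compute_charge(list(intensity_mA = 1)), "must carry")
})

test_that("episode segmentation applies the half-open overlap rule", {
  ev1 <- data.frame(onset_s = 100, set_id = 1L)
  ep <- segment_episodes(ev1)
  expect_equal(ep[, c("bl_start", "bl_end", "stim_start", "stim_end")],
               data.frame(bl_start = 70, bl_end = 100, stim_start = 100,
                          stim_end = 130))
  expect_false(ep$excluded)

  # boundary-only contact is retained
  ep2 <- segment_episodes(data.frame(onset_s = c(60, 120), set_id = 1:2))
  expect_false(any(ep2$excluded))

  # genuine overlap excludes the later episode
  expect_warning(
    ep3 <- segment_episodes(data.frame(onset_s = c(60, 100), set_id = 1:2)),
    "excluded"
  )
  expect_identical(ep3$excluded, c(FALSE, TRUE))

  # an onset earlier than one baseline length is excluded too
  expect_warning(
    ep4 <- segment_episodes(data.frame(onset_s = c(10, 80), set_id = 1:2)),
    "excluded"
  )
  expect_identical(ep4$excluded, c(TRUE, FALSE))

  expect_error(segment_episodes(data.frame(onset_s = c(60, 50),
                                           set_id = 1:2)),
               "strictly increasing")
})

test_that("threshold charge takes the minimal charge with a >= 5 bpm drop", {
  rec <- toy_records(charge = c(0.05, 0.08, 0.12), drop = c(3, 6, 9))
  expect_equal(threshold_charge(rec), 0.08)
  # the criterion is absolute bpm, not relative reduction
  rec_hi <- toy_records(charge = c(0.05, 0.08), drop = c(4.9, 5.0))
  expect_equal(threshold_charge(rec_hi), 0.08)
  expect_error(threshold_charge(toy_records(c(0.05, 0.1), c(2, 4.9))),
               class = "vns_threshold_undefined")
  ties <- toy_records(charge = c(0.08, 0.08), drop = c(5, 7))
  expect_equal(threshold_charge(ties), 0.08)
})

test_that("subject summaries pick the arg-max record with charge tie-break", {
  rec <- toy_records(charge = c(1, 2, 3), drop = c(18, 72, 68.4), hr_bl = 180)
  s <- summarize_subject("s1", "vagotomy", rec, q_thr = 0.25)
  expect_equal(s$dhr_max, 0.4)
  expect_equal(s$q_at_dhr_max, 2)
  expect_equal(s$q_norm_at_dhr_max, 8)
  # tie on delta_hr resolves to the smaller charge
  rec2 <- toy_records(charge = c(3, 2), drop = c(40, 40))
  s2 <- summarize_subject("s2", "vagotomy", rec2, q_thr = 1)
  expect_equal(s2$q_at_dhr_max, 2)
  # single qualifying record defines every field
  rec3 <- toy_records(charge = 0.5, drop = 9)
  s3 <- summarize_subject("s3", "vagotomy", rec3)
  expect_equal(s3$q_thr, 0.5)
  expect_equal(s3$q_at_dhr_max, 0.5)
  expect_equal(s3$q_norm_at_dhr_max, 1)
  # undefined threshold propagates
  expect_error(summarize_subject("s4", "vagotomy",
                                 toy_records(0.5, 2)),
               class = "vns_threshold_undefined")
})

test_that("charge markers are scale-equivariant, normalized charge is not", {
  rec <- toy_records(charge = c(0.4, 0.9, 2.2, 5), drop = c(2, 6, 11, 14))
  s <- summarize_subject("s", "vagotomy", rec)
  for (c_scale in c(0.1, 3, 42)) {
    rec2 <- rec
    rec2$charge_uC <- rec2$charge_uC * c_scale
    s2 <- summarize_subject("s", "vagotomy", rec2)
    expect_equal(s2$q_thr, s$q_thr * c_scale)
    expect_equal(s2$q_at_dhr_max, s$q_at_dhr_max * c_scale)
    expect_equal(s2$q_norm_at_dhr_max, s$q_norm_at_dhr_max)
  }
})

test_that("delta_hr stays below 1 and vanishes only at equality", {
  set.seed(11)
  hr_bl <- runif(200, 40, 300)
  hr_st <- runif(200, 0, 300)
  d <- compute_delta_hr(hr_bl, hr_st)
  expect_true(all(d <= 1))
  expect_identical(d == 0, hr_st == hr_bl)
})

test_that("response extraction reproduces windowed rates from truth peaks", {
  m <- toy_model(noise = 0)
  d <- lhs_sample(parameter_ranges("vagotomy"), 3, seed = 21)
  ex <- simulate_experiment(m, d, seed = 22, trace_noise_sd_mV = 0)
  peaks <- r_peak_series(ex$recording$truth$r_peaks, 1000, "truth")
  resp <- compute_responses(peaks, ex$recording$stim_events, d,
                            subject_id = "t", condition = "vagotomy")
  expect_equal(nrow(resp), 3)
  expect_equal(resp$delta_hr, ex$truth$delta_hr_true, tolerance = 0.01)
  expect_equal(resp$charge_uC, ex$truth$charge_uC)
})
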