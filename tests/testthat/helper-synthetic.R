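# shared helpers for building fixtures in code

# match detected peaks to truth at a tolerance; returns tp / fn / fp counts
match_peaks <- function(detected, truth, tol_s) {
  detected <- as.numeric(detected)
  tp <- sum(vapply(truth, function(t) any(abs(detected - t) <= tol_s),
                   logical(1)))
  fp <- sum(vapply(detected, function(t) !any(abs(truth - t) <= tol_s),
                   logical(1)))
  list(tp = tp, fn = length(truth) - tp, fp = fp)
}

# additive white noise scaled to a target SNR (dB) wrt the clean trace power
noise_sd_for_snr <- function(clean_trace, snr_db) {
  sqrt(mean(clean_trace^2) / 10^(snr_db / 10))
}

# small subject model with convenient round numbers
toy_model <- function(state = "vagotomy", hr = 180, qthr = 0.2,
                      dhr = 0.129, noise = 2, id = "toy") {
  subject_model(state, hr_baseline = hr, q_thr_true = qthr,
                dhr_max_true = dhr, hr_noise_sd = noise, subject_id = id)
}

# hand-built response records
toy_records <- function(charge, drop, hr_bl = 180) {
  data.frame(
    hr_bl_bpm = hr_bl, hr_stim_bpm = hr_bl - drop,
    delta_hr = drop / hr_bl, charge_uC = charge
  )
}
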