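---
title: "Methods: cardiac-synchronized VNS analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac-synchronized VNS analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vnschrono` analyses cardiac-synchronized vagus nerve stimulation (VNS)
experiments in which bursts of current pulses, triggered on the ECG R-peak,
are applied to the cervical vagus nerve under three innervation states:
intact innervation, bilateral rostral vagotomy, and the fully denervated
isolated (Langendorff) heart. The analysis chain is

1. **Design** — Latin hypercube sampling (LHS) of the five burst parameters
   (intensity $I$ in mA, pulse width $PW$ in µs, number of pulses $NP$,
   intra-burst frequency $f$ in Hz, onset delay in ms) within per-condition
   ranges;
2. **Acquisition** — ECG at 1 kHz with a stimulation-event log, 30 s of
   stimulation per parameter set followed by a 30 s pause;
3. **Beat detection** — offline energy-operator (Pan–Tompkins lineage)
   R-peak detection, plus an emulation of the online dynamic-threshold
   trigger used for cardiac synchronization;
4. **Markers** — per episode, the relative heart rate reduction
   $\Delta HR = (HR_{bl} - HR_{stim}) / HR_{bl}$ and the burst charge
   $Q = I \cdot PW \cdot NP$ (mA·µs = nC, reported in µC); per subject,
   the physiological threshold charge $Q_{thr}$ (smallest tested charge
   that lowers heart rate by at least 5 bpm), the maximum reduction
   $\Delta HR_{max}$, its charge $Q_{\Delta HR,max}$ and the normalized
   charge $\tilde{Q}_{\Delta HR,max} = Q_{\Delta HR,max} / Q_{thr}$;
5. **Statistics** — Shapiro–Wilk-gated descriptors, Kruskal–Wallis
   comparisons across innervation groups, Wilcoxon signed-rank tests of
   baseline versus stimulated heart rate, and Spearman correlations between
   each stimulation parameter (plus charge) and $\Delta HR$.

Because real recordings of this kind are not distributable with a package,
all of this runs against a first-class synthetic-data generator whose
defaults emulate the study conditions at desk scale; the generator also
provides ground truth against which every stage is validated.

# Design: Latin hypercube sampling

For $n$ requested parameter sets, each parameter's interval $[lo, hi]$ is
divided into $n$ equal-width strata and each stratum is used exactly once;
pairing across parameters is by independent random permutations. Two
placement modes exist: uniform-within-stratum (the default, standard LHS
practice) and stratum midpoints (useful for exact reproducibility checks).
The integer parameter `num_pulses` is stratified on the continuous scale,
then rounded half-up and clamped; this preserves stratification up to the
rounding and honours integrality. No orthogonality or maximin optimisation
is attempted — plain LHS is the design the analysis assumes.

A burst occupies `delay + (num_pulses - 1)/frequency` after the trigger.
`validate_burst_fit()` checks this against a cardiac-cycle budget but only
warns: the published delay ranges run close to typical cycle lengths, so
near-cycle bursts were evidently tolerated in the original rigs.

# The synthetic generator

## Dose–response model

Each synthetic subject carries a saturating Hill dose–response in
normalized charge $u = Q / Q_{thr}^{true}$:

$$\Delta HR(u, NP) \;=\; \Delta HR_{max}^{true}\,
\frac{u^{h}}{K^{h} + u^{h}}\,
\bigl(1 + g\,(NP - NP_{ref})\bigr)
\quad\text{clipped to } [0, \Delta HR_{max}^{true}],$$

with Hill exponent $h = 4$, a weak pulse-count gain $g = 0.02$ per pulse
around the mid-range reference $NP_{ref}$, and no dependence on frequency
or delay (they enter timing only). A Hill curve is the minimal form with a
threshold region, a quasi-linear range and saturation; $h = 4$ makes
saturation reachable within the tested charge ranges while keeping a
recognisable threshold.

**5-bpm alignment.** The half-effect constant $K$ is not free: it is solved
per subject from $\Delta HR(1, NP_{ref}) \cdot HR_{bl} = 5\ \mathrm{bpm}$,
i.e. $K^h = \Delta HR_{max}^{true} HR_{bl} / 5 - 1$. A burst of charge
exactly $Q_{thr}^{true}$ then lowers the noise-free heart rate by exactly
5 bpm, so the marker-level threshold estimate targets the model parameter
itself (up to the granularity of the tested-charge ladder, below).

## Default cohorts and calibration

The shipped cohorts are 6 intact, 5 vagotomy and 4 isolated subjects.
Baseline heart rates are fixed per subject (means 147, 180 and 155 bpm;
spreads chosen so group dispersion is of the order the study reports), the
saturation response is state-level (0.402, 0.129, 0.385), and the latent
threshold charges average 0.09, 0.20 and 8.0 µC. The isolated latents sit
about 1 µC below the 9 µC group value they are calibrated to reproduce:
the reported marker is the smallest *tested* charge above threshold, and
the wide isolated-heart ranges yield a sparse charge ladder near 9 µC
(adjacent tested charges typically 0.5–3 µC apart), which inflates the
marker by roughly that amount on average. The narrow in-vivo ranges sample
charge densely near their thresholds, so no such offset is needed there.

## Waveform synthesis

Beats are placed by stepping through the instantaneous heart-rate profile
($t_{k+1} = t_k + 60 / (HR(t_k) + \epsilon_k)$ with
$\epsilon_k \sim \mathcal{N}(0, \sigma_{HR})$, default
$\sigma_{HR} = 2$ bpm), and each beat contributes a three-Gaussian PQRST
template: R amplitude 1 mV with 8 ms width, and P and T bumps whose offsets
and widths scale with the local RR interval so morphology stays valid from
40 to 300 bpm. White Gaussian noise is added to the trace. This is adequate
for energy-operator detection and makes no claim of pathophysiological
realism — no arrhythmia, no baseline wander, no electrode artefacts, no
respiratory modulation. Passing detector tests on this generator therefore
demonstrates correctness of the detection logic, not clinical-grade
performance on hospital ECGs.

## Episode dynamics

Each episode is 30 s of unchanged baseline followed by 30 s of stimulation
during which the rate steps down by the expected response (no onset
latency is modelled). After the burst train ends the rate relaxes back
exponentially. The recovery time constant defaults to 0.2 s: the protocol
this emulates pauses *until the heart rate has returned to baseline*, and
because each episode's baseline window is exactly the preceding pause, a
slow washout would leak the previous response into the next baseline
measurement and bias every downstream marker (a 5 s constant, for example,
leaves a 17 % average residual in a 30 s window, depressing measured
baselines by up to ~10 bpm after strong responses and inflating recovered
threshold charges by ~40 %). The fast default keeps baseline windows clean,
which is what the protocol's wait-for-baseline rule guarantees in the real
experiment. Ground truth stores, per episode, both the model-level expected
response and the window-mean noise-free response actually realised by the
profile.

# R-peak detection and triggering

## Offline detector

The offline path is band-pass (5–15 Hz Butterworth, zero-phase with
reflection padding) → five-point derivative → squaring → 150 ms centred
moving-window integration → adaptive dual-threshold peak picking with a
200 ms refractory period and RR-based search-back. Two implementation
details matter on fast hearts:

* the band-pass ringing of a narrow QRS produces side lobes in the
  integrated signal, so candidate maxima are first reduced by non-maximum
  suppression within half a refractory span, and each surviving candidate
  is snapped to the trace maximum within ±50 ms before thresholding — the
  adaptive scan then operates on R-apex-aligned fiducials;
* the refractory comparison carries 2 % slack, so rhythms whose RR equals
  the refractory period exactly (300 bpm at the 200 ms default) are not
  half-rejected by fiducial jitter.

Thresholds are initialised from the first two seconds of the integrated
signal; search-back triggers when the gap since the last accepted beat
exceeds 1.66 times the running median RR and accepts the strongest skipped
candidate above half the main threshold. All constants (`bandpass_hz`,
`integrate_ms`, `refractory_ms`, `match_window_ms`) live in
`detector_config()`; they follow the energy-operator detector lineage and
no claim is made that they equal the constants of any particular rig.

## Online trigger

The trigger emulation is a single causal pass over the causally band-pass
filtered signal: the threshold is $\theta = 0.6$ times the running signal
maximum with exponential decay (2 s time constant, with an absolute floor
of 0.1 mV so the warm-up period does not fire on noise), a trigger is
emitted at the first sample crossing the threshold, and a 200 ms refractory
follows. Causality is tested literally: truncating the future may not
change past triggers.

## Windowed heart rate

`mean_hr()` is $60 / \overline{RR}$ over the RR intervals that lie entirely
inside the half-open window; intervals straddling a boundary are excluded.
This definition is unbiased for partial windows, unlike beat counting, and
all reported heart-rate descriptors depend on it.

# Markers

Episode windows are `[onset − 30, onset)` and `[onset, onset + 30)`;
an episode whose baseline would overlap an earlier stimulation window (in
its interior — boundary contact is fine) is excluded with a warning rather
than silently mismeasured. The threshold-charge criterion uses the absolute
drop in bpm (at least 5), not the relative reduction — the two coexist
deliberately. $Q_{thr}$ is computed over tested combinations only, with no
interpolation. The arg-max record for $\Delta HR_{max}$ resolves ties
toward the smaller charge (charge-efficient and deterministic). Subjects in
which no tested burst reaches the 5 bpm criterion have no threshold; they
are excluded from charge-normalized summaries but retained for heart-rate
statistics.

# Statistics

* **Descriptors.** Shapiro–Wilk at $\alpha = 0.05$ gates the dispersion
  measure: mean ± sd when normality is not rejected, mean ± IQR (Q3 − Q1,
  linear-interpolation quantiles) otherwise. Reporting a *mean* with an
  IQR is unusual; it is implemented literally because it is the convention
  of the reports this package reproduces.
* **Group comparisons.** Kruskal–Wallis with tie correction; fully tied
  data returns $H = 0$, $p = 1$ by convention. Descriptors and group
  comparisons run on subject-level values.
* **Paired test.** Wilcoxon signed-rank on baseline versus stimulated
  heart rate, zero differences dropped, exact null up to 25 informative
  pairs and normal approximation with continuity correction beyond. The
  paired test pools per-episode pairs within a condition, where it has the
  power such reports quote; subject-level pairing at $n \le 6$ cannot reach
  the quoted significance levels.
* **Correlations.** Spearman's $r$ between each predictor (five parameters
  plus derived charge) and $\Delta HR$, pooled across subjects within each
  condition (the record count per condition equals all tested parameter
  combinations, which is consistent with pooling). $p$-values use the
  $t$ approximation, or a seeded permutation test below 10 records.
  Constant predictors yield missing values, not zero. No multiple-testing
  adjustment is applied anywhere, mirroring the analysis this reproduces.

# Numerical and reproducibility choices

* All randomness is seed-derived; design, simulation and statistics seeds
  are explicit in `pipeline_config()`, and functions restore the caller's
  RNG state. Identical configurations produce byte-identical CSV outputs.
* CSV is the canonical exchange format (full-precision `%.17g`);
  `read_response_db()` validates rows, recomputes a missing charge column,
  rejects rows with non-positive baselines (reporting line numbers) and
  adapts foreign headers through a column map.
* Problem sizes: the default pipeline simulates 15 subjects × 75–100
  episodes × 60 s at 1 kHz (about 70 M samples end to end) in roughly two
  minutes on one core. The test suite uses the same study-scale run once
  and smaller designs elsewhere.

# Known limitations

* The generator's noise model (white trace noise + Gaussian beat-to-beat
  rate jitter) contains none of the structured artefacts that dominate real
  ECG trouble (motion, mains, electrode pops); detector performance numbers
  on synthetic data are upper bounds.
* The chronotropic model is memoryless between episodes apart from the
  exponential washout; no habituation, no baroreflex dynamics, no
  respiratory sinus arrhythmia.
* Threshold-charge recovery is limited by the granularity of the tested
  charge ladder — with wide parameter ranges the smallest qualifying tested
  charge can sit far above the latent threshold. This is a property of the
  experimental design, not of the estimator, and it is why the isolated
  cohort's latent thresholds are set below the group value they reproduce.
* The online trigger is an emulation for analysis and testing; it is not a
  real-time implementation and carries no latency guarantees beyond the
  tested synthetic behaviour.
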