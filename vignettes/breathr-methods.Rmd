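---
title: "Methods: breath segmentation, the pause statistic, and rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath segmentation, the pause statistic, and rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breathr)
```

# The model of a breath

`breathr` treats plethysmography airflow as a signed signal in mL/s with
inspiration negative. A breath is delimited by inspiration onsets
(positive-to-negative zero-crossings); the intervening
negative-to-positive crossing is the expiration onset. Segments are
half-open `[insp_onset, next insp_onset)` and tile the recording; sample
indices are 1-based (the R convention). Partial breaths before the first
and after the last inspiration onset are discarded.

Opioids add a third phase to this two-phase skeleton: after the
expiratory lobe, airflow sits near zero for tens to hundreds of
milliseconds before the next inspiration — the **pause**. Under
hypercapnia the pause often terminates with an active-expiration
transient, which is *part of* the pause rather than its end. The pause
is therefore defined operationally: the time from the first sample after
the expiratory peak at which flow falls below a threshold (default
0.5 mL/s) to the next inspiration onset, regardless of later
re-excursions above threshold. Phase additivity, `Ti + Te + pause =
period` to within one sample, holds by construction and is asserted as a
property test on every synthetic breath.

Two readings of "expiration" are reconcilable in the output: `te_ms`
excludes sub-threshold time, and `te_total_ms = te_ms + pause_ms`
includes it.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `hysteresis` | 0.05 | mL/s | a crossing counts only once the signal reaches this excursion on the far side for two consecutive samples; rejects baseline noise without delaying clean crossings |
| `min_breath_ms` / `max_breath_ms` | 50 / 5000 | ms | QC band wide enough for ~0.2–20 Hz breathing, so even deeply depressed breaths with several-hundred-ms pauses pass |
| `min_peak_insp_flow` | 0.2 | mL/s | flags candidate breaths too faint to be real inspirations |
| `flow_threshold` | 0.5 | mL/s | the pause threshold: low airflow that is "almost zero" on the scale of murine expiratory flow |
| `min_pause_ms` | 50 | ms | sub-threshold spans shorter than this are measured but not called pauses; 50–100 ms events are plausible false positives, and the raw span is always exported so the pause distribution can be rebuilt at any cutoff |

QC-flagged breaths stay in the table (with `qc_flags`) and are excluded
from session means — visible, never silently dropped.

Tidal volume is the trapezoidal integral of |flow| over inspiration,
reported in µL. No humidity/temperature (Drorbaugh–Fenn) correction and
no body-weight normalization are applied: with stable chamber
conditions, within-animal drug/control *ratios* are the interpretable
quantity, and that is the unit of statistics throughout.

# Paired statistics

The crossover design — every animal measured under control and drug —
motivates three choices:

1. **Gated paired test.** Shapiro–Wilk is run on the paired differences
   (the standard paired reading; per-condition testing is available by
   gating on the raw vectors yourself). At `normality_p >= 0.05` a
   paired Student's *t* is used, otherwise the Wilcoxon signed-rank test
   (the published description says "rank sum", but for paired data the
   signed-rank test is the test meant).
2. **Effect size.** Paired Cohen's `d_z = mean(diff)/sd(diff)`. Only the
   paired form can produce the effect sizes of ~6 seen when all animals
   shift in the same direction.
3. **No multiplicity correction.** Raw p-values are reported per metric,
   and the output flags this so downstream users can adjust if they
   compare many metrics.

The deleted-vs-sham comparison is a 2 (group, between) × 2 (pre/post,
within) mixed repeated-measures ANOVA, fitted with `aov` and a subject
error stratum. With one between factor and a time factor balanced
within every subject, group and time are orthogonal, so these sums of
squares coincide with Type-II even for unequal group sizes; with two
within levels no sphericity correction is required. The between-group
denominator df is `n_subjects - 2` (13 animals give the familiar
F(1, 11) structure). A constant response returns `F = 0` for every
effect rather than 0/0.

# Slice rhythm analysis

In vitro population recordings (nominally 10 kHz) are band-pass filtered
3–400 Hz (2nd-order Butterworth, zero-phase forward–backward),
rectified, and integrated with a 50 ms centered moving average. Burst
detection on this envelope is deliberately simple and fully
parameterized, because no published algorithm exists to reproduce:

- threshold = baseline-epoch median + `k_mad` (default 5) MADs;
- supra-threshold events with onset gaps under `min_ibi_s` (default 1 s)
  are merged;
- merged events with less than `min_duration_s` (default 0.1 s) of total
  supra-threshold time are discarded as noise — population bursts carry
  hundreds of ms above threshold, noise excursions a few ms;
- amplitude is the envelope peak above the baseline median; the integral
  above baseline (`area`) is exported as an alternative size measure,
  since peak-vs-area is a genuinely open choice.

Because the threshold is data-driven, burst counts are invariant to
global gain, which is asserted as a property test. Dose–response curves
divide each epoch's burst rate and mean amplitude by the baseline
epoch's, so the baseline point is exactly (0 nM, 1, 1) and
renormalization is idempotent. **Rhythm cessation** is the absence of
burst onsets in the final `window_s` (default 300 s) of an epoch —
"stopped and stayed stopped", the state that antagonist wash
subsequently reverses. Epoch boundaries come from metadata (fixed
20-minute bath epochs), not change-point detection.

# The synthetic-data generator

The generator exists so that every stage has exact ground truth. It
emulates the *features the pipeline measures*, not lung mechanics:

- **Breath waveform.** Half-sine lobes: inspiration of duration Ti and
  peak −PIF; expiration shaped so that, when a pause is programmed, the
  lobe sits just above the 0.5 mL/s threshold at the programmed end of
  Te and then drops to a residual 0.1 mL/s — strictly positive (no
  spurious crossings) and strictly sub-threshold (pauses detectable by
  design). Half-sines make tidal volume analytic:
  `tv = (2/pi) * pif * ti`. An optional terminal transient emulates
  hypercapnic active expiration. A stress test of boundary behaviour can
  be built by passing custom `breath_params` with a lobe near threshold.
- **TV-preserving rule.** Per breath, target volume and PIF are drawn
  independently and `ti = (pi/2) * tv / pif`. This preserves tidal
  volume under airflow depression *by construction* and programs the
  negative Ti-vs-PIF correlation seen in real breathing.
- **Regimes.** Hypercapnic saline: tv 127.3 µL (CV 0.10), PIF 4.0 mL/s
  (CV 0.15), Te 50 ms (CV 0.15) — Ti ≈ Te ≈ 50 ms, ~10 Hz. Hypercapnic
  morphine: PIF ×0.4 (hence Ti ×2.5), log-normal pauses with median
  200 ms (sdlog 0.5) on 23.4% of breaths. The pause probability was
  solved once, by Monte Carlo at design time, so that the *mean
  instantaneous frequency* ratio (the arithmetic mean of 1/period that
  the pipeline reports, not the reciprocal of the mean period) is
  exactly 0.5; the resulting pause share of the mean period is ~23%.
  Normoxic regimes breathe at ~4 Hz and encode a 60% rate and airflow
  reduction (pause probability 0.76, median 500 ms), on the same
  derivation. White measurement noise (sd 0.02 mL/s) is added; the pause
  residual (0.1 mL/s) sits 20 noise SDs below the pause threshold and
  7.5 above the negative hysteresis bound, so neither pause detection
  nor crossing detection is noise-limited.
- **Cohorts.** Each animal gets latent log-normal amplitude and duration
  factors (CV 0.15) multiplying the regime means of *both* its sessions,
  so between-animal variability cancels in within-animal ratios and the
  programmed effects are recovered in expectation. Seeds are mandatory;
  identical seeds give byte-identical written files.
- **Slices.** Bursts are triangular envelopes on a 100 Hz carrier with
  mild multiplicative noise over 1/f background noise; baseline
  inter-burst intervals are uniform on 5–10 s, and per-epoch rate and
  amplitude multipliers implement agonist depression (multiplier 0 =
  silenced). The near-deterministic carrier keeps the integrated
  envelope's peak at the programmed burst centre, so detector accuracy
  is scored against ground truth (≥95% of peaks within 25 ms).

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: real breath-shape variability
(sniffs, sighs, movement artefacts), behavioural-state switching within
a session, chamber physics, drug pharmacokinetics, or electrode drift in
slice recordings. Recovery results validate the pipeline's correctness
on signals with known structure, not its robustness to every artefact of
a real rig.

# Numerical choices and degenerate inputs

- Crossing localization: linear interpolation between the last
  zero-straddling sample pair before the confirming excursion, rounded
  to the nearest sample; a state commit requires two consecutive samples
  beyond the hysteresis threshold, so isolated noise spikes cannot flip
  the detector.
- Pause search starts at the expiratory peak, never on the rising limb
  of expiration.
- A breath whose expiratory lobe never reaches the threshold reports the
  brief sub-threshold lobe tail as its pause span; the `min_pause_ms`
  gate keeps such tails out of `has_pause`.
- Flat traces yield zero crossings; fewer than two inspiration onsets
  yields an empty segmentation with a warning, not an error.
- Empty pause vectors give an empty density with a warning; a
  single-valued pause distribution widens its bin range by ±0.5 ms to
  avoid zero-width bins.
- `read_trace` rejects non-monotonic time, >1% sampling jitter, and
  non-finite samples (listing their indices); it never truncates.
- All generator randomness flows through a single seed argument;
  `regime_expected_rate` uses an internal fixed seed so programmed
  ratios are deterministic functions of the regime.

# Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the study designs at
reduced scale, chosen so that estimates are comfortably inside the
tolerances being asserted: breathing sessions of 40–120 s (≈200–1200
breaths each; a 60 s saline session already yields ~600 breaths, giving
sub-1% standard errors on session means), 29-animal cohorts, and slice
simulations of 10-minute epochs at 2 kHz with the 5-minute cessation
window of the full design. The statistical structure — regime
parameters, cohort size, epoch logic — is the full-scale one.

# Known limitations

- The pause is measured to the next inspiration onset; if one instead
  ends it at the active-expiration onset, pauses shorten by the
  transient's duration. Both conventions are recoverable from the
  exported table (`pause_ms`, `te_total_ms`, and the raw trace).
- The burst criterion is validated against synthetic ground truth only;
  on real electrodes, `k_mad`, `min_ibi_s` and `min_duration_s` should
  be checked against a scored segment before batch use.
- `aov`-based mixed ANOVA assumes no missing cells (every subject
  measured at both times); unbalanced *within*-subject data are
  rejected, not imputed.
- Approximated volumes are comparable within animal across conditions,
  not across animals or rigs.
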