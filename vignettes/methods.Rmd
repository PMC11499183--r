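---
title: "Methods: auditing automated QTc against the manual tangent method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing automated QTc against the manual tangent method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtcaudit)
```

## The question

Electrocardiographs print a QTc value and an interpretation line on every
ECG. Clinicians frequently act on that number without re-measuring, yet
the machine's QT algorithm differs from the reference manual technique in
two structural ways:

1. **Superimposition.** The machine forms a global QT from the *earliest*
   QRS onset to the *latest* T-wave end across all leads. A human reader
   instead measures one lead (II or V5 by convention, unless another lead
   is clearly longer). Because the superimposed interval is a max-minus-min
   over leads, it is mathematically never shorter than any single lead's
   QT; under per-lead measurement variability it is biased long.
2. **Correction.** The machine applies a heart-rate correction (Bazett)
   but typically no QRS-duration adjustment. The manual protocol subtracts
   the QRS excess over 100 ms when the QRS is wide (>= 120 ms), so in
   bundle branch block the two methods diverge further.

`qtcaudit` builds a fully synthetic, seeded test bench for this
discordance: a waveform generator whose ground-truth fiducials are
*defined by the tangent construction itself*, an algorithmic reader that
implements the manual protocol, a stylized machine emulator, and the
downstream accuracy statistics (confusion table against the manual gold
standard, predictive values with Wilson intervals, agreement, and a
logistic model of false-positive predictors).

## Synthetic beats with an analytic tangent oracle

Each beat is a sum of gaussian deflections (P, Q, R, S, T, optionally U),
in the style of dynamical ECG simulators. The gaussian gives the tangent
method a closed form: the tangent at the inflection point of a gaussian
limb (at `center + sigma`) crosses the baseline at exactly
`center + 2 * sigma`. The generator exploits this three times per beat:

* **QRS onset** — the Q deflection (sigma 4 ms) is centered at
  `2 * sigma_Q`, so its leading-limb tangent crossing sits at 0 ms, the
  beat's reference time.
* **QRS offset** — the S deflection is centered at
  `true_qrs_ms - 2 * sigma_S`, so its trailing-limb crossing sits at
  `true_qrs_ms`.
* **T end** — the T deflection is centered at
  `true_qt_ms - 2 * sigma_T`, so the tangent-method T end is exactly
  `true_qt_ms`.

Ground truth is therefore not an annotation added after the fact: it is
the analytic solution of the very construction the estimator performs.
A delineator that implements the tangent method correctly must recover
`true_qt_ms` on noise-free records up to discretization error, and any
residual is interpretable as estimator bias, not label noise.

```{r oracle}
tr <- synthesize_record(synth_config(seed = 1, rhythm =
  rhythm_spec("sinus", mean_rr_ms = 1000, rr_cv = 0)))
m <- manual_qt(tr$record)
c(truth = tr$truth$true_qt_ms, measured = m$qt_ms)
```

Default morphology (units in ms and mV): Q 8/4/-0.15, R ~1.0 mV with
sigma `qrs/11`, S -0.25 with sigma `max(6, qrs/12)`, T amplitude 0.35
(males) or 0.30 with sigma 40/36 (male/female), P at -90/20/0.12, U at
`qt + 70`/22/0.08. Twelve leads share the same template scaled by
physiologic per-lead factors (lead II and V4 largest), so amplitude
scaling changes legibility but not the tangent landmarks. Records add
white noise, optional 0.25 Hz baseline wander, and optional artifact
bursts; none of these alter the ground truth.

Rhythms: sinus (normal RR variability, CV 0.02), atrial fibrillation
(gamma-distributed RR, CV 0.18, no P wave), premature ventricular and
atrial beats (short coupling, compensatory pause, wide inverted-T PVC
morphology), bigeminy (every second beat a PVC), and bundle branch block
(QRS widened to >= 120 ms with discordant T).

## The algorithmic manual reader

`detect_beats()` finds R peaks on lead II, then delineates every lead
around those anchors:

* **Baseline** — median amplitude over the 60–20 ms window before QRS
  onset (PR-segment proxy).
* **Landmarks** — Q and S troughs from a narrow (8 ms) Savitzky–Golay
  smooth; the T peak from a wider (30 ms) smooth of the ST–T region.
* **Tangent** — the steepest point of the terminal limb is located on the
  smoothed derivative, then the tangent line itself is fit by ordinary
  least squares on the raw samples in a 20 ms window around that point,
  and intersected with the baseline. The limb is locally straight at its
  inflection, so the line fit is unbiased there and far less
  noise-sensitive than a pointwise derivative. The search is truncated at
  the first *sustained* (>= 8 ms) baseline crossing and at the first
  sustained slope reversal, so U waves and the next P wave are never
  entered while single noisy samples cannot stop the search early.

`manual_qt()` then applies the protocol's selection rules:

* **Beats** — ectopic beats and the beat after an ectopic are never
  measured. In AF, QT is averaged over the first five usable beats
  (flagged when fewer exist). Otherwise one representative beat is
  measured: the usable beat whose preceding RR is closest to the median.
  If that beat is illegible on every lead, the reader walks to the next
  most representative beat. Bigeminal records (>= 40% ectopy) raise a
  typed `qtc_excluded` condition: the protocol cannot measure them.
* **Leads** — lead II or V5 (the longer; ties favour II), unless a
  non-primary lead is *measurably* longer. Two reading-realism parameters
  are deliberate additions where the protocol is silent: a non-primary
  lead must exceed the best primary lead by more than `lead_margin_ms`
  (default 10 ms — a caliper comparison cannot resolve less), and leads
  whose largest T deflection is under 0.15 mV are unmeasurable. Without
  the margin, taking a literal maximum of twelve noisy per-lead reads
  inflates QT by roughly the expected maximum of twelve noise draws
  (~+13 ms at 0.02 mV noise), which no human comparison of near-equal
  leads reproduces.
* **RR** — the preceding RR of the measured beat (mean preceding RR of
  the averaged beats in AF), then Bazett `QT / sqrt(RR/1000)` and, for
  QRS >= 120 ms, the adjustment `QTc - (QRS - 100)`.

## The machine emulator

The vendor algorithm is proprietary; `automated_qt()` is a deliberate
mechanistic caricature keeping only the two behaviours that drive the
discordance: on the same representative beat(s), QT is the latest
tangent T end minus the earliest QRS onset *across all measurable
leads*; RR is the global mean over the record; QTc is Bazett-only, with
no QRS adjustment. By construction the automated QT dominates every
single lead's QT on the measured beat, which yields the package's
central directional invariant: on default synthetic cohorts the mean
automated-minus-manual QTc difference is positive. The *magnitude* of
that gap depends on noise level, lead-amplitude spread and morphology,
and is not a calibrated estimate of any particular device.

`render_interpretation()` adds the final machine behaviour: even when
the automated QTc crosses the long-QT threshold, the printed text omits
"prolonged QT" with probability 0.75 (a Bernoulli model of interpretation
suppression; the true logic is unknown).

## Classification and statistics

Long QT is QTc >= 470 ms (males) / >= 480 ms (females), inclusive, with
the manual reading as gold standard; `label_pair()` produces TP/FP/TN/FN.
`diagnostic_metrics()` reports sensitivity, specificity, PPV and NPV with
Wilson score intervals (never 0/1 point intervals; undefined metrics are
NA). `agreement()` gives Pearson r and Cohen's kappa in closed form.
`fit_logistic()` is a maximum-likelihood logistic fit with Wald
intervals; complete separation and non-convergence are detected and
flagged rather than silently reported. `compare_groups()` picks the
classical two-group test: Student t for continuous covariates,
chi-square for categorical, switching to Fisher's exact test by
Cochran's rule (any expected cell under 5, or a 2x2 table with under 40
observations).

```{r table}
dm <- diagnostic_metrics(confusion(c(rep("TN", 485), rep("FN", 4),
                                     rep("FP", 53), rep("TP", 25))))
dm
```

## Cohorts and the end-to-end pipeline

`cohort_config()` describes an unselected hospital-style population:
AF 3%, paced 0.2%, other rhythm 1.4%, BBB 4.4%, artifact 16%, PVC 4%,
PAC 1.76%, U waves 0.7%, 52% female, heart rate 83 +/- 19 bpm, age
52 +/- 18 years, gold-standard adjusted QTc ~ N(417, 35) ms. Each
record's target QTc is mapped back to a raw QT at its heart rate so the
whole cohort keeps an analytic truth. `run_pipeline()` chains
simulate → measure (both methods) → correct → classify → analyze and
writes measurements, exclusions, paired calls, a JSON report and a run
log, each stamped with the seed and a config hash; the same config and
seed reproduce every artifact byte for byte.

Typical problem sizes: a 10 s, 500 Hz, 12-lead record is a 5000 x 12
matrix; a 200-record cohort generates and delineates in about a minute
on one CPU.

## What the synthetic data does and does not emulate

Captured: tangent-consistent fiducials; lead-amplitude structure; RR
statistics of sinus rhythm and AF; ectopy with post-ectopic pauses;
BBB widening with discordant T; U waves; white noise, wander and
artifact bursts; prevalence structure of an unselected hospital cohort.

Not captured: real T-wave morphologies (biphasic, notched, flattened),
respiration-locked amplitude modulation, electrode placement effects,
pediatric morphology, true vendor algorithms (median-beat forming,
proprietary T-end rules), and reader-to-reader variability. Conclusions
about the *direction* and *mechanism* of machine-manual discordance
transfer; absolute magnitudes do not.

## Known modeling tensions

* The source protocol's exclusion arithmetic implies a small pediatric
  share (~3%) while describing ~13–17% of records as pediatric
  elsewhere; the cohort generator uses the age distribution (52 +/- 18,
  truncated at 1), implying ~3%.
* Reported suppression counts (39 of 52-odd machine-positive prints vs a
  75% rate on 53 false positives) do not reconcile exactly; suppression
  is modeled as Bernoulli(0.75).
* The reader's lead-comparison resolution and minimum legible T
  amplitude are unstated; the defaults above are documented choices,
  exposed as parameters.
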