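---
title: "Startle-reflex assays of tinnitus and frequency discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Startle-reflex assays of tinnitus and frequency discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpias)
```

## The assays

**gpias** analyses two behavioural assays built on the acoustic startle
reflex (ASR) — the whole-body flinch a rodent produces to a loud sound
burst, quantified as peak force on a platform transducer.

*Gap detection (GPIAS).* A brief silent gap in an ongoing narrow-band
background noise normally inhibits the startle that follows it.  An
animal experiencing tinnitus in that noise band is thought to perceive
its phantom sound "filling in" the gap, so the gap loses its inhibitory
power — band-specific loss of gap-prepulse inhibition is the operational
behavioural signature of tinnitus.  A session has 98 trials: startle-only
(SA) bookends first and last, and 8 SA plus 8 gap (GA) trials in each of
six bands (6–8, 10–12, 14–16, 18–20, 26–28 kHz and 2–32 kHz broadband),
randomly intermixed.  The per-trial ASR amplitude is the maximum force in
the 550 ms after startle onset minus the mean activity in the preceding
500 ms, and per band

$$\mathrm{ASR_{inhibition}}(\%) = 100 \times \frac{\overline{SA} - \overline{GA}}{\overline{SA}}.$$

*Frequency discrimination (PPI).* A brief shift of a continuous
background tone to a nearby frequency acts as a prepulse: the larger the
relative shift $\Delta f$ (in percent of the background frequency), the
more it inhibits the subsequent startle.  A session is 9 SA trials, 120
prepulse trials over nine frequencies in pseudorandom order, and one
closing SA trial.  Two tasks are defined: FD-medium (12 kHz background,
shifts up to +32%) and FD-high (22 kHz background, shifts down to −32%).
Inhibition is self-normalised within a session against the zero-shift
trials (`ASRnopps`):

$$\mathrm{PPI}(\%) = 100 \times \frac{\mathrm{ASR_{nopps}} - \mathrm{ASR_{pps}}}{\mathrm{ASR_{nopps}}}.$$

## The psychometric model

PPI as a function of the shift is modelled with a generalized logistic,

$$\mathrm{PPI}(\Delta f) = \frac{a}{1 + e^{\,b + c\,\Delta f}} - \frac{a}{2},$$

which passes through the origin when $b = 0$ and saturates at $a/2$.
This symmetric single-scale form was chosen over a two-asymptote variant
(`a1/(1+exp(b+c df)) - a2`) because it enforces the two properties the
assay guarantees by construction — zero inhibition at zero shift (up to
the offset $b$) and a single saturation level; the two-asymptote form
remains selectable via `fit_psychometric(form = "two-asymptote")` for
data that do not honour the self-normalisation.

The discrimination threshold `Th` is the shift at which the *fitted*
curve reaches a stated inhibition level (40 percentage points by
default; the level is a parameter, so a 50%-based threshold is equally
runnable).  It is read as an absolute PPI level, not as a fraction of
the fitted maximum; the closed-form inversion is

$$Th = \frac{1}{c}\left[\ln\!\left(\frac{a}{L + a/2} - 1\right) - b\right],$$

defined whenever the level $L$ lies below the asymptote $a/2$.
`threshold_from_fit()` returns `NA` otherwise, and every converged fit
satisfies the identity `predict(fit, fit$th) == th_level` to better than
1e-6 — this identity is part of the test suite.

Fitting is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
multi-start initialisation: $a$ from twice the largest observed |PPI|
(bounded into $(0, 200]$, i.e. inhibition at most 100%), $b = 0$, and
$c$ over the grid $\pm\{1, 0.1, 0.01\}$, keeping the lowest-RSS
solution.  Flat point sets (zero variance in PPI) are reported as
non-converged with an absent threshold rather than returning an
arbitrary slope.

## Threshold uncertainty: parametric bootstrap

Per-frequency ASR summaries (mean, SD) feed a parametric bootstrap: each
of 1000 draws resamples every frequency's ASR from
$\mathcal{N}(\text{mean}, \text{SD})$, recomputes PPI against the drawn
zero-shift reference, refits the logistic (warm-started at the point
estimate) and extracts the threshold.  Draws with failed refits or
undefined thresholds are discarded and counted (`n_failed`); a result
with more than half its draws failed is flagged unreliable.  Normal
draws can produce negative forces; they are clipped at a small positive
floor (`floor = 1e-6` by default, configurable) since amplitudes are
forces.  A post-exposure threshold differs significantly from baseline
when its bootstrap mean lies at least one *baseline* bootstrap SD from
the baseline mean — deliberately the printed rule of the assay rather
than a formal test, reproduced verbatim by
`compare_threshold_to_baseline()`.

## Artifact exclusion

Excessive movement before the startle inflates the force signal's
variability.  Each trial's pre-startle SD is computed over the 9 s
before startle onset (population convention; the rule is a relative
comparison, so the convention cancels and is fixed only for
reproducibility).  Within a session, a trial is excluded when its pre-SS
SD strictly exceeds 1.3 times the mean pre-SS SD of all trials of the
same frequency group — the noise band in gap sessions, the prepulse
frequency in FD sessions (FD application is toggleable via
`fd_sessions = FALSE`).  The candidate trial is included in its own
group mean, the comparison is strict (`> 1.3 ×`), and flags are computed
in a single pass from the original group means, making the rule
idempotent.

## Tinnitus classification

A mouse is Tinnitus(+) when its gap detection shows a significant
decrease at 4 weeks post exposure — the time chronic tinnitus is
expected to be established — pooling over all six bands.  The default
contrast pairs per-(band, session) percent inhibition at baseline
against week 4 in a two-tailed paired t-test at $\alpha = 0.05$, gated
on the direction (significant *and* decreased).  The direction gate
keeps the two-tailed convention of the printed p-values while making the
label one-sided.  When the two timepoints have unequal session counts
the pairing falls back to per-band means.  A literal alternative — week-4
GA amplitudes against their SA counterparts, with tinnitus read as the
*absence* of significant suppression — is available as
`mode = "ga-vs-sa"`; both are documented because the assay literature
states the contrast ambiguously, and neither mode is asserted to be the
only valid reading.

## Repeated-measures inference

`rm_anova_two_way()` implements the classical univariate within-subject
decomposition for complete balanced subject × time × band designs: each
main effect and the interaction is tested against its own
subject-by-effect error stratum.  Sphericity is assessed per effect by
Mauchly's test on the effect's orthonormalised contrast scores (for the
interaction, the Kronecker product of the two factors' contrasts), using
the Box chi-square approximation with the second-order correction term —
the same approximation as `stats::mauchly.test`, with which the tests
agree to machine precision.  Effects failing Mauchly at p < 0.05
(configurable) get Greenhouse–Geisser-scaled degrees of freedom, with
$\hat\varepsilon = (\mathrm{tr}\,S)^2 / (d\,\mathrm{tr}\,S^2)$ bounded
into $[1/d, 1]$.  Huynh–Feldt correction and unbalanced designs are out
of scope.  Follow-up paired t-tests are adjusted with
`bonferroni_adjust()`, whose family size is explicit (six bands for gap
analyses, eight non-zero shifts for FD) because the battery reports
subsets of families.

## What the synthetic cohort emulates

The simulator exists so every stage runs, and is testable, without
animal data.  It generates, per mouse and timepoint, seeded trial
schedules and per-trial quantities with the statistical structure the
analysis assumes:

* **Amplitudes** are lognormal with configurable CV (startle amplitudes
  are positive and right-skewed; the assay literature specifies no noise
  model, so this is a package choice).  The trial-level CV defaults to
  0.2, a typical session-to-session variability for platform startle
  measures.
* **Stable individual traits.** Each mouse's startle scale and
  psychometric slope are drawn once per cohort (lognormal, CVs 0.25 and
  0.12) and held fixed across timepoints.  This matters for the 1-SD
  bootstrap rule: the rule presumes that the baseline bootstrap spread
  is dominated by persistent between-animal differences, against which
  the between-timepoint wobble of a stable group is small.  A generator
  without stable traits makes control groups trip the rule at a high
  rate for purely statistical reasons.
* **Tinnitus** is a multiplicative reduction of gap inhibition per band
  ("gap-filling"): effective inhibition =
  `gap_inhibition × (1 − tinnitus_effect)`, active from a configurable
  onset timepoint (default week 4).  Defaults: baseline inhibition 0.65
  in every band, effect 0.8 in the broadband and two highest bands —
  the bands in which exposure-induced deficits concentrate.
* **Post-exposure FD impairment** is a change of the logistic
  parameters, by default a halved slope (`c_scale = 0.5`, doubling the
  threshold) at weeks 4 and 8 for true-tinnitus mice in both tasks, and
  a milder transient mid-frequency change (`c_scale = 0.7`, week 4
  only) for exposed mice without tinnitus.
* **Movement artifacts** occur with per-trial probability 0.05 and
  inflate the pre-startle noise SD threefold, exercising the exclusion
  rule.
* **ABR thresholds** are generated directly as numbers on the
  10–80 dB/10 dB grid with a sustained +20 dB shift at 28 kHz in exposed
  mice — no evoked-potential waveforms are synthesised.
* **Traces** (`simulate_trace()`) are Gaussian baseline noise plus a
  trapezoidal startle transient (20 ms rise, 60 ms plateau, 20 ms fall)
  whose plateau equals the latent amplitude, so noiseless traces
  round-trip exactly through amplitude extraction, both directly and
  after block-mean decimation.  Simulated traces are emitted at the
  analysis rate (1 kHz default); the 100× block-mean decimation step is
  modelled separately as `downsample_trace()`, standing for the
  raw-acquisition reduction whose original rate the protocol leaves
  unstated.

The default cohort mirrors the targeted study design: 6 controls, 22
exposed of which 14 truly develop tinnitus, timepoints baseline/1/4/8
weeks, three gap sessions per timepoint (baselines in this assay family
are averaged over three sessions) and one session per FD task.

What the generator does **not** emulate: habituation and drift within a
session, hearing-loss-induced amplitude changes, correlated trial-level
noise, or any cochlear/neural mechanism.  Passing tests therefore show
that the pipeline recovers the structure it assumes, not that real data
satisfy those assumptions.

## Numerical and design choices

* The 40 ms gap is placed with its *onset* 100 ms before startle onset
  (the literal reading of "presented 100 ms prior"); the alternative
  offset-aligned reading would shift it by 40 ms and is noted as an open
  interpretation.
* 120 prepulse trials cannot divide evenly over 9 frequencies; counts
  are 13 or 14, with the three 14-trial frequencies fixed by list
  position (not seeded) so the trial multiset is identical across
  seeds.
* The peak-search window for the ASR amplitude is `(onset,
  onset + 550 ms]`, excluding the onset sample, which belongs to the
  baseline window `[onset − 500 ms, onset)`.
* Times are stored in seconds, frequencies in kHz; sound levels are
  carried as metadata only — no acoustics are modelled.
* All randomness flows through named integer seeds (`with_seed`
  internally saves and restores the global RNG state); cohorts, traces
  and bootstraps are byte-reproducible from `(config, seed)`.
* Degenerate cases are explicit: zero-variance paired differences are
  flagged rather than producing NaN t-statistics; a zero SA mean leaves
  inhibition `NA` with a warning; an absent or zero `ASRnopps` is an
  error because PPI cannot be normalised.

## Problem sizes used in the shipped checks

The package's own test suite exercises: 200 single-session threshold
recoveries at trial CV 0.15 (median relative threshold error is required
≤ 10%); classifier operating characteristics over 200 null and 100
affected simulated mice (size ≤ α plus two Monte-Carlo SEs; sensitivity
≥ 90%); a study-scale cohort (28 mice, 4 timepoints) for the end-to-end
partition and ANOVA degrees of freedom; and bootstrap comparisons at 300
draws in tests (1000 remains the analysis default in `run_pipeline()`).

## Known limitations

* The RM-ANOVA requires complete balanced designs; mice lost to
  follow-up must be dropped or imputed upstream.
* The 1-SD bootstrap rule is a heuristic with no controlled error rate;
  it is reproduced for fidelity, not endorsed as inference.
* Group-pooled bootstraps (as used for the threshold figures) treat the
  between-mouse spread as the resampling noise; a per-mouse bootstrap
  mode is available through `bootstrap_thresholds()` on per-mouse
  points.
* XLSX datasets are read-only (and only when `readxl` is installed);
  the canonical interchange format is the CSV directory written by
  `write_dataset()`.
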