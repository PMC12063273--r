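---
title: "Propulsion metrics and symmetry from split-belt treadmill gait: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propulsion metrics and symmetry from split-belt treadmill gait: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

propulsr reimplements a complete propulsion analysis for hemiparetic and
healthy treadmill gait: from per-plate anteroposterior ground reaction
force (AP-GRF) and foot-marker signals to per-step propulsion peak and
impulse, propulsion symmetry, and linear mixed models of gait speed on
those outcomes. Because the study population's raw recordings are not
available, the package pairs the pipeline with a synthetic gait-data
generator whose parameters are the study's published estimates; every
analysis step can then be validated by parameter recovery against known
ground truth.

## Signal conditioning

Force plates sample at 1000 Hz, motion capture at 100 Hz. Each condition
is trimmed by 10 s at the start and 5 s at the end to isolate steady-state
gait, then all channels (force and marker alike) are low-pass filtered with
a second-order Butterworth at 15 Hz applied forward and backward. We read
"second-order zero-phase" as a second-order design run in both directions —
the standard biomechanics convention — giving an effective fourth-order
magnitude response and zero group delay. The implementation initialises the
filter at steady state and extends the signal by odd reflection before
filtering, so constants pass exactly and edge transients stay confined to
the discarded extensions. Force is then resampled to 100 Hz by decimation;
the 15 Hz filter already acts as the anti-alias stage, so no further
filtering is applied.

Two ordering choices are not fixed by the source description and are made
here once: trimming precedes filtering (start/stop transients never enter
the filter), and filtering precedes resampling. Both choices only affect
samples within about a second of the condition boundaries; since at least
5 s is always trimmed, extracted metrics are identical under either order
(the test suite asserts the commutation property away from the edges).

## Gait events and step exclusion

Stance phases are estimated from foot markers alone: initial contact (IC)
is the forward extremum of the heel marker's AP position relative to the
pelvis reference, terminal contact (TC) the backward extremum of the toe
marker, the standard kinematic event detector for treadmill gait. The
detector enforces a minimum peak separation of 0.4 expected stride times
(stride time from a nominal cadence model, 60 + 40·speed steps/min) and a
prominence guard (an extremum must reach the upper 40% of the trajectory's
range) so that numerical ripple in flat stretches is never an event.
Events must alternate IC, TC per leg; stance intervals are half-open
`[ic, tc)`; stances shorter than 0.2 s or longer than 2.5 s are flagged
implausible; stances touching the trimmed-window boundary are flagged
edge-invalid rather than truncated.

A step is a crossover — invalid for per-plate force attribution — if at any
sample during the stance the contralateral foot's heel or toe ML coordinate
lies on or across the belt midline towards the stance side (the boundary
counts: "partially placed" includes touching the midline). The midline and
belt geometry are configuration, defaulting to a midline at ML = 0 with
the left belt at negative ML.

Per condition and leg, at least 23 valid steps are required; a condition
failing that on either leg is dropped, and a participant with two or more
failing conditions is excluded entirely. Steps invalid for event-level
reasons (crossover, edge) and steps with no propulsive lobe both count
against the 23-step threshold — the stricter reading, since the source
does not separate the two.

## Propulsion peak, window, and impulse

Within a stance the propulsion peak is the maximum of the positive
(anterior) AP-GRF; ties resolve to the latest index because propulsion
occurs in late stance. The propulsion window is bounded by the
zero-crossings enclosing the propulsive region, with two refinements for
atypical curves: an interior negative dip separating two propulsive lobes
is bridged and its area subtracts from the impulse, while a trailing (or
leading) negative lobe with no propulsive signal beyond it is excluded.
Bridging is implemented symmetrically around the peak via lobe
connectivity, with two numerical guards: a positive excursion below 1% of
the peak never counts as a lobe (filter ripple), and a dip deeper than 50%
of the peak is never bridged (the early-stance braking lobe is never
absorbed into the window). Zero-crossings are sign changes between adjacent
samples — no sub-sample interpolation, since the 100 Hz trapezoid already
reproduces closed-form lobe areas to well under 0.5%.

The impulse is the signed trapezoidal integral over the window, extended by
one bounding sample on each side so the near-zero crossing samples
contribute their slivers. Peak and impulse are divided by body mass in kg
(units N/kg and N/kg·s; "corrected for body weight" with weight in newtons
would produce different printed units). Per-step metrics are averaged over
valid steps per condition and leg.

## Symmetry and the observation table

Propulsion symmetry is the paretic leg's share of total propulsion,
`paretic / (paretic + non-paretic)`, computed per condition for peak and
impulse; controls use the left leg as numerator. The value is carried as a
fraction throughout modelling — the control-model intercepts are printed on
the fraction scale (0.50, 0.51) in the source, which pins the modelling
scale — and rendered as a percentage only in displays. The
symmetry-at-comfortable-walking-speed covariate is the observed symmetry of
the CWS condition (not a model-based estimate — the simplest reading of the
source; a BLUP-based alternative is noted but not implemented), broadcast
to all of a participant's rows. Participants whose CWS condition is missing
or excluded drop out of the symmetry models only; their per-leg rows remain.

## Mixed models

All models are REML fits (lme4) with participant as the grouping factor;
covariates enter uncentered, speed in m/s:

* Symmetry (stroke): `sym ~ speed * sym_cws + (1 + speed | participant)`.
  The `sym_cws` main effect is estimated but marked not-reported — with
  uncentered covariates it has no meaningful interpretation; the
  interaction carries the question of whether the speed effect depends on
  baseline asymmetry.
* Symmetry (control): `sym ~ speed + (1 + speed | participant)`.
* Per-leg propulsion (stroke): `y ~ speed * leg + (1 + speed * leg |
  participant)` with the non-paretic leg as reference (the printed negative
  paretic effects fix this coding). If the speed-by-leg interaction is
  significant at 0.05, two per-leg post-hoc models
  (`y ~ speed + (1 + speed | participant)`) provide the per-leg slopes.
* Control propulsion: `y ~ speed + (1 + speed | participant)`, pooling the
  exchangeable legs.

Degrees of freedom use the Kenward-Roger correction (pbkrtest) by default,
with Satterthwaite and a no-df fast path (for Monte-Carlo loops, where only
estimates are needed) as options; estimates and SEs are invariant to that
choice. The rich per-leg random structure is frequently singular at n = 15
— expected and benign for the fixed-effect estimates — and is flagged in
every fit object rather than silently accepted; a structure-reduction
ladder is deliberately not applied unless the optimizer fails outright.
No multiple-testing correction is applied anywhere; the 0.05 level gates
only the post-hoc decision rule. Diagnostics (Q-Q quantile pairs, residual
histogram material, residuals vs fitted, a Shapiro-Wilk summary) are
computed per fit.

## The synthetic generator

The generator is first-class, tested code, and its defaults are the study
conditions. Cohorts: 15 stroke participants (comfortable walking speed
0.71 ± 0.18 m/s truncated to [0.5, 1.1] and rounded to the 0.1 m/s
treadmill grid; body mass log-normal, median 80 kg with sigma matched to
the published IQR) and 16 controls (CWS 1.25 ± 0.12 m/s — unreported for
the young control cohort, set to a typical young-adult value; mass median
68 kg). Schedules follow the acquisition protocol: stroke participants
walk 0.2 m/s up to CWS in 0.2 m/s increments (randomized), then +0.1 m/s
steps to CWS + 0.4 m/s (the margin is unreported; 0.4 yields the typical
eight conditions); controls walk 0.4-1.6 m/s in 0.2 m/s increments plus a
CWS condition — eight conditions in total. Conditions at or below 0.4 m/s
last 3 min, faster ones 2 min.

Per metric (peak, impulse) and participant, condition means follow the
generative mixed model `intercept + slope·v + leg·(leg_effect +
interaction·v)` plus Gaussian latents (intercept, slope, leg, and
speed-by-leg deviations) with the published SDs, a condition-level
residual, and 10% between-step noise (between-step variability is
unreported; 10% CV is typical of per-step force metrics). Negative draws
are floored at a small positive value, and a physical-consistency cap
bounds each step's impulse at 0.85 × peak × stance duration (no curve can
integrate to more than its peak times its support); capped and floored
draws are counted in the ground truth. Step counts come from the cadence
model and the usable (trimmed) duration; a configured fraction of steps is
flagged as crossovers.

Three latent correlations complete the parameterization. The peak
slope-interaction correlation (-0.68) is forced in closed form by the three
published peak SDs (slope 0.43, interaction 0.57, paretic post-hoc slope
0.42). The cross-metric source correlation (0.8) expresses that the same
limb impairment drives both metrics; it leaves each metric's marginal
distribution untouched and exists to keep the joint peak/impulse draws
physically coherent. The impulse leg-interaction correlation (-0.72) is the
generator's calibration device: the symmetry models' coefficients are not
injected anywhere — symmetry is always derived from the generated per-leg
values — so the published symmetry-model estimates act as calibration
targets. A more negative leg deficit steepening the impulse gain is exactly
the study's own finding (faster walking helps most where asymmetry at CWS
is largest). The correlation and the unprinted per-leg intercepts (0.226
peak, 0.25 impulse, placing cohort-mean CWS symmetry near 0.40) were fixed
by one calibration sweep against the emergent symmetry-model coefficients
and then frozen in `inst/extdata/params_study.yaml`; every value in that
file carries a provenance tag.

In waveform mode each stance is rendered at 1000 Hz as a braking half-sine
followed by a propulsive lobe whose amplitude and duration solve the
step's peak and impulse exactly (half-sine area 2AT/pi; when the required
half-sine is wider than the stance allows, the lobe flattens into a
quarter-sine/plateau/quarter-sine of the same peak and area). Heel and toe
markers move backward at belt speed during stance and return along a
half-cosine during swing, so the pelvis-relative extrema encode the
injected IC/TC times; ML coordinates place feet on their own belts except
during injected crossover steps. Interior dips and trailing lobes are
injectable for window-rule testing. What the generator does not emulate:
double-support force exchange between plates, vertical-force dynamics
(a constant stance plateau only), marker noise and dropouts, fatigue
drift, or any non-Gaussian step-to-step structure. Passing recovery tests
therefore validates the pipeline's arithmetic and the models' estimation
properties on data satisfying the stated assumptions — not robustness to
real-world artefacts.

## Validation strategy and problem sizes

Because no empirical dataset exists to re-analyse, the package's tests are
organised around three oracles: closed forms (half-sine areas, the
analytic Butterworth magnitude), ground-truth injection (event times,
per-step metrics, crossover lists), and parameter recovery (50 replicates
at the study's cohort sizes must return each generative fixed effect
within twice its published SE in at least 90% of replicates, and
Monte-Carlo means at n = 200 participants must converge to injected values
within 5% or the Monte-Carlo resolution, whichever is larger). The type-I
calibration of the post-hoc decision rule is checked over 100 null
replicates. These replicate counts keep the default suite within a few
minutes on one core while leaving the binomial pass probabilities
comfortably high; `scripts/acceptance.R` reruns the recovery at 50
replicates from a user seed.

## Known limitations

* The C3D support is a deliberate subset (Intel, floating-point, the
  package's own label conventions) sufficient for interchange of the
  package's recordings; it is not a general C3D parser.
* The stance-estimation reference method behind the source analysis is not
  fully specified there; the pelvis-relative extremum detector implemented
  here is the field's standard, but parameter choices (separation factor,
  prominence) are this package's own and are configuration-exposed.
* The published control impulse model is internally inconsistent (its SE
  and t statistic disagree by an order of magnitude); the generator uses
  the point estimate and the separately published random-slope SD and
  makes no attempt to resolve the inconsistency.
* The published peak-symmetry interaction row has the same defect
  (estimate/SE inconsistent with its t); nothing in the generator depends
  on it, since symmetry-model coefficients are emergent.
* Real hemiparetic gait departs from the generator's assumptions in ways
  listed above; recovery results quantify pipeline correctness, not
  clinical generalisability.
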