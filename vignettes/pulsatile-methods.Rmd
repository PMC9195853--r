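---
title: "Models and methods behind pulsatile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulsatile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsatile)
library(dplyr)
```

`pulsatile` implements the computational machinery of a yes/no
change-detection experiment with pulsatile vibrotactile skin indentations:
stimulus synthesis, kinematic intensity measures, psychometric mixture-model
fitting, synthetic observers, and the downstream threshold analyses. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the simulations do and do not establish.

## The stimuli

Every stimulus is a pulse train: brief indentations separated by rest at a
static base indentation of 1 mm. A single pulse is one period of a raised
cosine,

$$p(t) = A\,\bigl(1 - \cos 2\pi f t\bigr), \qquad t \in [0, 1/f],$$

where $f$ is the *waveform frequency* of the sinusoid the pulse is cut from
and $A$ its amplitude. The pulse starts and ends at the base (a sinusoid
"starting from one minimum and ending at the next", offset so the minimum
sits at the base), its width is the period $1/f$, and its peak excursion is
$2A$. The reference stimulus throughout is a 500 ms train at a 90 Hz pulse
rate built from $f = 170$ Hz, $A = 40\ \mu m$ pulses, sampled at 40 kHz —
pulse width $1000/170 = 5.882$ ms. Shape-change comparisons raise $f$ to
175–240 Hz in 5 Hz steps (width shrinking to $1000/240 = 4.167$ ms); rate
changes raise the pulse rate to 95–135 Hz with the pulse unchanged.

We read "an amplitude of 40 microns" as the sinusoid amplitude $A$, making
the peak excursion $2A = 80\ \mu m$; the alternative reading (total excursion
40 µm, $A = 20$) is available by passing a different `amplitude_um`. Nothing
downstream depends on which reading is used, because every analysis is
invariant to a common amplitude scale.

Discretisation conventions: a pulse occupies `floor(fs / f)` samples and its
final sample is the first rest sample (exactly zero). This guarantees that
pulses never overlap at the highest admissible rate (the design requires
`pulse_rate <= f`, satisfied by all stimuli here: $90\text{–}135 \le 170$),
at the cost of truncating the pulse by less than one sample. Pulse $k$
(0-based) starts at time $k/\text{rate}$, rounded to the sample grid. A train
of duration $D$ holds `floor(rate * D)` pulses.

## Session schedules

Sessions follow the method of constant stimuli. Each change level is
presented 30 times and an equal number of no-change trials (comparison
identical to reference) is added, so exactly half the trials are no-change.
With 14 shape levels this gives $14 \times 30 + 420 = 840$ trials in three
blocks of 280; with 9 rate levels, $9 \times 30 + 270 = 540$ trials in three
blocks of 180. These totals are only consistent with the change-level sets
*excluding* the reference value, which is how `change_levels()` is defined.
Within each block every level appears equally often and the order is a
seeded uniform permutation; 20 practice trials (10 change, 10 no-change) can
be prepended, flagged, and are excluded from analysis. Per-block level
balance is our choice of the most even realisation of the fixed per-block
totals; any schedule with the same totals works identically downstream.

## Kinematic intensity formulations

Six "temporally global" intensity formulations are computed over the entire
stimulus (rest included — the averaging window is the full 500 ms):
$\overline{|v|}$ (mean speed), $\overline{v^2}$, $\overline{|v|^3}$,
$\overline{|a|}$, $\overline{a^2}$, $\overline{|a|^3}$, with $v$ and $a$ the
velocity and acceleration of the indentation trajectory. Derivatives are
central differences (one-sided at the ends), applied to the commanded
waveform (measured, calibrated actuator trajectories would require hardware
data and are out of scope). The
discretisation error is bounded by closed forms: one pulse has path length
$4A$, so $\overline{|v|} = 4An/D$ for $n$ pulses, and
$\int v^2 = (2\pi f A)^2/2f$ per pulse, so
$\overline{v^2} = 2\pi^2 f A^2 n / D$. At 40 kHz the sampled values agree
with these to well under 1%, and the error falls as the sampling rate grows.

The central property of the stimulus design is that the shape-change family
lies on an *iso-feature line* of mean speed: pulses get narrower but the path
length per pulse stays $4A$ and the pulse count stays fixed, so
$\overline{|v|}$ is constant across 170–240 Hz (relative deviation
$< 0.5\%$; discretisation of pulse boundaries prevents exact equality, and
0.5% is our tolerance for calling an axis constant). All other formulations
grow with $f$. Rate changes move every formulation, including mean speed
(linearly: $4Ar/D$ at fixed pulse shape). `intensity()` exposes the time-mean
as the canonical statistic; a "summed" variant (mean × sample count) is
available and differs only by a constant factor, which cancels in all
within-design comparisons.

## The psychometric model and its fitting

The probability of reporting a change at stimulus level $x$ is the mixture

$$P(x; m, w, \gamma, \delta) = \gamma + (1 - \delta - \gamma)\,S(x; m, w),$$

with $S$ a cumulative Gaussian (optionally logistic), $m$ the level at which
$S = 0.5$, $w$ the width over which $S$ rises from 0.05 to 0.95, $\gamma$
the false-alarm rate (lower asymptote) and $\delta$ the lapse rate (upper
asymptote shortfall). The width definition fixes the Gaussian scale at
$\sigma = w / (2\,\Phi^{-1}(0.95)) = w/3.2897$ and the logistic scale at
$w / (2 \ln 19)$.

Fitting is bounded multistart maximum likelihood. (This model family is what
the psignifit toolbox fits; `pulsatile` implements the same mixture model and
exclusion rules with ML point estimation rather than psignifit's Bayesian
machinery, which is deliberately out of scope.) Choices:

* **Bounds.** $m$ within the tested range extended by the width cap on both
  sides; $w \in (0, 2 \times \text{span}]$; $\gamma, \delta \in [0, 0.1]$ by
  default (a psignifit-like lapse cap, configurable). These are conventional
  defaults, not estimates.
* **Starts.** 16 Latin-hypercube points over the box (seeded) plus one
  moment-based start; each refined with `L-BFGS-B`; best negative
  log-likelihood wins, ties broken by smaller $w$.
* **Clamping.** Predicted probabilities are clamped to
  $[10^{-9}, 1 - 10^{-9}]$ inside the likelihood so saturated data stay
  finite.
* **No-change trials.** Their "yes" proportion is the empirical false-alarm
  rate. By default they enter the fit as a data point at the reference level
  with $\gamma$ free (`gamma_mode = "reference_point"`); alternatively
  $\gamma$ can be fixed at the empirical rate (`"fixed"`) or the no-change
  trials ignored. Both conventions are implemented and tested; the default
  keeps the most information in the likelihood.

**Validity and thresholds.** A fit is valid only if the *false-alarm
corrected* curve $(P(x) - \gamma)/(1 - \gamma)$ (the standard high-threshold
correction; the correction family offers several variants and this is the
common one) crosses 0.5 strictly inside the tested range. Fits whose
corrected curve never reaches 0.5 are flagged `did_not_reach_half`; fits
whose crossing sits on a range limit (within $10^{-3}$ of the span) are
`threshold_on_limit`. The threshold is the corrected 0.5 crossing, found by
monotone root-finding. Algebraically the corrected curve crosses 0.5 where
$S = \tfrac{1}{2}(1-\gamma)/(1-\delta-\gamma)$: with $\delta = 0$ the
correction cancels and the threshold equals $m$ for any $\gamma$; a positive
lapse rate shifts it above $m$. Thresholds are reported on the native axis
(waveform frequency for shape, pulse rate for rate) and as percent change —
width-based for shape, $100(1 - 170/f^*)$, and rate-based for rate,
$100(r^* - 90)/90$.

## Synthetic observers

No per-trial human data are deposited, so the pipeline is exercised on
parametric observers. An observer codes stimuli on a single axis — pulse
width (ms), pulse rate (Hz), or one of the six intensities — and detects a
change with probability given by its own psychometric mixture evaluated at
the absolute axis difference between comparison and reference; on no-change
trials it responds "yes" at rate $\gamma$. This embodies the hypothesis space
the experiment was designed to separate: a pulse-width coder is blind to rate
changes (its axis is constant there) and responds at $\gamma$ throughout,
yielding no valid psychometric function — exactly the exclusion pattern that
separates shape and rate performance; a mean-speed coder is likewise blind to
shape changes.

Working-memory degradation in gap sessions is modelled as a multiplicative
inflation of the width, $w' = w \times \text{inflation}$, inflation $\ge 1$.
This is the simplest mechanism that can represent both lossless storage
(inflation = 1, the null hypothesis of the gap comparison) and graded
degradation; nothing in the pipeline depends on this particular mechanism
choice. Lapses by default only cap
the upper asymptote, matching the fitted model; an optional "full lapse"
mode flips responses with probability $\delta$ on both trial types.

Cohorts draw per-participant $m$ and $w$ from normal distributions
(truncated at a tenth of their mean to stay positive) with common $\gamma$,
$\delta$ and inflation; each participant runs the four sessions
(shape/rate × gap/no-gap) with session order counterbalanced over the 24
permutations, assigned cyclically. The default population —
pulse-width coders with $m = 0.9 \pm 0.25$ ms, $w = 0.9 \pm 0.2$ ms,
$\gamma = 0.06$, $\delta = 0.02$, inflation 1 — was chosen once as a
realistic competent population: thresholds near the middle of the
achievable width-difference range (0–1.7 ms), false-alarm and lapse rates
typical of practised psychophysical observers, and lossless storage
matching the null structure of the gap comparison. Population parameters
are free simulation inputs, not estimates of any real cohort.

## The analysis chain

`fit_cohort()` aggregates a response table per participant × condition ×
gap, fits each cell, applies the validity rules and converts thresholds.
`validity_census()` counts valid fits (and records participants invalid on
no-gap shape, the pre-analysis exclusion bookkeeping).
`compare_gap_nogap()` takes participants valid in *both* members of a
gap/no-gap pair — the paired design forces this — and reports the paired
t-test, the Pearson correlation of the paired thresholds, and an effect size
labelled `auc`: the probability of superiority, the proportion of pairs in
which the gap threshold exceeds the no-gap threshold with ties counted one
half. Probability of superiority is the natural ROC-type effect size on
paired data; the label and its definition are recorded in the run manifest
so downstream readers never have to guess. No multiple-testing correction is
applied (raw p-values are reported).

`rescale_to_intensity()` re-expresses a condition's levels on one of the six
intensity axes (synthesising the comparison train per level) and refits with
a logistic sigmoid on that axis. An axis whose relative span across levels is
below 0.5% is degenerate — mean speed under shape changes, by construction —
and the fit is skipped with an explicit flag rather than attempted. Pooling
trials across participants is the default (`mode = "pooled"`);
per-participant fits averaged afterwards are available
(`mode = "individual"`). Pooled curves weight prolific responders more;
averaged individual fits weight participants equally — choose per question.

## Calibration simulations and their scale

Two simulation harnesses quantify the pipeline's statistical behaviour, at
sizes chosen to give stable estimates at desk scale:

* `recovery_simulation()`: 200 replicates of the shape design (14 levels ×
  30 trials) from a known generator ($m = 205$, $w = 40$, $\gamma = 0.1$,
  $\delta = 0.02$); the median absolute error of $\hat m$ is a few Hz, well
  under $w/4 = 10$ Hz, and shrinks further at 300 trials per level.
* `type1_simulation()`: 200 replicate cohorts of 8 width-coding observers
  with inflation = 1 (true null), full shape sessions fitted (8 multistarts)
  and compared; the paired t-test rejects at the nominal 5% rate to within
  binomial error.

```{r calibration, eval = FALSE}
rec <- recovery_simulation(200, seed = 1)
median(abs(rec$m_hat - 205))

sims <- type1_simulation(200, n_participants = 8, seed = 1)
mean(sims$p_value < 0.05)
```

(Not evaluated here — together these take a few minutes; run them directly
or via `scripts/acceptance.R`.)

## What the simulations do and do not show

The synthetic observers share the fitted model's functional form, so
parameter recovery shows the estimation chain is consistent and calibrated —
not that the model is true of human observers. Real data bring
sequential dependencies (feedback-driven criterion shifts), attention
lapses correlated in time, fatigue across blocks and inter-individual
variation in the coding axis itself, none of which the generator emulates.
The generator also treats the coding axis as exactly one-dimensional;
humans may mix cues. Passing tests therefore validate the software and the
statistical machinery, and demonstrate that the design separates local
(pulse-width) from global (rate/intensity) coders; they say nothing new
about tactile memory.

## Known limitations

* ML point estimates only: no Bayesian posteriors or credible intervals, and
  goodness-of-fit checking is limited to the validity rules.
* The 12-bit DAC quantisation of the physical stimulator is noted but not
  modelled; waveforms are ideal commanded trajectories.
* Intensity formulations are kinematic; dynamic (force/stress) formulations
  are out of scope.
* `threshold_on_limit` uses a fixed relative tolerance ($10^{-3}$ of the
  span); fits whose threshold sits within that sliver of the boundary are
  conservatively invalid.
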