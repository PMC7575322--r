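---
title: "Detecting monosynaptic pyramidal-interneuron connections and tracking their transmission probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting monosynaptic pyramidal-interneuron connections and tracking their transmission probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoconn)
```

## The problem

In extracellular recordings from hippocampal CA1, a pyramidal cell that makes
a monosynaptic excitatory contact onto an interneuron leaves a characteristic
fingerprint in the spike-time cross-correlogram (CCG) of the pair: a large,
sharp peak at 0.5–2.5 ms after the pyramidal (reference) spike, reflecting the
short conduction and synaptic delay of a single synapse. The height of that
peak, above what joint firing rates alone would produce, is the
*spike-transmission probability*: the excess probability that one presynaptic
spike discharges the postsynaptic interneuron. It is a physiologically
interpretable proxy for connection weight, and tracking it across behavioural
sessions (familiar environment, novel environment, familiar environment with
optogenetic perturbation, familiar again) asks whether network perturbations
leave lasting traces in synaptic coupling.

`monoconn` implements the full chain: CCG construction, peak detection,
chance correction, quality control, per-session metrics, and the mixed-model
statistical layer — plus a synthetic generator that plants connections with
known parameters so that every stage can be validated against ground truth.

## The correlogram and the detection statistic

For a reference train $A$ (pyramidal) and target train $B$ (interneuron), all
spike pairs are histogrammed by lag $t_B - t_A$ into 101 bins of 1 ms,
centred on integer lags $-50 \dots +50$ ms, with bin edges at half-integer
milliseconds. This lattice is chosen deliberately: the monosynaptic
0.5–2.5 ms latency window is then *exactly* the two bins centred at +1 and
+2 ms, so no partial-bin bookkeeping is needed. Bins are half-open
$[c - 0.5, c + 0.5)$ ms; a zero-lag coincidence of two distinct cells sits in
the 0-bin, and self-pairs are excluded only for autocorrelograms.

Because reference spike counts vary across cells and sessions, raw counts are
normalised per reference spike:

$$P(\tau) = \frac{\mathrm{count}(\tau)}{N_{\mathrm{ref}}}.$$

**Chance level.** Two cells firing independently at rates $r_A, r_B$ produce
an expected flat CCG with $P \approx r_B \Delta$ per bin (bin width
$\Delta = 1$ ms), regardless of $r_A$. The chance level is estimated
empirically as the mean of $P(\tau)$ over the 82 flank bins
$|\tau| \in [10, 50]$ ms — far enough from the peak to exclude monosynaptic
structure, near enough to track slow co-modulation.

**Detection.** The peak statistic is

$$z = \frac{\max(\mathrm{count}_{+1}, \mathrm{count}_{+2}) - \bar{c}_{\mathrm{flank}}}{\mathrm{SD}(c_{\mathrm{flank}})},$$

computed on raw counts over the flank bins, and a pair is significant when
$z \ge 3$ (three standard deviations above baseline). The max over the two
peak bins is used because a genuine 1–2 ms-wide peak may concentrate in
either lattice bin depending on latency; the baseline SD comes from the same
flank region as the chance mean so the two estimates are consistent. When
the flank SD is zero (pathologically sparse histograms) detection is
undefined and reported as not significant with a flag.

**Transmission probability.** For quantification (as opposed to detection),

$$p_{\mathrm{trans}} = \sum_{\tau \in \{+1, +2\}} \left( P(\tau) - \hat{c} \right),$$

i.e. extra postsynaptic spikes per presynaptic spike in the monosynaptic
window. Chance subtraction makes the statistic rate-compensated: doubling
both firing rates of an unconnected pair leaves its expectation at zero (a
property the test suite checks directly). Estimates for weak or unconnected
pairs can be slightly negative; these are sampling noise around zero and are
deliberately *not* clamped, because clamping would bias session averages
upward. Detection runs on the CCG accumulated over the whole set of
exploration sessions (maximum statistical power, one decision per pair);
per-session CCGs are used only to quantify transmission. The REST session is
excluded from the detection histogram so pulse-locked firing cannot shape
it.

**Quality filters.** Sparse or irregular histograms are removed: a pair is
kept only if FAM1 or FAM2 contributes at least 1000 coincidence counts in
the ±50 ms window *and*, in a qualifying session, the SD of the bin values
is below one third of their mean. The dispersion criterion is evaluated on
the flank bins by default — evaluated over all 101 bins, a strong genuine
peak could fail its own quality filter, which would systematically discard
the strongest connections. Because the choice is a judgement call, the
all-bins variant remains available via `dispersion_on = "all"`.

## Session metrics

*Rates* are spikes per second within each session interval. *Change scores*
between sessions use the bounded normalised difference

$$c = \frac{r_2 - r_1}{r_2 + r_1} \in [-1, 1],$$

applied identically to rates, transmission probabilities and pairing counts;
$\pm 1$ means activity exclusive to one session, and the score is undefined
(missing) when both values are zero. Transmission values are floored at zero
before the score so its bounds survive small negative estimates.

*Split-half baseline.* Within-session stability is measured by splitting a
session into alternating 5 s blocks (odd- vs even-numbered from session
start, trailing partial block dropped), computing the metric on each
interleaved half, and correlating the halves across pairs. This is the
ceiling against which cross-session correlations are compared with the
Fisher Z-test
$Z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$.
Block-straddling spike pairs are not counted in the split-half CCGs; at 5 s
blocks and ±50 ms lags this loses ~1% of pairs symmetrically in both halves.

*Pairing events* count, per direction, spike pairs whose lag falls within a
window $W \in \{10, 20, 50, 100\}$ ms: `count_dir_plus` counts pyramidal
spikes preceding the interneuron spike ($0 < t_{int} - t_{pyr} \le W$),
`count_dir_minus` the reverse, and `count_all` their sum. Exact zero-lag
ties are directionless and counted in neither; both directions and the sum
are always reported, so either sign convention can be read off. For
independent Poisson trains $E[\mathrm{count\_all}] = 2 W r_1 r_2 T$, which
is why pairing counts are largely explained by the two rates and must be
adjusted for them before being interpreted as coupling.

## The statistical layer

All population-level inference runs on the tidy pair-session table, with the
animal as a random intercept — pairs recorded in the same animal share
electrode placement, behavioural idiosyncrasies and transgene expression, so
treating them as independent would overstate the evidence.

- `fit_lmm()` fits `response ~ predictors + (1 | animal_id)` via `lme4`,
  with Satterthwaite t/F tests (`lmerTest`) for per-coefficient inference.
  Rows with missing values in used columns are dropped listwise with a
  logged count (the most defensible default when per-session metrics can be
  individually missing).
- `model_comparison()` answers "does X predict the response *independently*
  of Y": the full ML model is compared against the model dropping one
  predictor, on identical rows, with a likelihood-ratio test. The
  likelihood-ratio form is the standard way to compare nested mixed models
  and is what "mixed model comparison" denotes here; the Satterthwaite
  per-coefficient p-values are reported alongside, and for a single
  continuous predictor the two agree closely.
- `lrt_random_effect()` tests the animal variance component by comparing
  the ML mixed model against the plain linear model. A variance is tested
  on its boundary, so the $\chi^2_1$ reference is conservative (the null is
  a 50:50 mixture of a point mass and $\chi^2_1$); the conservative naive
  test is used and documented rather than corrected, and the type-I error
  simulations in the test suite confirm the level is at most nominal.
- `partial_correlation()` residualises both variables on the controls and
  correlates the residuals. When one variable is fully explained by the
  controls the partial correlation is reported as 0 (there is no residual
  association left); it is missing only when both residuals are constant.
- `holm_bonferroni()` applies the step-down correction across the pairing
  windows; `fisher_z_compare()`, `mann_whitney()` and `r2_with_ci()` (with a
  seeded nonparametric bootstrap percentile interval) complete the battery.

ML is used for every model entering a likelihood comparison; REML is
available for variance reporting only.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the recording-day structure the method is
designed for: four 25 min (1500 s) exploration sessions FAM1 → NOV → FAML →
FAM2 and an 18 min (1080 s) rest session; pyramidal base rates log-normal
around 1 Hz (≈0.3–3 Hz), interneurons around 12 Hz (≈5–30 Hz); an
animal-level multiplicative rate offset (log-SD 0.1) creating the
across-animal variability the mixed models absorb.

Background activity is homogeneous Poisson per cell per session. A planted
connection converts each presynaptic spike, with the session's transmission
probability, into one extra postsynaptic spike at a truncated-normal latency
(mean 1.4 ms, SD 0.3 ms, truncated to 0.5–2.5 ms so planted peaks land
entirely in the detection window). Transmission spikes are *added* onto the
background rather than replacing background spikes: the detection statistic
assumes an additive peak above a flat chance floor, and this is exactly the
generative model for which the estimator should be unbiased — which the
recovery tests confirm (planted 0.02/0.05/0.10 recovered within ±0.01).
Postsynaptic spikes closer than 0.1 ms are merged, as a stand-in for the
absolute refractory limit.

Optogenetic perturbation is modelled as: during FAML, light epochs
alternating with no-light epochs (10 s epochs, 40% duty cycle — the
footprint of a light zone covering one-third to one-half of the arena); a
configurable fraction of interneurons (default 60%) and pyramidal cells
(default 25%) multiplicatively suppressed (factor 0.3) inside light, and a
fraction of pyramidal cells (default 15%) enhanced (factor 2, the
disinhibition signature). The rest session carries 500 ms test pulses every
3 s; the pulse period is not constrained by the experimental description, so
3 s is a package default exposed in the config. Light-response classes are
recovered from the PSTH (20 ms bins, −0.1 to +0.6 s around pulse onset) by
comparing in-pulse with pre-pulse spike probability at a ±50% threshold.

Deliberately **not** simulated: spatial trajectories and place fields, theta
modulation, bursting, refractory dynamics, and spike-sorting artifacts.
Chance correction only requires that the flanks estimate the joint-rate
floor, so flat Poisson backgrounds are sufficient to validate the statistic;
but passing tests on this generator therefore demonstrate correctness of the
*estimator machinery*, not robustness to place-field co-modulation or
sorting contamination in real data. On real recordings the 10–50 ms flanks
absorb slow co-modulation into the chance estimate, which is precisely the
purpose of that design, but short-timescale common drive (e.g. shared theta
phase) can still widen peaks in ways the generator does not produce.

## Numerical and interface choices

- Spike times are double-precision seconds internally. Klusters `.res`
  files carry integer sample indices at a user-supplied rate (default
  20 kHz); cluster ids 0 and 1 are skipped as noise/artifact clusters (the
  common Klusters convention), overridable via `noise_clusters`.
- Lag binning assigns each pair by direct comparison of the lag against the
  half-integer bin edges, so counts are identical to an all-pairs brute
  force (the test suite asserts exact equality); candidate pairs are located
  by bisection with one-bin slack so the search can never change a bin
  assignment.
- Sessions missing a metric (e.g. zero reference spikes) yield missing
  transmission values, excluded listwise by the model layer with a logged
  count.
- The pair-session table is written with 17 significant digits so CSV round
  trips are bit-stable; missing values are empty fields.
- The full pipeline is deterministic given the config seed; reruns produce
  byte-identical pair tables.

## Problem sizes used in validation

The packaged validation suite runs at desk scale, chosen so the full suite
completes in a couple of minutes while keeping every check statistically
meaningful: exact CCG equivalence on 20 random pairs of up to $10^4$ spikes;
null calibration on 200 independent 1 Hz/15 Hz pairs over 1500 s (≤2% false
positives at 3 SD); sensitivity on 100 planted $p_{\mathrm{trans}} = 0.05$
pairs (≥95% detected); estimator recovery at 0.02/0.05/0.10 over 20 seeds
each (bias < 0.01); change-score recovery across 50 pairs (r ≥ 0.8); and
50-replicate model-comparison logic at 78 pairs across 4 animals, matching
the scale of a realistic dataset.

## Known limitations

- Only excitatory (peak) connections are detected; inhibitory troughs and
  jitter- or convolution-based significance methods are out of scope.
- The 3 SD rule tests the two peak bins against a normal approximation of
  the flank distribution; at very low counts the Poisson skew makes the
  rule slightly anticonservative, which the 1000-count filter exists to
  prevent.
- The chi-square reference for the random-effect test is conservative near
  the boundary; borderline animal-effect p-values should be read
  accordingly.
- With four animals the random-intercept variance is estimated from four
  draws; singular fits are flagged, not suppressed.
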