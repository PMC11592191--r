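---
title: "Boltzmann modeling of potassium conductances in developing cochlear-nucleus neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boltzmann modeling of potassium conductances in developing cochlear-nucleus neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmephys)
library(dplyr)
```

## The scientific problem

Neurons of the avian nucleus magnocellularis (NM) — the bird analogue of the
mammalian anteroventral cochlear nucleus — acquire their hallmark fast,
precise firing during embryonic development largely by up-regulating
voltage-gated potassium channels.  Two channel classes dominate the
steady-state outward current: a low-voltage-activated (LVA, Kv1-like)
conductance that opens near rest, and a high-voltage-activated (HVA,
Kv3-like) conductance that drives fast repolarization.  Neurotrophin
signaling (BDNF acting through TrkB) modulates these conductances early in
development, and the standard way to quantify such effects from whole-cell
voltage-clamp data is to model the activation of each channel class with a
Boltzmann curve and compare the fitted parameters across experimental
groups.

`nmephys` implements that analysis end to end, together with a
conductance-based simulator that generates voltage- and current-clamp sweep
families from known ground-truth channel parameters, so every stage of the
pipeline can be validated against data whose answer is known.

## The model

### From the I-V curve to open probability

Steady-state currents are measured from voltage-clamp families (commands
from $-100$ to $+20$ mV in 5-mV increments, 150 ms) by averaging each sweep
over the 1-ms window beginning 3 ms before command offset, i.e. $[147, 148)$
ms for a 150-ms step.  Command voltages are corrected once for the liquid
junction potential ($-10$ mV for the K-gluconate internal), so the analysis
voltage axis runs from $-110$ to $+10$ mV.  We read the phrase "a 1-ms
average at the end of the command, 3 ms before it ends" as a window that
*begins* 3 ms before offset: it matches the worked example and keeps clear of
the capacitive transient at command offset.

The I-V curve is split into the two channel-class bins on the corrected
axis — LVA $[-60, -25]$ mV and HVA $[-20, +30]$ mV — and the *differential
conductance* is the forward difference between consecutive in-bin points,
reported at the midpoint of each 5-mV increment (pA/mV $=$ nS).  A pair of
points contributes only when both lie inside the bin, so no slope straddles
the gap at $-22.5$ mV, and the midpoints land exactly on the standard
read-out grid ($-42.5$, $-2.5$, $+17.5$ mV).  Dividing by the largest in-bin
slope normalizes the curve to an empirical open probability
$P_O \in [0, 1]$ (per-bin normalization; the two classes are treated as
independent sigmoids).  Occasional negative slopes from recording noise are
clipped to zero for the open-probability curve only and flagged; the raw
slopes are never altered for the current-domain fit.

### The Boltzmann curve and its integral

Each activation curve is fitted with

$$P_O(V) = B + \frac{1 - B}{1 + e^{(V_{50} - V)/K}},$$

where $V_{50}$ is the half-activation voltage, $K > 0$ the slope factor
(mV), and $B$ a baseline open fraction.  For the LVA bin $B$ is fixed at 0;
for the HVA bin it is free in $[0, 1)$ because the HVA bin sits on top of
fully activated LVA conductance, which the baseline term absorbs.

Multiplying by the maximal differential conductance $G_{max}$ and
integrating over voltage gives the closed-form current model fitted directly
to the in-bin raw (V, I) points:

$$I(V) = B\,G_{max}V + G_{max}(1 - B)\,K
  \ln\!\left(e^{V/K} + e^{V_{50}/K}\right) + C,$$

with $C$ an integration constant.  The log-sum term is evaluated as
$\max(V, V_{50}) + K\log(1 + e^{-|V - V_{50}|/K})$, which is exact and
overflow-safe.  The package verifies (as an acceptance test) that this
closed form agrees with trapezoid quadrature of the conductance to within
$10^{-6}$ relative error over $[-100, +30]$ mV, and that its central
difference returns the conductance at all read-out voltages.

The grid has no point at $V = 0$, so a literal "Y-intercept" initialization
for $C$ is not available; $C$ is instead initialized so the model passes
through the lowest-voltage in-bin point and is then co-fitted.  This
preserves its role as the additive offset of the I-V curve while keeping the
fit well posed.

Fits use Levenberg–Marquardt least squares (`minpack.lm`) with box
constraints ($K > 0$, $G_{max} > 0$, $B \in [0, 1)$, $K \le 40$ mV — slope
factors beyond that are physically meaningless and only arise on the
degenerate near-linear ridge).  A data-driven start is tried first and a
small start grid is used as fallback, preferring converged solutions by
residual sum of squares.  When the optimum sits on a rank-deficient ridge
the fit is still reported, with non-finite standard errors and a warning —
never silently accepted.  Group comparisons use the per-neuron fitted
values, matching the one-dot-per-neuron presentation of the source data;
fitting the group-averaged curve is available but not the default.

### Current-clamp features

Active properties come from 100-ms square current injections ($-100$ to
$+200$ pA or more, 10-pA increments, 10 repetitions each).  The current
threshold $I_T$ is the smallest amplitude that evokes at least one action
potential on 5 or more of 10 repetitions (at least half, if fewer
repetitions exist), and suprathreshold features are averaged over 10
repetitions at $1.25 I_T$ ("25% above threshold" — the package follows the
figure-caption reading, since an injection at 25% *of* threshold is by
definition subthreshold).  Latency is measured to the AP *peak*; rise and
repolarization rates are the extreme positive and negative dV/dt within the
AP window, computed by central differences on the native grid.  The
derivative is smoothed with a 0.2-ms running mean before rate measurements
(configurable, 0 disables): at a 50-kHz digitization rate the *maximum* of
an unsmoothed finite-difference derivative is dominated by sample noise
(0.3 mV of noise contributes $\sim$10 mV/ms per sample), and the smoothing
window plays the role of the recording chain's low-pass filter.  The spike
detector (upward dV/dt crossing of 10 mV/ms with peak above $-20$ mV) is a
configurable default: source recordings rarely state theirs.

Passive properties come from a $-10$ pA step: input resistance
$R = \Delta V / I$ with $\Delta V$ averaged over the last 5 ms of the
injection, the membrane time constant $\tau$ from a single-exponential fit
to the first 10 ms of the response (5 ms for E20–21 cells, whose faster
membranes decay within the shorter window), and capacitance $C = \tau / R$
(ms/MΩ $=$ nF), an identity that holds exactly by construction.  The
charging plateau is anchored at the measured late-window value, so the
exponential fit estimates only the amplitude and time constant — this
roughly halves the variance of $\tau$ at realistic noise.  The first 0.1 ms
after stimulus onset is blanked to avoid the stimulus edge.

### Inclusion rules and statistics

Neurons are included when the resting potential is below $-50$ mV (E13) or
$-55$ mV (E20–21) — "below" meaning more hyperpolarized — and the series
resistance is at most 10 MΩ.  Outliers are removed per metric within each
age × region × condition group by a single-pass two-standard-deviation rule
(mean and SD computed once, not iterated).  Two-group contrasts use Welch's
t-test; three or more groups use one-way ANOVA with all-pairs Bonferroni
comparisons plus the heteroscedasticity-robust pair of Welch and
Brown–Forsythe ANOVAs.  The Brown–Forsythe statistic for means,
$F^* = \sum_i n_i(\bar x_i - \bar x)^2 / \sum_i (1 - n_i/N)s_i^2$ with
Satterthwaite denominator degrees of freedom, is implemented from the
textbook formula (no installed package provides it) and cross-checked by
Monte-Carlo calibration and a hand-computed example.  Shapiro–Wilk normality
checks are reported for transparency but do not gate test selection: the
analysis plan prescribes the tests directly.  Boltzmann read-outs are
compared at exactly $-42.5$ mV (LVA $P_O$ and conductance), $-2.5$ mV (HVA
$P_O$) and $+17.5$ mV (HVA conductance).

## The synthetic-data generator

The simulator is a single-compartment membrane:

$$C_m \frac{dV}{dt} = -\Big[g_{leak}(V - E_{leak})
 + G_{LVA}a_L(V - E_K) + G_{HVA}a_H(V - E_K)
 + g_{Na}m^3h(V - E_{Na})\Big] + I_{inj}(t),$$

with each potassium activation relaxing first-order (time constants 2 ms
LVA, 1 ms HVA — far faster than the 147-ms measurement point, so measured
currents are genuinely steady-state) toward its Boltzmann steady state, and
a minimal m³h sodium mechanism whose only purpose is to produce an onset
spike; its parameters are fixtures, not claims about sodium currents (the
measured potassium currents deliberately exclude it, as sodium is transient
or inactivated at the steady-state window).  Current-clamp integration uses
a fixed 0.01-ms step (exponential Euler for the gates, forward Euler for
voltage) in compiled code; an acceptance-style test compares against a
10× finer reference step.

Default parameters were calibrated once so that the *analysis pipeline
applied to noise-free simulated control sweeps* reproduces the magnitudes
typical of E13 high-frequency control recordings: differential conductance
near 20 nS at $-42.5$ mV and near 70 nS at $+17.5$ mV, steady-state current
near 460 pA at the $-40$ mV step, input resistance near 210 MΩ, and time
constant near 8.6 ms.  Calibrating through the pipeline, rather than setting
the channel $G_{max}$ to the published conductance values directly, matters
because of a real and intended model mismatch, discussed next.  Treatment
conditions are represented *only* as multiplicative scalings of the two
potassium conductances, with the BDNF preset using the published
treated/control ratios of the fitted conductances (11.92/20.19 for LVA,
50.40/72.76 for HVA) at the published group sizes (16 control, 20 BDNF, 11
rescue, 6 antagonist-only).

Between-neuron variability is log-normal jitter on $g_{leak}$, the two
$G_{max}$ values, and $C_m$ (log-normal for positivity and the right skew
conductances show), with coefficients of variation (0.30, 0.17, 0.28, 0.12)
chosen so simulated group SDs approximate the published group SDs.
Per-neuron resting potentials are drawn from a normal distribution
(default $-65 \pm 2.5$ mV) and realized exactly by solving the leak reversal
in closed form; series resistances are drawn from N(6, 2) MΩ truncated at
2, so a realistic fraction of neurons fails QC.  Recording noise (20 pA on
current, 0.3 mV on voltage) is added to recorded samples only, not to the
dynamics; one root seed deterministically derives all per-neuron and
per-sweep child seeds, so cohorts are bit-reproducible.

Problem sizes used by the validation suite — cohorts of 16 vs 20 neurons,
100 recovery replicates, 200 replicate cohort pairs for the power estimate,
10,000-replicate null calibrations — match the study design where one
exists and otherwise were chosen as the smallest sizes that make the Monte
Carlo error negligible relative to the tolerance being checked.

### What the generator does and does not emulate

The generator's channel currents are ohmic:
$I = G_{max}P_O(V)(V - E_K)$.  The Boltzmann analysis, however, models the
*slope* of the I-V curve, and for an ohmic Boltzmann channel
$dI/dV = G_{max}[P_O + P_O'(V)(V - E_K)]$ — the driving-force term makes the
slope overshoot $G_{max}$ inside the activation range and even fall again
at the top of the LVA bin.  The fitted activation curve is therefore a
*descriptive* summary of simulated (and real) data, exactly as it is for
real recordings, and fitted parameters are not numerically identical to the
generator's channel parameters.  Three consequences shape the validation
design:

* **Quantitative parameter-recovery checks** draw their ground truth from
  the fitted model family itself (open-probability curves from the
  Boltzmann equation, I-V curves from its integral) — the standard
  self-consistent recovery design.  Recovery from generator cohorts is
  checked directionally and against the noise-free base-parameter fit, not
  against the raw channel $G_{max}$.
* **Condition effects survive the mismatch**: scaling a channel's
  $G_{max}$ scales its entire contribution to the I-V curve, so fitted
  conductance read-outs scale in the same direction (the scaling
  equivariance of the fit is itself a tested invariant).
* Real recordings contain features the generator omits entirely: series
  resistance and capacitance artifacts, channel kinetics beyond first-order
  activation, inactivation, stochastic threshold variability (measurement
  noise does not enter the dynamics, so the 5-of-10 threshold rule binds
  only through detection jitter in synthetic data), seal leak drift, and
  multi-compartment effects.  Passing tests validate the *analysis code*,
  not these aspects of real data.

## Numerical choices and edge cases

* Half-open steady-state windows resolved on the sample grid; 0-based time.
* Junction correction is applied exactly once; a protocol flag makes double
  correction an error rather than a silent bias.
* The Boltzmann evaluation uses `plogis` and the integral a log-sum-exp
  form; both are finite for arbitrary voltages.
* Exact-model fits recover parameters to ~$10^{-9}$ relative; the optimizer
  tolerances ($10^{-9}$) sit far below every scientific tolerance used in
  tests.
* Degenerate inputs fail loudly: non-positive maximum conductance in
  normalization, fewer in-bin points than free parameters, windows outside
  the trace, positive-going responses to negative steps, all-subthreshold
  threshold searches (an explicit no-threshold result, not an error).
* A corrupted neuron inside a cohort is skipped with a recorded reason;
  the rest of the cohort is analyzed.

## Known limitations

* The HVA integrated fit estimates five parameters from seven in-bin
  points; its raw $G_{max}$ is weakly identified (large standard errors),
  while the conductance read-out at $+17.5$ mV — the quantity compared
  across groups — is stable.  This mirrors the wide published HVA group SDs.
* The open-probability SDs published for HVA channels are not reproduced;
  their units are unclear in the source and they enter no comparison here.
* Embryo nesting is recorded (at most 6 neurons per embryo) but not modeled
  as a random effect, matching the original analysis plan.
* Kv-subtype decomposition, gating kinetics, inactivation, and synaptic or
  morphological modeling are out of scope.
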