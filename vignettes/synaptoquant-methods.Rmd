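---
title: "Methods: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

# Scope

`synaptoquant` implements the quantitative analyses used to characterise
single-vesicle endocytosis and its synaptic consequences across five
recording modalities: cell-attached lock-in capacitance, double-patch
current drift, carbon-fiber amperometry, live-cell fluorescence imaging
(pHluorin, GCaMP, iGluSnFR, Fura-2), and evoked-response trains. Every
analysis stage is paired with a forward model in the synthetic-recording
generator, so each estimator can be validated by parameter recovery or by
analytic identity without any experimental data.

# Fission-pore analysis from lock-in admittance

A cell-attached lock-in measurement splits the patch admittance into a real
part Re and an imaginary part Im at the carrier's angular frequency
$\omega$; $\mathrm{Im}/\omega$ tracks the patch capacitance. A vesicle of
capacitance $C_v$ connected through a pore of conductance $G_p$ contributes

$$\mathrm{Re}(Y) = \frac{\omega^2 C_v^2 G_p}{G_p^2 + \omega^2 C_v^2},
\qquad
\mathrm{Im}(Y) = \frac{\omega C_v G_p^2}{G_p^2 + \omega^2 C_v^2}.$$

Inverting gives the two estimators implemented in `gp_from_re_im()` and
`gp_from_im()`:

$$G_p = \frac{\mathrm{Re}^2 + \mathrm{Im}^2}{\mathrm{Re}},
\qquad
G_p = \frac{\omega C_v}{\sqrt{\omega C_v/\mathrm{Im} - 1}}.$$

Both apply to baseline-subtracted, event-attributable admittance. The two
routes agree to numerical precision on noiseless forward-simulated pores;
this identity is one of the package's standing acceptance checks.

## Step detection

The detection statistic is a sliding two-window mean difference on the Im
channel (20 ms windows by default). Its noise scale is estimated robustly
from the statistic itself (median absolute deviation), and the threshold is
`max(min_step * omega, 3 * noise)` with `min_step = 0.2 fF` — steps at or
above 0.2 fF are the reliably detectable regime, and smaller candidates are
never reported. Step size is measured between plateau means placed outside
the detected transition (100 ms windows), so slowly closing pores still
report the full $\omega C_v$ change. Downward Im steps are endocytic,
upward steps exocytic; the per-patch event count (`count_endocytic_events`)
is the number of downward steps in the first 5 minutes.

## Pore timing

The pore window is delimited by two conductance thresholds: `g_on = 2 nS`
(the pore becomes measurable) and `g_off = 10 pS` (closure). These values
are a package design choice — they bracket the range over which the
estimators respond usefully — and both are configurable. The timing is
applied through the Re channel: near onset, Im sits within a fraction of a
percent of its plateau while Re rises sharply from zero, so Re gives a far
better-conditioned crossing in the presence of noise. Because the onset is
a step-like deflection smoothed by the lock-in output filter, it is timed
at the *half level* of $\mathrm{Re}(g_{on})$, the standard unbiased
convention for locating a low-pass-filtered step; closure is timed directly
at $\mathrm{Re}(g_{off})$. Both thresholds are floored at four times the
pre-event noise SD. With the default 1 ms, 4-pole output filter this keeps
measured durations of 20–100 ms pores within about ±2 ms of truth.

Durations of 15 ms or less are flagged `kinetics_valid = FALSE` and
excluded from kinetic statistics: shorter events are distorted by the 1 ms
lock-in output filter. Duration distributions are right-skewed, so they are
log-transformed (base 10, `log_transform()`) before Student's t-tests.

# Whole-cell capacitance

`simulate_whole_cell_admittance()` is the exact three-element circuit
(membrane capacitance $C_m$, membrane conductance $G_m$, series conductance
$G_s$); `solve_equivalent_circuit()` is its closed-form inversion from one
complex admittance sample plus the DC conductance $G_t$, assuming a 0 mV
reversal potential for the DC current:

$$G_s = \frac{A^2 + B^2 - A G_t}{A - G_t}, \quad
G_m = \frac{G_t G_s}{G_s - G_t}, \quad
C_m = \frac{B G_s^2}{\omega\,[(G_s - A)^2 + B^2]},$$

with $Y = A + iB$. The degenerate purely-real case ($C_m = 0$, where only
$G_t$ is identifiable) returns the consistent factorisation $G_m = G_t$,
$G_s = \infty$. Round-tripping the forward model recovers parameters to
better than $10^{-9}$ relative over a wide log-spaced grid.

Exocytosis is quantified as $\Delta C_m$: the mean $C_m$ over 40–100 ms
after a depolarization minus a 50 ms pre-depolarization baseline (the first
40 ms are skipped because the transient gating-capacitance artifact has
decayed by then; no additional artifact correction is applied). Cells with
leak above 150 pS are discarded (`qc_leak`, strict inequality). Calcium
influx is the integral of the absolute baseline-subtracted evoked current
with the first 10 ms excluded (the unblocked Na$^+$ transient).

# Endocytosis-associated current drift

In double-patch recordings the drift is the difference between straight
lines fit to 20–100 ms segments of the patch current before and after the
capacitance drop, both *extrapolated to the event time* — differencing
extrapolated fits (rather than window means) makes the estimator exact for
any shared baseline slope. A 10 ms guard gap on each side of the event
excludes the filtered transition from both fits.

**Sign convention.** The trace carries the as-plotted pipette current,
which is the negative of the membrane patch current in the cell-attached
configuration. Loss of an outward membrane current at positive patch
voltage therefore appears as an *upward* drift of the plotted current
(positive `delta_I`), and loss of inward current at negative voltage as a
downward drift. The generator and the estimator share this convention.

`rectification_test()` summarises an assembled I–V curve with the OLS
$R^2$ of a straight line through the points and a rectification index,
defined here as |mean drift at the most positive voltage| / |mean drift at
the most negative voltage|: about 1 for an ohmic (non-specific leak) loss,
well above 1 for an outwardly rectifying conductance. The index definition
is a package convention — the underlying observation is qualitative
(linear vs non-linear I–V) and needed a quantitative handle.

# Amperometry

Single-spike analysis follows the four standard criteria: (i) only spikes
with baseline-subtracted peak > 10 pA are considered; (ii) at most 100
spikes are analyzed per cell (earliest first); (iii) the foot is delimited
by the first sustained departure above baseline + 3 SD and the spike onset,
obtained by back-extrapolating the maximal-slope line of the rising phase
to the foot current level; (iv) feet shorter than 0.5 ms are excluded from
foot statistics. The amplitude criterion is additionally applied to a
lightly smoothed (0.6 ms boxcar) copy of the trace with a 3-SD noise guard,
so single noise excursions cannot promote a subthreshold spike.

Parameter conventions: half-width is the full width at half maximum with
linearly interpolated crossings; the decay constant is a single-exponential
least-squares fit between the 75% and 25% crossings of the falling phase (a
contiguous window bounded by first crossings, so noise cannot select
samples); quantal size is the trapezoidal integral of the
baseline-subtracted current from the suprathreshold departure to the first
sustained return to baseline. Baseline is the pre-stimulus segment with a
first-order drift fit. Spikes whose half-maximum extents touch are flagged
overlapping and excluded from shape statistics, but still counted for
spike frequency (spikes within 15 s of stimulation).

Group statistics are computed as mean ± SEM *of the per-cell medians*: the
cell, not the spike, is the unit of replication.

# Optical kinetics

ROI conventions: 4 × 4 pixel boxes centred on boutons for pHluorin/GCaMP;
automatic detection for iGluSnFR via a difference image (mean response
frames minus mean pre-stimulus frames) thresholded at mean + 3 SD, keeping
connected components strictly larger than 10 pixels. Normalization is
$\Delta F/\Delta F_{max}$ for pHluorin and iGluSnFR and $\Delta F/F_0$ for
GCaMP, with $F_0$ from pre-stimulus frames only; normalization is
idempotent.

Exponential fits use Levenberg–Marquardt least squares with a positivity
bound on $\tau$. The pHluorin (endocytic) fit keeps the offset free,
because retrieval can be incomplete and the trace plateaus above baseline;
the calcium decay fixes the offset at zero, since calcium returns to rest.
Reacidification is isolated with acid-pulse (pH 5.5) windows: surface
reporter is quenched, and the surviving signal — endocytosed,
not-yet-reacidified vesicles — decays with the reacidification time
constant; the reported rate is $1/\tau$. Fura-2 is reported as the
elementwise 340/380 ratio after per-channel background subtraction, which
is invariant to any common gain. Series whose baseline declines by more
than 2% over the recording are rejected outright (no bleach correction is
applied, matching the acquisition convention).

# Train analysis

Per-stimulus amplitudes are extracted with residual subtraction: the decay
tail (final 30% of the preceding inter-stimulus interval) is fit with a
single exponential and extrapolated under the next response; the amplitude
is the raw peak minus the extrapolated residual. Summated responses with a
common decay constant add to a single exponential, so the extraction is
exact in the noiseless limit — a property the tests assert at
machine-precision tolerance. Peaks are searched 1–50 ms after each stimulus
for IPSCs and over the full inter-stimulus interval for frame-rate
iGluSnFR data. Amplitudes below 3 noise SD are recorded as failures (zero)
and kept in the normalization.

Trains are normalized to the first response. The steady state is the mean
of the last 10 normalized responses for 250-pulse IPSC trains and the last
5 for 50-pulse iGluSnFR trains; the paired-pulse ratio is the second over
the first amplitude. We average *normalized* amplitudes before group
comparison (the train figures are expressed in normalized units).

# Statistics

Two-tailed Student's t-tests (unpaired by default, paired where the design
pairs observations); one-way ANOVA with Student–Newman–Keuls stepwise post
hoc comparisons for three or more groups. The SNK procedure compares pairs
of ordered means against the studentized range distribution with the
spanned number of means, applying the usual non-contradiction rule; unequal
group sizes use the Tukey–Kramer standard error. "SNK" is our reading of
the post-hoc procedure named in brief as "Newman"; under the complete null
its familywise error equals the full-span studentized-range test, which the
calibration checks confirm (≈0.05 at $\alpha = 0.05$). No further
multiple-testing correction is applied. Summaries are mean ± SEM with n.

# The synthetic generator: what it does and does not emulate

The generators produce, with JSON-serialisable ground truth: pore events
under the admittance model above (instantaneous or with an arbitrary
$G_p(t)$ profile, default linear closure from 2 nS), patch currents with
voltage-dependent conductance loss, amperometric spikes (foot plateau,
raised-cosine rise, exponential decay), pHluorin/calcium ROI series and
bouton image stacks, and geometric depressing trains
$a_n = a_{ss} + (1-a_{ss})r^{n-1}$. Noise is additive white Gaussian,
applied before the lock-in output filter (four cascaded 1 ms single-pole
stages approximating a 24 dB/octave setting). The cell-attached carrier
frequency is not a measured quantity here and defaults to 20 kHz
(standard for sub-fF cell-attached work; whole-cell uses 1 kHz);
simulations treat it as a free parameter.

Deliberately not modelled: pore flicker and reopenings (a pore is a single
monotone closure), stray pipette capacitance, camera shot noise and motion
in imaging, vendor acquisition formats, and release-probability estimation.
Passing recovery tests on these generators therefore demonstrates
correctness of the estimators under the stated forward models, not
robustness to every artifact of real recordings.

# Numerical choices and problem sizes

Default units at external interfaces are seconds, pA, pS, and fF; internal
admittance computation is in SI. Sample indexing is 0-based in time
(`t = (i-1)/fs`), intervals half-open. Isolated samples with Re ≤ 0 inside
a pore are masked, not fatal; a whole segment of non-positive Re is an
error. Exponential fits retry from perturbed starts before falling back to
a `port`-algorithm fit, which removes a rare start-configuration
singularity of the LM solver on noiseless data.

The bundled two-arm ("WT" vs "KO") study in `run_pipeline()` encodes the
effect directions the analysis should detect — fission-pore durations
× 1.6, positive-voltage conductance loss × 0.2, endocytic τ × 1.75, IPSC
steady state × 0.44 and iGluSnFR steady state × 0.64 in the KO arm — at
deliberately modest problem sizes (6 cells, 12 boutons, 8 trains, 12 drift
measurements per voltage and arm) chosen so a full run completes in about a
second while every encoded effect is detected at $\alpha = 0.05$ across
seeds. The acceptance checks use 100 event-free traces, 50 injected steps,
a 10×10×10 circuit grid, 200 simulated boutons, and 10,000-replicate null
calibrations; these sizes are the package's validation conditions.

# Known limitations

- Pore durations shorter than ~5 ms cannot be timed reliably through the
  1 ms output filter; they are flagged invalid rather than reported.
- The step detector assumes events are separated by at least the
  `min_separation` refractory window (250 ms default); bursts of closer
  events merge.
- The residual-subtraction train extractor assumes a mono-exponential
  decay between stimuli; strongly non-exponential synaptic currents would
  bias the extrapolation.
- The iGluSnFR ROI construction (difference image + threshold) is a
  documented stand-in for the published subtraction-series procedure it
  approximates; only the >10 pixel rule is taken as fixed.
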