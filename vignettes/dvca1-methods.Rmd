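---
title: "Methods: intrinsic excitability, resonance, and position analysis with dvca1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic excitability, resonance, and position analysis with dvca1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvca1)
```

## Scope

dvca1 implements the quantitative analysis workflow used to compare the
intrinsic excitability of dorsal and ventral CA1 pyramidal neurons in a
rodent epilepsy model: feature extraction from current-clamp step
families, chirp-based subthreshold resonance, spike-train and
action-potential waveform metrics, sliding-window EEG seizure-candidate
flagging, a printed regression locating a slice on the dorsoventral
axis from anatomical shape ratios, Sholl morphometry on SWC
reconstructions, and radial immunostain profiling. Group-level
hypothesis testing (t tests, ANOVAs, post hocs) is deliberately out of
scope — only the Holm–Šidák step-down adjustment is provided, because
it wraps the repeated-comparison pattern the other measures feed into.

Because no raw recordings are distributed with the original study, the
package ships a synthetic-data module whose generators have exact
ground truth; every analysis stage is validated against those
generators or against closed forms.

## Units and containers

All signals are carried as `trace` objects: `(t0, dt, n)` plus samples
and a unit tag (mV, pA, or µV). Canonical units are mV, pA, ms, µV,
µm, MΩ, Hz; a slope of steady-state voltage (mV) against current (pA)
is a resistance in GΩ and is reported as `1000 ×` that slope in MΩ.
Times are never stored as an explicit column, which makes resampling
inconsistencies unrepresentable. Operations check the unit tag before
touching samples. The liquid junction potential of whole-cell
recordings (≈12 mV in this preparation, conventionally left
uncorrected) is *not* applied anywhere; it can be carried as sweep-set
metadata.

## Subthreshold measures

**Resting membrane potential** is the mean over a pre-stimulus baseline
window. The measurement procedure is not prescribed by the protocol
text, so the averaged-baseline convention (robust, with standard error
σ/√n) is a package decision.

**Input resistance** uses the step family: for every sweep with step
amplitude inside [−70, 10] pA, the steady-state deflection is the mean
over the last 100 ms of the 800-ms step minus the mean over the last
100 ms of baseline, and the OLS slope of deflection against amplitude
is reported. Late-step averaging is our choice (the protocol text does
not state windows); it avoids contaminating the estimate with sag
transients. Sweeps in which action potentials were generated are
excluded before fitting — the exclusion reuses the −20 mV spike
detector — and are reported alongside the fit.

**Rebound slope**: for hyperpolarizing, spike-free sweeps, the rebound
amplitude (peak of voltage minus baseline within 400 ms after step
offset) is regressed on the membrane potential at the end of the step
(mean of its last 10 ms). A memoryless membrane gives slope 0; a
hyperpolarization-activated conductance (I~h~-like) makes deeper steps
rebound further, giving a negative slope. The 400-ms window is a
configurable default; the protocol text is silent on it.

## Chirp resonance

The stimulus is a **linear** chirp, `I(t) = A·sin(2π(f₀t + (f₁−f₀)t²/2T))`,
±50 pA swept 0→15 Hz over 15 s. Linear frequency sweep is the standard
ZAP convention; the protocol text states only the endpoints.

The impedance amplitude profile is computed from single full-length
FFTs of the mean-subtracted voltage and the current, evaluated on
0.5–15 Hz. The band starts at 0.5 Hz to exclude the DC bin and leakage
near 0 Hz; no taper is applied (mean subtraction only), matching the
minimal published description. Two modes exist:

* `magnitude` (default): `|V̂(f)/Î(f)|`. Frequencies where `|Î|` falls
  below 1% of its band maximum are not evaluated.
* `real_ratio`: `Re(V̂)/Re(Î)`, the literal ratio of real parts. The
  real part of the chirp spectrum has zeros that make this ratio
  numerically unstable, so the floor is applied to `|Re(Î)|` and the
  mode is kept behind a flag rather than being the default; the
  published wording is likely shorthand for the standard magnitude
  impedance. On noise-free resonant simulations the two modes agree at
  the fitted peak to well within 5% (tested), although the raw
  real-ratio profile is visibly noisier.

The **peak resonance frequency** is the argmax, on a 0.01-Hz grid, of a
degree-6 polynomial fitted to impedance versus frequency. Order 6 is a
configurable default: it tracks a single-peaked profile over 0.5–15 Hz
without ringing; the published description says only "a polynomial
function". Ties break toward the lower frequency, and a fitted maximum
sitting at the lower band edge means the profile is monotone
decreasing — a low-pass membrane — and is flagged non-resonant.

## Suprathreshold measures

Spikes are counted at upward crossings of **−20 mV** (the conventional
reading of "measured at −20 mV"), with the spike time at the local
maximum; detections closer than 2 ms are merged keeping the taller
peak, preventing double counts on noisy repolarizations. Derivatives
are central differences over one sample step, in mV/ms (the estimator
is not specified in the protocol text).

Per-spike landmarks: **threshold** is the voltage at the first sample —
searching forward from 3 ms before the detection crossing, which
guarantees the sub-criterion foot is captured — where dV/dt ≥ 20 mV/ms;
**max dV/dt** is taken between threshold and peak; **amplitude** is
peak voltage minus resting potential. The **fAHP** is found by scanning
dV/dt from the threshold time: the first zero-crossing (+→−) is the
spike peak, the second (−→+) is the trough, and the fAHP amplitude is
threshold minus trough voltage (positive when the trough undershoots
threshold). If the second crossing is not within 1.5 ms after the peak
the fAHP is reported absent; the published "within 1.5 ms of each
spike" is anchorless, and we anchor it at the peak.

Train metrics: ISIs are successive spike-time differences; the
**SFA ratio** is ISI₆/ISI₁, present only with ≥7 spikes. The source
description is internally inconsistent about the direction of this
ratio (sixth-to-first in one place, first-to-sixth in another), so the
package defaults to ISI₆/ISI₁ and exposes the reciprocal through
`convention = "isi1_over_isi6"` instead of choosing silently. Whether
"sixth spike" means the sixth interval or the sixth instantaneous
frequency is likewise unstated; the ISI convention is adopted and
documented here.

The **FI curve** counts in-step spikes per amplitude over the 100–500 pA
family, and trains of 8–11 spikes (inclusive) are selected for waveform
analysis, matching the middle of the response curve.

## EEG seizure candidates

Power is the within-window **variance** (mean squared deviation from
the window mean, µV²) over a 3-s window stepped by 15 ms — exactly 12
samples at 800 Hz. Defining power around the window mean makes the
detector invariant to electrode DC drift; the published description
fixes only the units. Windows are left-aligned and a trailing partial
window is dropped. Flagging is **strictly above** 100 µV² ("above"),
so a window at exactly threshold never flags; runs of flagged windows
become intervals spanning the union of member windows, merged when
they overlap. The output is labeled *candidates*: confirming an
electrographic seizure and its behavioral correlate is human review,
outside the algorithm. Power is computed per channel (whether the
original analysis summed channels is unstated).

## Dorsoventral position model

The printed regression
`position = −7.23 + 0.43·CA1 + 0.50·CA3 + 0.34·DG` (mm, dorsal
positive) is evaluated exactly; the package never re-fits it (its
training data belong to a prior study), and the ±0.59 mm / 90%
confidence accuracy is carried as metadata only. Zone classification
uses four contiguous 1.5-mm bins reconstructed from the published
midpoints (dorsal ≈ 2 mm, ventral ≈ −2.5 mm): dorsal [1.25, 2.75],
dorsal-intermediate [−0.25, 1.25), ventral-intermediate [−1.75, −0.25),
ventral [−3.25, −1.75), everything else "outside". The source never
prints bin edges, so these are a labeled reconstruction; each bin
includes its lower (printed) edge so boundary positions classify
deterministically.

## Morphometry

Sholl analysis counts, for concentric spheres at 20.6-µm increments
about the soma centroid, the dendritic segments (parent–child chords
with child type 3 or 4) whose endpoint distances straddle the radius.
This is Neurolucida-style chord counting; a segment tangent to a
sphere without endpoint straddle is not counted — a documented
limitation of the chord approximation. Whether the original tracings
were analyzed with 2D circles or 3D spheres is unstated; 3D is the
default and `flatten_z = TRUE` reproduces a projected analysis.
Dendritic length is the sum of chord lengths; surface area uses the
lateral frustum formula `π(r₁+r₂)·√(L²+(r₁−r₂)²)` per segment, with
soma surface, spines, and axons excluded. Segments whose parent is a
soma node measure from the soma centroid.

## Immunostain profiles

ROI quantification is the arithmetic mean over an axis-aligned
rectangle (0 is black; lighter means more protein, per the acquisition
calibration). The radial profile samples the image by bilinear
interpolation at stations along a polyline from the alveus to the
hippocampal fissure (so stratum oriens lands in the first bins and
SLM in the last), averaging across `width` perpendicular 1-px offsets,
then bins the normalized arc length into 20 equal segments. Stations
sit at midpoints of equal subintervals whose count is a multiple of
the bin count: every bin receives equally many stations, no station
sits on a bin edge, and reversing the path reverses the bin order
exactly. The profile width is a required argument — the original
tool's internals are not restated — and no background subtraction is
applied by default (an optional constant dark-frame offset exists).

## The synthetic-data module

The model neuron is a **generalized (resonant) integrate-and-fire**
membrane,

$$C\frac{dV}{dt} = -g_L(V - E_L) - g_1 w + I(t), \qquad
\tau_1\frac{dw}{dt} = (V - E_L) - w,$$

the simplest model with a closed-form impedance
`Z(ω) = 1/(g_L + iωC + g_1/(1 + iωτ_1))` exhibiting an interior
resonance peak. Its DC resistance is `1/(g_L + g_1)`. The original
study contains no biophysical model; the generator's only job is known
ground truth. Integration uses exact exponential updates of the linear
subsystem per sample (input held constant over each step), which is
unconditionally stable for stiff draws; a step coarser than one tenth
of either time constant is rejected. With spiking enabled, threshold
crossings are logged exactly, a stereotyped spike waveform is pasted
into the voltage (so a −20 mV detector sees the spikes), and
integration resumes from reset after the refractory period; the
per-spike dead time is exposed so closed-form rate oracles can account
for it. Observation noise (default 0 mV) is added to the returned
voltage only and never feeds back into dynamics or the spike log.

Other generators: AP templates whose threshold/peak/trough/slope
landmarks equal their arguments by construction; EEG as 30-Hz
low-passed Gaussian background rescaled to an exact RMS plus
amplitude-modulated sinusoidal seizure epochs of specified RMS; random
binary dendritic trees; axis-aligned banded images; and anatomical
ratio triples drawn to invert the position model exactly. Every
generator is a pure function of (parameters, seed).

**What passing tests do and do not show.** The generators emulate the
*mathematical structure* the analyses assume — linear subthreshold
dynamics, stereotyped spikes, stationary background EEG with discrete
high-power epochs, clean layered images. Real recordings add
electrode drift, series-resistance artifacts, non-stationary noise,
movement artifacts in EEG, tissue autofluorescence, and tracing
errors. Passing the suite therefore demonstrates correctness of the
computations under their stated definitions, not robustness to every
failure mode of real data.

## Validation conditions and problem sizes

The test suite validates each stage against independent oracles under
fixed seeds: 20 random resonant parameter sets (C ∈ [150, 250] pF,
g_L ∈ [10, 20] nS, g₁ ∈ [15, 35] nS, τ₁ ∈ [40, 80] ms, redrawn until
the closed-form resonance sits above 1 Hz, since the recovery claims
concern resonant membranes) for input-resistance (within 2%) and
peak-frequency (within 0.25 Hz) recovery; 50 seeded
leaky-integrate-and-fire simulations for exact spike-count agreement;
20 seeded 60-s EEG records (3-µV background, one 10-s 30-µV epoch) for
full epoch recall; 50 random trees for morphometry oracle equality;
and 100 random p-vectors for the Holm–Šidák oracle. Simulations use
dt = 0.25 ms for step families, 0.5 ms for 15-s chirps, and 0.1 ms for
spiking runs — fine enough that discretization error is far below
every stated tolerance. Acceptance-style simulations use the
generator's default of zero observation noise, the condition under
which the recovery tolerances are stated; separate unit tests exercise
0.1–0.2 mV observation noise.

## A worked example

```{r example}
p <- resonant_neuron_params(C = 300, g_L = 15, g_1 = 20, tau_1 = 50,
                            E_L = -66,
                            spike = list(V_T = -50, V_reset = -62,
                                         b = 0, refractory = 40))
steps <- synth_step_sweeps(p, amplitudes = c(-70, -50, -30, -10, 10,
                                             seq(100, 500, 50)),
                           dt = 0.25, seed = 1)
chirp <- synth_chirp_sweep(p, dt = 0.5, seed = 1)
rep <- run_cell_report(list(steps, chirp))
rep$subthreshold$rin_mohm       # expect 1000/(15+20) = 28.57 MOhm
rep$resonance$peak_freq_hz
rep$fi$counts
```

## Known limitations

* No ABF/NWB/EDF binary readers; the sweep-table CSV is the exchange
  format (binary acquisition formats are future adapters).
* The impedance computation assumes a single continuous chirp sweep;
  no segment averaging or smoothing of spectra (the original may have
  smoothed; unstated).
* Sholl counting misses tangent segments without endpoint straddle.
* The zone bin edges are a reconstruction from printed midpoints, not
  published values.
* `real_ratio` impedance is retained for comparability but is
  statistically inefficient; use the default magnitude mode for
  quantitative work.
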