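---
title: "Detecting surface prewetting transitions from fluorescence time-lapse stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting surface prewetting transitions from fluorescence time-lapse stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prewetr)
```

## The problem

When a protein solution below its bulk saturation concentration is exposed
to a membrane it binds, molecules first adsorb as a thin layer whose mean
fluorescence grows with first-order (Langmuir-type) kinetics. If the surface
concentration crosses a critical value, the layer switches abruptly to a
thick, condensed state: a *prewetting transition*. In a single-channel
time-lapse this shows up in two complementary ways:

* bright condensates appear and their number per area grows rapidly, then
  saturates;
* the histogram of log pixel intensities splits from one mode (adsorbed
  layer) into two (adsorbed + condensed).

`prewetr` turns both signatures into a delay-corrected onset time
$t_{pw}$, quantifies condensate geometry through the *layer index*, relates
onset times across bulk concentrations, and estimates critical
concentrations from titration series. Every detector is validated against
a synthetic-stack generator with exact ground truth.

## The histogram metric

Per frame, log pixel intensities $x$ are binned into a probability
distribution $P(x,t)$ with $\sum_x P(x,t) = 1$. Two densities are fitted by
least squares: a single Gaussian $F_1$ and a sum of two Gaussians $F_2$
(each normalised to unit mass), and each fit is scored by its residue

$$r_i(t) = \sum_x \left[F_i(x,t)\,\Delta x - P(x,t)\right]^2 .$$

A one-component fit of the same data can never beat the two-component fit,
so the residue difference $r_0(t) = r_1(t) - r_2(t)$ is non-negative; it
stays near zero while the distribution is unimodal and jumps when the
condensed branch splits off. The raw switch time $\hat t_{pw}$ is the first
time $r_0$ exceeds a fixed threshold (default `1e-4`; the preset `2e-5` in
`detection_threshold_preset()` serves low-contrast mixture comparisons),
after the per-frame trace is refined from the native 5–10 s sampling to a
1 s grid.

Implementation choices the data cannot dictate, made once and documented:

* **Log base.** Natural log. A constant rescaling of intensities shifts
  $x$ additively and leaves every residue invariant, so the choice is
  inert.
* **Bin scheme.** 100 uniform bins, fixed across frames so $r_i(t)$ is
  comparable over time, spanning the envelope of the per-frame 0.1–99.9
  intensity percentiles (minimum of the lower, maximum of the upper).
  Pooled whole-stack percentiles would slice several percent off the
  dimmest frame's lower tail whenever later frames are much brighter, and
  a truncated tail masquerades as skew — enough to push $r_0$ over the
  detection threshold on a perfectly unimodal frame. Pixels outside the
  span are excluded and each frame's histogram renormalised (clamping
  them into the edge bins would fabricate a second mode). Dark pixels are
  floored at $10^{-3}$ of the stack median before the log.
* **Fit initialisation.** The one-component fit starts from histogram
  moments (plus inflated/deflated-width restarts); the two-component fit
  is multi-start — the one-component solution split $\pm1$ sd, and a
  25th/90th-percentile start — and always also considers the *collapsed*
  candidate equal to the one-component solution. The best-of-starts rule
  therefore guarantees $r_2 \le r_1$ by construction, not by hope.
* **Spline policy.** A cubic smoothing spline with smoothing chosen by
  generalized cross-validation, evaluated on a 1 s grid (and clamped at 0
  for $r_0$). Both metrics share it. A smooth refinement necessarily
  crosses a threshold at 10% of a step's height slightly *before* the step
  frame; the tests hold the crossing to within one frame interval of the
  linear-interpolation crossing.

## The rate metric

Condensates are segmented per frame by robust background + $k\sigma$
thresholding (default $k = 4$, minimum area 4 px; the background is the
mode of the log-intensity histogram mapped back to linear scale, its noise
a MAD estimate). The condensate count per field area gives a number-density
trace; its spline derivative is the condensation rate, and the onset is the
earliest time of maximal rate. On well-separated bright condensates this
classical pipeline replaces interactive pixel-classification segmentation
with something reproducible and parameter-light.

## Delay correction

Acquisition starts a little after the protein is added. The mean
(background-referenced) intensity over the first 0–30 s is fitted with a
straight line; its x-intercept $t_0$ locates the moment of bulk addition on
the acquisition clock, and $t_{pw} = \hat t_{pw} - t_0$. When kinetics ran
before frame 0, $t_0$ is negative and the correction moves $t_{pw}$ onto
the kinetics clock. The camera offset must be supplied (or taken from the
stack metadata): it is not identifiable from the trace itself, exactly as
an experimenter must know their detector baseline.

Error bars on $t_{pw}$ come from re-detecting at $0.9\times$ and
$1.1\times$ the threshold (reported as a (low, high) range), matching how
onset uncertainties are usually quoted for threshold rules.

## Layer index

For each condensate the integrated intensity $V$ (a volume proxy, since
the optical section is thicker than the condensate) and footprint area $A$
are tabulated; the layer index $\alpha$ is the OLS slope of $\log V$ on
$\log A$. A monolayer gives $\alpha = 1$; spherical caps of fixed contact
angle give $\alpha = 1.5$ exactly. Background-subtracted intensities are
used (subtraction is a choice — the convention is flagged, and $V \le 0$
rows are excluded from the log fit and counted). Condensates are pooled
across the analysed frame by default.

## Concentration scaling and $\rho_0$

With first-order adsorption at rate $\propto c_b$ and a *common* critical
surface concentration, the onset time obeys
$t_{pw} = c_\mathrm{crit}/(k_{on} l\, c_b) \propto c_b^{-1}$.
`fit_onset_scaling()` fits the exponent in log–log space. Because
$k_{on}$, $k_{off}$ and the conversion length $l$ are unknown,
surface concentrations are reported on a relative scale: $\rho_0$ is fixed
so that the unsaturated reference condition (bulk 100) plateaus at 100 A.U.
after rescaling — the plateau being the mean of the final 10% of frames,
accepted only if the tail varies by less than 1%. `surface_concentration_at_onset()`
then interpolates each condition's rescaled trace at its own $t_{pw}$; a
small coefficient of variation across conditions supports a common critical
surface concentration. "Curation" of traces here means only the exclusion
of frames after a detected reversal.

## Phase diagrams

Titration series (condensed volume fraction in bulk, condensed area
fraction on the membrane) are fitted with a straight line through the
points with positive response, replicates pooled; the critical
concentration is the x-intercept, with a delta-method standard error.
Zero-response points sit below the transition and are excluded — including
them would bias the intercept. Negative raw intercepts are clamped to zero
and flagged.

## The synthetic generator

`generate_timelapse()` emulates the experiment the detectors assume:

* **Adsorption.** Langmuir kinetics
  $c_s(t) = (k_{on} c_b l / k_{off})(1 - e^{-k_{off} t})$ with the linear
  limit at $k_{off} = 0$. Both readings of "first-order binding" are
  selectable; the early-time behaviour, which is all the detectors use, is
  identical.
* **Nucleation.** A finite areal density of nucleation sites (default
  0.6 µm⁻², about a hundred condensates per field) is consumed with
  per-site rate 0.25 s⁻¹ once the noise-free layer crosses the critical
  surface concentration (default 100 A.U.). This gives a sharp onset *and*
  a peaked condensation rate; a constant areal rate that never saturates
  would have no rate peak and would leave the rate metric ill-posed.
* **Geometry.** Spherical caps of fixed contact angle (default 60°,
  restricted to (0, 90°] so the projected column integrates to the cap
  volume), footprint radius growing linearly at 0.08 µm/s to a
  per-condensate mature radius — log-normal around 0.35 µm with cv 0.3,
  since real condensate populations have a broad size spread and that
  spread is what makes a single-frame layer-index fit well-posed —
  rendered with 4× supersampling so the $\alpha = 1.5$ law holds down to
  small condensates. Placement is uniform, rejection-sampled with
  non-overlap at the mature radii, so condensates never merge.
* **Noise.** Dominantly *log-normal multiplicative* (cv 0.15), plus
  additive read noise (sd 2 A.U.) on a constant camera baseline
  (80 A.U.); a Gaussian-approximation shot term is available but off by
  default. The multiplicative term keeps the log-intensity peak width
  roughly level-independent, as in real detector data; a purely additive
  model would collapse the histogram to a one-bin spike as the layer
  brightens and skew the log distribution at low signal, both of which
  corrupt the residue statistic in ways real data does not.
* **Dissolution.** An optional phenomenological phase in which all radii
  shrink linearly to zero, reversing the histogram split — a stand-in for
  actin-driven condensate disassembly, not a mechanistic model of it.
* **Delay.** `acquisition_delay` discards the first seconds of kinetics,
  so $t_0$ recovery is testable.

Default study conditions: 128×128 px at 0.1 µm/px, 5 s frames, 54 frames,
$k_{on} l = 0.005$ A.U. nM⁻¹ s⁻¹, $k_{off} = 0$, so bulk equivalents
100/250/500 nM nucleate at 200/80/40 s — all well past the 0–30 s
delay-fit window. The generator seed fully determines the stack.

What the generator does *not* emulate: coalescence and Ostwald ripening,
spatial illumination gradients, drift, photobleaching, or actin fibres.
Passing tests therefore demonstrate correctness of the detectors under the
assumed statistical structure, not robustness to every artefact of real
microscopy.

## Numerical safeguards and degenerate inputs

* $r_0 \ge 0$ is guaranteed per frame (collapsed two-component candidate).
* Spline refinement requires ≥ 4 frames; switch detection reports an
  absent result (`NA`) rather than guessing when the threshold is never
  crossed; reversal requires the trace to stay below threshold for 3 frame
  intervals.
* A rate trace whose maximum is within numerical ripple of zero (relative
  tolerance $10^{-6}$ of the density scale) is "no condensation", an error.
* Ties at a plateaued rate maximum break to the earliest time (onset
  semantics).
* All-foreground segmentations warn and return an empty mask; empty masks
  tabulate to empty tables, not errors.

## Problem sizes used in validation

The test-suite simulation batches use the default study conditions: 20
seeds × 3 bulk concentrations for onset accuracy, metric agreement and the
scaling exponent; 8 dissolution stacks plus the 60-stack batch for
reversal behaviour; 200 replicates for the titration estimator. These
sizes give stable pass/fail behaviour for the stated bounds (e.g. the
onset-exponent band [−1.15, −0.85]) while keeping a full run in minutes.

## Known limitations

* The two-Gaussian residue rule is a change-point heuristic, not model
  selection; no information criteria, no >2-component mixtures.
* Segmentation assumes bright condensates on a dim uniform layer; dense
  fields that merge condensates violate the number-density reading.
* The detected onset necessarily lags true nucleation by the time
  condensates need to become visible (a few seconds under the default
  conditions); the onset-exponent band absorbs this small bias, and the
  delay correction cannot remove it because it is not an acquisition
  delay.
* Surface concentrations are relative (A.U. anchored to the reference
  bulk concentration); absolute rates and lengths are not identifiable.
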