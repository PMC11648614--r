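# prewetr

Detection and analysis of **prewetting transitions** in fluorescence
time-lapse imaging of protein condensation on supported lipid bilayers.

Proteins below their bulk saturation concentration can still condense *on a
membrane*: molecules first adsorb as a thin layer whose mean intensity
follows first-order binding kinetics, and once the surface concentration
crosses a critical value the layer switches abruptly to a thick, condensed
state. `prewetr` quantifies that switch from single-channel TIFF stacks,
for anyone reconstituting surface condensation in vitro (membrane-binding
phase-separating proteins, actin-nucleation factors, transcription-factor
coats) or building detectors for such data.

## What it computes

* **Onset time `t_pw`, two ways.**
  *Rate metric*: condensates are segmented per frame (robust background +
  k·sigma threshold, connected components), and `t_pw` is the time of
  maximum condensate-number increase per unit area.
  *Histogram metric*: per frame the log pixel intensities are binned into
  `P(x,t)`; a one-component Gaussian `F1` and a two-component Gaussian
  `F2` are fitted by least squares and scored by the residue
  `r_i(t) = sum_x [F_i(x,t) dx - P(x,t)]^2`. The residue difference
  `r0 = r1 - r2 >= 0` jumps when the histogram splits; `t_pw` is its first
  crossing of a fixed threshold (default `1e-4`). Both metrics are
  spline-refined to 1 s, corrected by the acquisition delay `t0` (the
  x-intercept of the 0–30 s mean-intensity kinetics), and carry error bars
  from a ±10% threshold variation. Reversal of the split (condensate
  dissolution) is detected the same way, downward.
* **Layer index `alpha`**: the slope of log integrated intensity vs log
  area across segmented condensates — 1 for a monolayer, 1.5 for spherical
  caps of fixed contact angle (`V ∝ A^1.5`).
* **Concentration scaling**: the power law `t_pw ∝ c_bulk^(-1)` expected
  when a common critical surface concentration is reached by first-order
  adsorption, and the rescaling `c_s(t) = rho0 * I_s(t)` that anchors the
  reference condition's plateau at its bulk concentration (100 nM → 100
  A.U.), so surface concentrations at onset can be compared across
  conditions.
* **Critical concentrations** from titration series, as the x-intercept of
  condensed fraction vs concentration.
* **A synthetic-stack generator** with exact ground truth (Langmuir
  adsorption, nucleation above a critical surface concentration,
  spherical-cap condensates, optional dissolution, seeded noise) used to
  validate all of the above.

## Worked example

```r
library(prewetr)

# a synthetic acquisition: bulk 250 nM, first-order adsorption, nucleation
# once the adsorbed layer crosses 100 A.U. (truth: t_nucleation = 80 s)
sim <- generate_timelapse(
  config     = simulation_config(seed = 7),
  adsorption = adsorption_params(c_b = 250, k_on = 0.005),
  geometry   = condensate_geometry())
sim$series
#> acquisition_series: 54 frames of 128 x 128 px, dt = 5 s, 0.1 um/px, c_b = 250 nM
sim$truth$true_t_nucleation
#> [1] 80

# histogram metric at the shared threshold 1e-4
det <- detect_prewetting(sim$series, threshold = 1e-4)
det
#> switch_detection (histogram metric)
#>   t_hat_pw = 83.0 s, t0 = -0.67 s, t_pw = 83.7 s
#>   threshold-sensitivity range: [83.7, 83.7] s
#>   split maintained (no reversal)

# layer index from the last frame's segmentation
frame <- sim$series$frames[, , 54]
mask  <- segment_condensates(frame)
tab   <- tabulate_condensates(frame, mask, pixel_size = 0.1)
layer_index(tab)
#> layer index: alpha = 1.401 +/- 0.010 (n = 97, 0 excluded)

# critical concentration of a titration series by axis intersection
cc  <- c(1000, 2000, 5000)
est <- estimate_csat(cc, 1e-4 * (cc - 500))
sprintf("c_sat = %.1f nM", est$c_sat)
#> [1] "c_sat = 500.0 nM"
```

Reading the output: the detected onset (83.7 s on the kinetics clock, after
subtracting the fitted delay `t0`) lags the true nucleation time by ~4 s —
the time condensates need to grow to visibility. The layer index 1.40 sits
near the spherical-cap limit 1.5, as it should for multilayered cap-shaped
condensates (rim pixels lost to segmentation bias it slightly down); a
monolayer would give 1.0.

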