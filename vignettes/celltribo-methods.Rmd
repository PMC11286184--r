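---
title: "Methods: friction correction, damage quantification and the piercing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: friction correction, damage quantification and the piercing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltribo)
```

This vignette documents the models behind `celltribo`, the assumptions they
rest on, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## 1. The slope-adjustment model

### Physical picture

A sphere is dragged at constant speed `v_t` (default 1 mm/s) over a sample
under a normal-force servo. If the surface under the probe has local slope
`dh/dx` — from mounting tilt and from the meniscus bowl that cured liquid
polymers form in a dish — the measured lateral force `F_x` contains both the
interfacial friction and the component of the contact load along the travel
direction. For small friction coefficients the slope term dominates:
at `mu = 0.05` a 2% slope doubles the apparent friction.

The correction is a planar rotation by the local surface angle
`theta(x) = atan(dh_p/dx)`:

$$F_{F,adj} = F_x\cos\theta - F_N\sin\theta,\qquad
  F_{N,adj} = F_N\cos\theta + F_x\sin\theta,\qquad F_N = |F_z|.$$

Under the quasi-static force balance of a sphere on an incline (servo holding
the *vertical* force, contact normal force
`N = |F_z|/(cos(theta) - mu*sin(theta))`), this rotation is the exact
inverse of the measurement process: `F_F,adj = mu*N` and `F_N,adj = N`.
Consequently the friction coefficient is estimated as
`F_F,adj / F_N,adj`, not as `F_F,adj / F_N,set` — using the true contact
load removes the residual `mu*tan(theta)` bias that the setpoint-normalised
estimate retains. Both the full rotation and the first-order variant
(`include_lateral = FALSE`, which drops the lateral force's contribution to
the adjusted normal load) are available; the full rotation is the default
because it is exact under the model.

Assumptions: quasi-static sliding (inertia negligible at 1 mm/s), a rigid
probe-arm (no compliance correction), slopes below 45 degrees (enforced), and
single-direction slides. Reciprocating experiments and viscoelastic creep are
out of scope.

### Height model

The measured probe height over the sliding phase is fit by a least-squares
polynomial in the stage position `x` (degree 5 by default; configurable).
Degree 5 is flexible enough for tilt plus a bowl-shaped meniscus while
remaining smooth, and its analytic derivative gives `dh_p/dx` without
numerical differentiation of noisy data. Evaluation outside the fit domain
is an error rather than an extrapolation.

### Phase segmentation

* **Motion onset**: first sample with `|x - x(0)| > max(3*sd_pre, 1 um)`.
  Stage encoders are nearly noiseless, so the 1 um floor is what matters in
  practice.
* **Baseline** `F_x,bm`: *median* lateral force over the pre-movement dwell —
  robust to drift and spikes. The baseline is a sensor offset, not a force,
  so it is subtracted from `F_x` *before* the rotation for both the static
  and the dynamic estimate; rotating an offset would leak it into the
  adjusted normal load.
* **Static peak**: largest `|F_x - F_x,bm|` within 0.5 mm of travel after
  onset. If the peak does not exceed `5 *` the robust pre-movement noise, it
  is flagged missing and static quantities are reported as `NA` — never
  invented.
* **Stabilization window**: from the first post-peak sample whose force is
  within `max(10%` of the trailing dynamic mean, `5 * noise, 1 uN)` of that
  mean, to 95% of the slide length (end effects excluded). The absolute
  floor matters for noiseless traces whose dynamic force is near zero (tilt
  cancelling friction).
* **Zero-slope window**: the contiguous run of sliding samples around the
  minimum of `|dh_p/dx|`, provided that minimum is below `1e-3` mm/mm.
  On a monotone (tilt-only) profile no such window exists and it is reported
  absent. The mean raw force over this window is the uncorrected estimate
  the correction is validated against.

### Amonton fits

`F_F = mu * F_N` is fit through the origin, `mu = sum(F_N F_F)/sum(F_N^2)`,
using the *adjusted* normal load of each slide as the abscissa. Static and
dynamic coefficients are fit separately.

## 2. The damage statistic

Damage is quantified as nuclei densities in the slide band relative to the
pooled blue-nucleus density `rho_ref` of reference areas flanking the track:

$$\mathrm{rel}_{blue} = \frac{\rho_{healthy}}{\rho_{ref}},\quad
  \mathrm{rel}_{red} = \frac{\rho_{dead}}{\rho_{ref}},\quad
  \mathrm{rel}_{removed} = 1 - \mathrm{rel}_{blue} - \mathrm{rel}_{red}.$$

Design choices:

* **"Healthy" excludes red-matched nuclei.** With healthy, dead and removed
  defined this way the three fractions partition unity exactly, which is the
  invariant users reason with. `rel_removed` may legitimately be slightly
  negative (the track happened to be denser than the references); it is
  reported as-is, never clipped.
* **Pooled references.** Blue counts of all reference regions are pooled
  into one density rather than averaged per region; pooling weights regions
  by area and is the lower-variance estimator.
* **Reference geometry.** Default: two bands flanking the track, same
  length, centred 3 track-widths away from the track centreline. Offsets
  and widths are explicit parameters because real fields of view vary.
* **Ratio robustness.** Because the statistic is a density ratio, any
  spatially uniform detection inefficiency cancels. The residual bias is the
  *density dependence* of detection (merged nuclei are likelier in dense
  areas); with the watershed splitting below this is a few percent at
  confluent densities.

### Nuclei detection

Per channel: min-max normalization (making all downstream thresholds
invariant to affine intensity rescaling), Gaussian high-pass background
subtraction (sd 25 um), Gaussian smoothing (sd 2 um), Otsu threshold guarded
by a noise floor (objects must exceed the image median by 5 robust SDs — a
blank or pure-noise image yields zero detections rather than Otsu
hallucinations), watershed splitting at intensity valleys (tolerance 0.02 on
the normalized scale), and an area filter of 20-600 um^2. Centroids use the
pixel-centre convention, origin top-left, converted to um by the pixel size,
which is a required input — never guessed.

Red detections are matched to blue by mutual nearest neighbours within 7 um
(about one nuclear radius); ties break by distance then index, so labelling
is deterministic. Unmatched red detections still count once as dead.
Nuclei closer than roughly the blob width merge into one detection; this
resolution limit is inherent and is why the statistic is built from density
ratios.

### Track width

The damage fraction `dead/rho + (1 - blue/rho)` is profiled in 10 um lateral
bins, smoothed with a 3-bin moving average, and the width is the full width
at half the plateau above background, with sub-bin edge interpolation. A
plateau must exceed both an absolute threshold (0.15) and 4 robust SDs of
the off-track bins, otherwise the width is 0 with a warning. FWHM was chosen
over the full extent because it is insensitive to the smoothing kernel and
to stragglers; the full-extent variant remains available
(`method = "full"`).

## 3. Contact mechanics and the piercing model

Hertz contact of a sphere (radius 1 mm, the probe used throughout) on a
half-space gives `a = (3FR/4E*)^{1/3}`, `delta = a^2/R`,
`p0 = 3F/(2 pi a^2)`; all computed in SI internally and reported in
mN/um/kPa. Default materials: glass `E = 70` GPa, `nu = 0.22`; polystyrene
`E = 3.0` GPa, `nu = 0.35`; soft PDMS `E = 73.32` kPa (the measured modulus
of the gel formulation used), `nu = 0.5`. The Poisson ratios and the PS
modulus are literature-typical defaults and are explicit, configurable
inputs.

The piercing model explains why slide-track widths on stiff substrates are
almost load-independent while Hertz predicts `a ∝ F^{1/3}`. A monolayer
(undeformed thickness `h_cell`, default 3 um) is far softer than probe and
substrate; cells compressed below a critical thickness `h_crit` (default
0.8 um, order set by back-calculating the observed ~78 um track under a
1 mm probe: `h_crit = (w/2)^2/2R ≈ 0.76` um) burst. After piercing the
substrate carries the load (the *load-transparent* monolayer assumption) and
the sphere indents it by the Hertz `delta`; cells die wherever the
sphere-substrate gap `r^2/2R - delta` is below `h_crit`:

$$w_{pred} = 2\sqrt{2R\,(h_{crit} + \delta)}.$$

Two open choices were resolved as follows:

* **Load-transparent vs series-stiffness monolayer.** The load-transparent
  variant is implemented: once pierced, the remaining cell matter carries a
  negligible share of the load compared to a GPa-scale substrate. A
  series-spring pre-piercing stage would change `delta` by order
  `E_sub/E_cell` corrections that are far below the model's other
  uncertainties.
* **Rigid-parabola gap.** The gap uses the undeformed sphere profile minus
  the Hertz approach. The full elastic gap profile would shift predicted
  widths by a few percent at these loads; the parabola keeps the model
  closed-form and its parameters interpretable.

A known limitation follows directly: on polystyrene the Hertz indentation
grows from 0.17 um (10 mN) to 0.70 um (80 mN), which is *not* negligible
against `h_crit ≈ 0.76` um, so the model predicts a width growth of about
25% over that load range. Observed growth is smaller (a few percent). The
model therefore captures the central qualitative finding — width growth far
below the Hertz factor of 2 — but overestimates the residual load dependence
unless the substrate is effectively rigid (`delta << h_crit`). The package's
tests state both sides of this honestly.

## 4. The synthetic-data generators

### Traces

`generate_trace()` composes, on a 100 Hz grid (rate configurable; typical
of benchtop tribometers): a pre-movement dwell (default 10 s, the loading
time used before slides), a linear pre-sliding force ramp over 0.1 mm ending
in the static peak, an exponential transition (0.05 mm) into dynamic
sliding, and a dynamic regime generated from the *exact* incline balance
with `mu_d`, so that the slope adjustment can be validated against ground
truth with no modelling error. Surfaces combine a tilt (default 0.02) with
an even-quartic meniscus bowl (default depth 0.05 mm over a 4 mm slide)
whose derivative vanishes at exactly one interior point — flat bottom,
upturned edges, as cured polymer surfaces show. Stick-slip is a sawtooth on
`mu_d` (fractional amplitude 0.1) with exponentially spaced release events
(mean 0.2 mm); its mean is zero so dynamic-friction estimates stay unbiased.
The normal-force servo is a first-order lag (tau 0.5 s) from the touch force
(0.3 mN) to the setpoint with AR(1) noise; the lateral channel adds white
noise plus a constant sensor baseline (0.05 mN) that the analysis must
recover and subtract. The ramp distance is an exact multiple of the sample
spacing at the defaults, so the static peak falls on a sample.

Not emulated: probe-arm compliance, adhesion, elastohydrodynamics, lubricant
films, servo overshoot dynamics. Passing recovery tests therefore
demonstrates correctness of the *analysis* under the stated force balance,
not that real traces contain no further physics.

### Images

`generate_image_pair()` places nuclei by a homogeneous Poisson process at a
confluent-monolayer density (default 400 /mm^2), assigns fates inside the
track band (`removed` with `p_remove`, else `dead` with `p_dead`), and
renders retained nuclei as isotropic Gaussian blobs (sd 4 um, peak
intensity jittered 0.8-1.25x, saturation-clipped) over a constant
background with Gaussian pixel noise. Dead nuclei render in both channels.
An optional hard-core spacing thins the Poisson process for
well-separated-field tests; the default keeps pure Poisson, including its
merged-nuclei challenge for the detector. No cytoplasmic stain, uneven
illumination, focus drift or staining variability is simulated — real
micrographs are harder than these, which is why the damage statistic is a
ratio and the tests check parameter *recovery*, not absolute counts.

### Study designs

`generate_experiment_set()` pairs traces and image pairs over a force grid
(default-style designs use 10-80 mN with 9 repeats, three slides per dish
being the practical layout). Trace noise scales with the dynamic signal
(sd = 5% of `mu_d * F_N` by default); track damage probabilities follow a
load map emulating the harsh stiff-substrate regime (removed fraction 0.46
at 10 mN rising to 0.80 at 80 mN, about half of retained track nuclei
dead), interpolated in log-force. Child seeds derive deterministically from
the master seed: a fixed seed reproduces the collection bit-for-bit.

## 5. Problem sizes and tolerances used by the test-suite

The suite validates recovery at sizes chosen to keep statistical bounds
meaningful: the friction design uses 4 forces x 9 repeats (36 slides); the
damage grid uses 12 probability combinations rendered on 6 x 1.2 mm fields
at 400 nuclei/mm^2 (track area 1.8 mm^2, about 720 track nuclei), where
binomial counting alone predicts per-fraction errors of ~0.01-0.02 —
the mean absolute recovery error asserted is 0.03. Exactness claims
(rotation magnitude preservation, Hertz self-consistency, partition
identity) are asserted at 1e-9 relative or exact identity; estimator checks
against independent oracles (closed-form incline balance, numerical Hertz
solve, direct fate counting) at the tolerance each derivation supports.
Recovery tolerances (1% noiseless slope correction, 5% noisy Amonton
recovery, 3-sigma fate fractions) reflect the residual biases analysed
above: the finite post-peak transition contributes up to ~0.3% to dynamic
means, and density-dependent detection merging a few percent to density
ratios.
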