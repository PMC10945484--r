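---
title: "Models and methods behind dibkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dibkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dibkit)
```

`dibkit` implements the analysis side of a three-assay campaign that
probes how small membrane-active solutes alter a phospholipid bilayer:
osmotic water permeability measured on droplet interface bilayers
(DIB), phase-transition thermodynamics from differential scanning
calorimetry (DSC), and acyl-chain packing order from Raman C–H
stretching intensity ratios.  This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic
generators do and do not emulate.

## 1. DIB osmotic permeability

### Model

Two aqueous droplets coated with lipid monolayers adhere in oil; the
contact zone is a bilayer disc of radius $r_c$.  Each droplet is a
*truncated sphere*: a sphere of radius $R_i$ minus the spherical cap
beyond the contact plane (cap height $h_i = R_i - \sqrt{R_i^2 -
r_c^2}$).  With solute trapped in each droplet (amount $n_i$ conserved)
and water free to cross the bilayer, the volume of droplet 1 obeys

$$\frac{dV_1}{dt} = -P_f\, v_w\, \pi r_c^2\,\bigl(c_2(t) - c_1(t)\bigr),
\qquad c_i(t) = n_i / V_i(t),$$

with $V_2 = V_\mathrm{tot} - V_1$ exactly (water-only transport).  In
the package's micrometre–second unit system the product of $v_w$ in
cm³/mol and concentrations in osmol/L contributes a factor $10^{-3}$.

Assumptions: ideal-dilute osmotic driving force (no activity
coefficients), impermeant solute, planar bilayer disc, spherical caps.
Osmolality readings in mOsm/kg are mapped to osmol/L with a solution
density of 1 kg/L (`mosm_kg_to_osmol_L()`); nominal NaCl molarity maps
with an ideal van 't Hoff factor of 2 (`nacl_osmolarity()`, the
osmotic coefficient is an explicit argument).

### Shrinkage geometry

How $r_c$ evolves as volumes change is not observable from volumes
alone, so the geometry is an explicit switch:

* `constant_contact_radius` (default): the disc is pinned at its
  initial radius; sphere radii follow from the volumes by inverting the
  truncated-sphere formula (monotone 1-D root find).
* `constant_contact_angle`: the contact angle of droplet 1,
  $\theta_1 = \arcsin(r_c/R_1)$, is held at its initial value, which
  makes $R_1 \propto V_1^{1/3}$ and $r_c = R_1\sin\theta_1$ closed
  form; droplet 2's radius is solved from its volume and the shared
  $r_c$.  Pinning *both* droplets' angles would over-determine the
  shared disc, hence this asymmetric but self-consistent definition.

Both modes exist in generator and fitter; matched modes round-trip, and
neither is asserted to be "the experimental truth".

### Inference

Volumes are reconstructed per frame from the measured radii
(`truncated_sphere_volume`), and in the pinned-disc mode the contact
radius is averaged along the trajectory before use — it is physically
constant there, so averaging only suppresses measurement noise.  The
*observable fitted is the hypotonic droplet's volume*, because the flux
law is linear in volume; "droplet 1" is the hypotonic (shrinking)
droplet, with input order breaking ties for isotonic pairs.

* `estimate_pf_initial_rate()`: linear fit of $V(t)$ over the first
  `window` samples, $P_f = |\text{slope}| / (v_w A(0) |\Delta c(0)|)$.
  Biased low on long windows (the gradient decays); used as the
  initialiser and cross-check.
* `estimate_pf_ode_fit()`: least squares between observed volumes and
  the forward-integrated model.  Two parameters are estimated: $P_f$
  and the initial volume $V_0$.  Treating $V_0$ as a nuisance parameter
  matters: the measured first frame carries the same noise as every
  other frame, and anchoring the model to it propagates that noise
  directly into $P_f$ (in simulations at 0.5 μm radius noise it
  inflates the estimator spread several-fold).  The fit profiles the
  residual sum of squares over $P_f$, solving the inner $V_0$ problem
  by a mean-residual fixed point (the model's sensitivity to $V_0$ is
  ≈1, so the mean residual is a near-exact Newton step).  A coarse
  logarithmic grid over $P_f$ brackets the global minimum before golden
  section — on noisy data the profile can develop shallow spurious
  basins at implausibly large $P_f$.  Search bounds are $[0, 10^4]$
  μm/s; hitting the upper bound raises a fit-failure error.  The
  standard error comes from the curvature of the profiled SSR.

Integration uses an adaptive Cash–Karp Runge–Kutta 4(5) with relative
tolerance $10^{-8}$ (the dynamics are non-stiff at these parameters; an
external ODE package is deliberately not required).  Non-finite states
abort with an error naming the step.

Replicates are pooled by `aggregate_condition()` as mean ± SEM (sample
SD / √n).  SEM is defined as 0 for n = 1 so that pipelines stay total;
this is documented rather than returning NA.  Condition-vs-control
shifts are reported by `percent_change()` and rounded to integer
percent, the granularity at which such shifts are conventionally
quoted.

### Synthetic trajectories and images

`simulate_dib_trajectory()` integrates the same ODE (shared code path
is only the integrator; the fitter re-derives geometry from the
observed table) and adds Gaussian noise *to the radii after
integration* — radii are what an imaging system measures, so noise on
volumes would be the wrong error model.  Defaults describe the nominal
experiment: 100 μm diameter droplets (±5 μm in the real assay), 30 μm
contact radius, pure water against 0.2 osmol/L (nominal 0.1 M NaCl,
ideal dissociation), 30 °C, 60 s at 1 Hz sampling.

`render_droplet_image()` draws the pair as two anti-aliased bright
disks (linear edge, one pixel wide) whose intensity passes through half
the disk brightness exactly on the true circle.  `fit_droplet_pair()`
therefore extracts the half-level iso-contour (level midway between
frame min and max, making it invariant to global intensity scaling)
with sub-pixel linear interpolation, splits the contour between the two
arcs by alternating Kasa circle fits with residual-based reassignment,
and derives $r_c$ from the sphere–sphere intersection of the fitted
circles rather than segmenting the low-contrast contact chord.
Coordinate convention: origin top-left, x = column, y = row, pixel
centres at integer coordinates.  The renderer makes no attempt at
microscopy realism (no refraction, halo, or illumination gradients);
a sub-half-pixel round-trip on these fixtures shows the fitting
pipeline is correct, not that it is robust to real optics.

## 2. DSC transition metrics

Heat flow (mW, endotherm-up by convention) is converted to molar excess
heat capacity via $C_p = q / (\beta\, n\, 4184)$ with $\beta$ the scan
rate in °C/s and $n$ the sample amount in mol (default: 15 μL of a
16 mg/mL DOPC suspension, MW 786.1, i.e. 3.05×10⁻⁷ mol).  The baseline
is the straight line through the mean points of two peak-free windows
flanking the transition (defaults −35…−28 and −8…−2 °C); windows that
intersect the detected peak support raise an error.  Sigmoidal
baselines are not implemented — a documented limitation, acceptable for
single well-resolved endotherms.

Metrics from the corrected trace:

* $T_m$: 3-point parabolic interpolation around the grid maximum
  (sub-grid apex without assuming a peak shape);
* $\Delta H$: trapezoidal integral over the contiguous region where the
  excess $C_p$ exceeds 1% of the peak maximum.  The cutoff is a
  reproducible stand-in for undocumented vendor integration limits; for
  a Gaussian peak it forfeits ≈0.24% of the area, visible in tests as a
  ΔH recovery of ~8.738 for a truth of 8.76 kcal/mol;
* $\Delta T_{1/2}$: linear interpolation of the half-maximum crossings
  nearest the apex.

A transition requires peak height above 5× the flanking noise SD
(MAD-based, outer 10% of points per side); competing local maxima at
≥50% of the main peak outside its support raise an ambiguity error
listing the candidates.  Heating scans only are analysed.

The generator works directly in excess-$C_p$ space, where apex, area
and FWHM of the Gaussian shape are exact identities; the skew-normal
variant is calibrated numerically (mode and FWHM of the unit shape to
~10⁻¹⁰ by optimisation, then axis rescaling) so the configured
$(T_m, \Delta H, \Delta T_{1/2})$ still hold.  Peaks truncated by the
scan window set a warning flag.

## 3. Raman packing-order ratios

Band intensities are *peak heights* (not areas) — the convention in
which such packing ratios are reported — measured as the window maximum
within ±10 cm⁻¹ of the nominal centre, refined by parabolic
interpolation so that coarse grids (tested 0.5 vs 2 cm⁻¹) agree within
1%.  "Intensity at ~2848" therefore means the local maximum near 2848,
tolerant of small instrument calibration offsets.  A band is "missing"
when the window maximum is non-positive, sits on the window edge, or
the window contrast is below 5% of the maximum; `band_ratios()`
additionally requires each height to clear 5× the MAD noise floor of
the off-band region, so a corrected baseline-only trace errors instead
of returning arbitrary ratios.

### Baseline choice

The conventional asymmetric-least-squares (ALS) smoother is provided
(`method = "als"`), but it is *not* the default: a single stiffness
cannot both track a strongly curved background (stiff settings leave
percent-level residuals on a pure polynomial input) and stay flat under
the ~180 cm⁻¹-wide C–H cluster (flexible settings bulge upward there by
~2%).  The default `method = "modpoly"` is iterative polynomial
fitting: fit a degree-5 polynomial, re-classify as peak any point whose
residual exceeds twice the spread of the below-baseline residuals,
refit to the remaining points, iterate to a fixed point.  Excluded
points exert no pull, so the polynomial is pinned by the band-free
flanks on both sides of the cluster; on polynomial backgrounds (which
is also the generator's baseline model) the removal is exact to
numerical precision.  Non-convergence raises an error.

Normalisation divides by the maximum in the 2848 ± 10 cm⁻¹ anchor
window (idempotent, scale-invariant); ratios are unchanged by
normalisation to 10⁻¹² by construction, and tests assert it.

### Calibration helper

The three C–H bands overlap, so configured amplitudes are not measured
heights.  `calibrate_band_amplitudes()` tunes the 2890 and 2930
amplitudes (2848 held fixed) by fixed-point iteration until the ratios
measured by the *full pipeline* (baseline correction, normalisation,
band ratios) on the noiseless spectrum equal the targets to 10⁻⁶.
Calibrating through the pipeline, rather than against isolated band
heights, makes the generator's stated ratios mean exactly what the
analyser will report — the round trip then validates the pipeline's
invariances (scaling, baseline, grid), not a tautology, because every
perturbation test changes the spectrum after calibration.

Replicate statistics follow the "3 samples × 3 regions" design:
regions are averaged within each independently prepared sample, and the
summary reports across-sample mean and *sample SD*.

## 4. Synthetic world: what a green test establishes

The generators reproduce the statistical structure the analysers
assume: conserved solute and water in the DIB model, additive Gaussian
measurement noise on radii / heat flow / intensity, polynomial
instrument baselines, Gaussian/Lorentzian bands and Gaussian or skewed
endotherms, all reproducible from integer seeds (identical config +
seed is bit-identical).  They do **not** emulate microscope optics,
droplet drift, detector nonlinearity, sigmoidal DSC baselines,
cosmic-ray spikes, fluorescence backgrounds, or any chemistry — solute
effects enter only through the user-set ground truth ($P_f$, $T_m$,
$\Delta H$, widths, ratios).  A green round-trip therefore certifies
the *estimators* (geometry, calibration, baseline handling, peak
metrology, uncertainty pooling) under the stated noise model, and
nothing about instrument-specific artefacts.

## 5. Numerical summary

| Quantity | Choice | Default |
|---|---|---|
| ODE tolerance | adaptive RK45, relative | 1e-8 |
| $P_f$ search | profiled 1-D, log-grid bracket + golden section | bounds [0, 1e4] μm/s |
| DSC peak support | contiguous > 1% of peak maximum | — |
| DSC apex | 3-point parabola | — |
| Peak detection | height > 5 × flank noise SD | — |
| Raman baseline | masked polynomial fit, 2-sigma exclusion | degree 5 |
| Band windows | ± 10 cm⁻¹, parabolic refinement | — |
| Calibration | pipeline fixed point | tol 1e-6 |
| SEM at n = 1 | defined as 0 | — |

Degenerate inputs error early with specific messages: zero osmotic
gradient (undefined $P_f$), non-intersecting spheres, contact radius
exceeding a droplet radius, blank or single-disk frames, baseline
windows touching the peak, missing bands.
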