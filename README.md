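# dibkit

Quantitative analysis for a three-assay model-membrane characterisation
pipeline, built around the question of how small amphiphilic solutes
(e.g. the soy isoflavones genistein and daidzein) change the physical
state of phospholipid bilayers:

1. **DIB water permeability** — two lipid-monolayer-coated aqueous
   microdroplets adhere in oil and form a droplet interface bilayer
   (DIB) across a contact disc of radius *r_c*.  An osmotic imbalance
   drives water across the bilayer and the hypotonic droplet shrinks.
   The osmotic water permeability coefficient *P_f* (μm/s) is defined by
   the volume flux law

   ```
   dV1/dt = -P_f · v_w · A(t) · (c2(t) - c1(t)),   A = π r_c²
   ```

   with `v_w` the molar volume of water (18 cm³/mol) and `c_i` the
   instantaneous osmolarities.  `dibkit` infers *P_f* from droplet-pair
   radius trajectories by refitting this ODE (or by an initial-rate
   shortcut), using truncated-sphere geometry for the volumes.

2. **DSC thermotropics** — endothermic thermograms of multilamellar
   vesicles are calibrated to molar excess heat capacity; the package
   reports the main transition temperature `T_m` (apex), transition
   enthalpy `ΔH` (integrated area, kcal/mol) and the width at half
   height `ΔT_1/2`, plus control-relative `ΔT_m` and `ΔH/ΔH°`.

3. **Raman packing order** — C–H stretching spectra are
   baseline-corrected and normalised at the ~2848 cm⁻¹ CH₂ symmetric
   stretch; the peak-height ratios `I2930/2848` and `I2930/2890`
   (terminal CH₃ over CH₂ symmetric / asymmetric) quantify acyl-chain
   rotational disorder and inter-chain packing.

Because raw instrument recordings for such experiments are rarely
published, the package ships first-class **synthetic data generators**
for all three assays (seeded, with recorded ground truth), so the whole
pipeline is testable end to end, plus CSV/JSON/JCAMP-DX/PGM interchange
and a small CLI.

## Worked example

```r
library(dibkit)

# --- DIB permeability: simulate a noisy droplet pair and refit Pf
cfg  <- dib_sim_config(true_Pf = 74, noise_sd_radius = 0.2, seed = 42)
traj <- simulate_dib_trajectory(cfg)
head(traj, 3)
#>   time_s    R1_um    R2_um    rc_um
#> 1      0 50.27419 50.03705 30.02494
#> 2      1 49.86339 50.14002 29.80067
#> 3      2 50.02529 50.32719 29.99964
estimate_pf_ode_fit(traj, attr(traj, "conditions"))
#> <permeability_estimate> Pf = 81.530 +/- 5.347 um/s (ode_fit, n = 61, rms = 6.93e+03 um^3)
```

A single replicate at 0.2 μm radius noise lands within ~1.5 standard
errors of the 74 μm/s ground truth; replicates are pooled with
`aggregate_condition()` (mean ± SEM).

```r
# --- DSC: control endotherm with an instrument baseline
tg <- simulate_thermogram(dsc_sim_config(baseline_slope = 0.01))
transition_metrics(subtract_baseline(heatflow_to_molar_cp(tg)))
#> <transition_metrics> Tm = -17.08 degC, dH = 8.738 kcal/mol, dT_1/2 = 2.040 degC
```

The generator truth was (−17.08 °C, 8.76 kcal/mol, 2.04 °C); the small
ΔH deficit (−0.25%) is the documented 1%-of-peak integration cutoff.

```r
# --- Raman: tune band amplitudes to target composite ratios, re-measure
cal <- calibrate_band_amplitudes(
  raman_sim_config(baseline_poly_coeffs = c(0.2, 0.05, 0.1)),
  target_2930_2848 = 0.88, target_2930_2890 = 0.96)
band_ratios(normalize_at(baseline_correct(simulate_raman_spectrum(cal))))
#> <band_ratio_result> I2930/2848 = 0.8800, I2930/2890 = 0.9600

# --- condition vs control, reported at integer-percent granularity
round(percent_change(94, 74))
#> [1] 27
```

## Command line

```sh
Rscript inst/cli/dibkit simulate dib   --config dib.json   --out traj.csv
Rscript inst/cli/dibkit estimate-pf    --traj traj.csv --conditions cond.json
Rscript inst/cli/dibkit analyze-dsc    --in tg.csv  --pre -35:-28 --post -8:-2
Rscript inst/cli/dibkit analyze-raman  --in spectra/ --out ratios.csv
Rscript inst/cli/dibkit run            --config study.json --out report/
```

`run` executes all assays for a list of conditions (lipid system ×
isoflavone × mole ratio) and writes `pf_summary.csv`, `dsc_summary.csv`,
`raman_summary.csv` and a `manifest.json` with seeds and checksums;
reruns with the same seed are byte-identical.

## Layout

- `R/synthetic-*.R` — seeded generators (DIB trajectories, thermograms,
  spectra) and the Raman amplitude calibration helper
- `R/geometry.R`, `R/imaging.R` — truncated-sphere geometry, frame
  rendering, sub-pixel circle fitting, identity-preserving tracking
- `R/permeability.R`, `R/dsc.R`, `R/raman.R` — the three analyzers
- `R/io.R`, `R/study.R`, `R/cli.R` — interchange, orchestration, CLI
- `vignettes/membrane-assays.Rmd` — models, assumptions, numerical
  choices and limitations
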