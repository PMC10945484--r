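# Shared fixtures and independent oracles.

# Slice-integration oracle for the truncated-sphere volume: integrate the
# circular cross-sections pi * (R^2 - z^2) from the far pole up to the
# bilayer plane at z = +sqrt(R^2 - rc^2).  Independent of the closed form
# used by the package.
slice_volume_oracle <- function(R, rc) {
  zmax <- sqrt(R^2 - rc^2)
  stats::integrate(function(z) pi * (R^2 - z^2), lower = -R, upper = zmax,
                   rel.tol = 1e-10)$value
}

# Control-geometry trajectory config used across tests.
control_dib_config <- function(...) {
  args <- list(initial_radius_1 = 50, initial_radius_2 = 50,
               initial_contact_radius = 30,
               osmolality_1 = 0, osmolality_2 = 0.2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dib_sim_config, args)
}

# Noiseless control endotherm with the instrument baseline used by the
# acceptance fixture.
control_dsc_config <- function(...) {
  args <- list(baseline_slope = 0.01, baseline_intercept = 0.2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dsc_sim_config, args)
}

run_dsc_pipeline <- function(config) {
  transition_metrics(subtract_baseline(heatflow_to_molar_cp(
    suppressWarnings(simulate_thermogram(config)))))
}

run_raman_pipeline <- function(spectrum) {
  band_ratios(normalize_at(baseline_correct(spectrum)))
}

# Osmole content per droplet along a trajectory, from the noiseless truth
# table (osmolarity times volume; constant when solute is conserved).
osmole_content <- function(traj) {
  tr <- attr(traj, "truth")
  list(n1 = tr$c1_osmol_L * tr$V1_um3, n2 = tr$c2_osmol_L * tr$V2_um3)
}
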