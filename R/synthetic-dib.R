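# Synthetic droplet-interface-bilayer (DIB) trajectories.
#
# Two monolayer-coated aqueous droplets adhere across a bilayer disc; an
# osmolarity difference drives water across the bilayer and the hypotonic
# droplet shrinks.  The simulator integrates the single-state ODE
#
#   dV1/dt = -Pf * v_w * A(t) * (c2(t) - c1(t))
#
# with per-droplet osmole content conserved and total water volume
# conserved (V2 = Vtot - V1 by construction), then converts volumes back
# to measurable radii under the chosen shrinkage geometry.

# Unit bridge: Pf [um/s] * A [um^2] * v_w [cm^3/mol] * dc [osmol/L]
#   -> dV/dt [um^3/s].  v_w cm^3/mol = 1e12 um^3/mol; osmol/L = 1e-15
#   osmol/um^3; the product of the two powers of ten is 1e-3.
OSMOTIC_FLUX_UNIT <- 1e-3

#' Convert measured osmolality to the osmolarity convention used here
#'
#' Osmometers report mOsm/kg solvent; the flux law wants osmol/L solution.
#' For the dilute saline used in DIB work the two are identified via a
#' solution density of 1 kg/L, i.e. `osmol/L = mOsm/kg / 1000`.
#'
#' @param mosm_per_kg Measured osmolality (mOsm/kg).
#' @return Osmolarity (osmol/L).
#' @export
mosm_kg_to_osmol_L <- function(mosm_per_kg) {
  if (any(mosm_per_kg < 0)) stop("osmolality must be >= 0", call. = FALSE)
  mosm_per_kg / 1000
}

#' Ideal osmolarity of a NaCl solution
#'
#' @param molarity NaCl concentration (mol/L).
#' @param osmotic_coefficient Particles per formula unit; the ideal
#'   fully-dissociated default is 2.
#' @return Osmolarity (osmol/L); 0.1 M gives 0.2 by default.
#' @export
nacl_osmolarity <- function(molarity, osmotic_coefficient = 2) {
  if (any(molarity < 0)) stop("molarity must be >= 0", call. = FALSE)
  stopif_not_scalar(osmotic_coefficient, "osmotic_coefficient", positive = TRUE)
  molarity * osmotic_coefficient
}

#' Configuration for the DIB trajectory simulator
#'
#' Defaults describe the nominal experiment: a pair of 100 um diameter
#' droplets (radius 50 um) with a 30 um contact radius, one droplet pure
#' water and the other carrying a nominal 0.1 M NaCl load (0.2 osmol/L
#' ideal), observed at 1 s intervals for 60 s at 30 degC.
#'
#' @param initial_radius_1,initial_radius_2 Initial sphere radii (um).
#' @param initial_contact_radius Initial contact radius (um),
#'   `< min(radii)`.
#' @param osmolality_1,osmolality_2 Osmolarities of droplets 1 and 2
#'   (osmol/L; use [mosm_kg_to_osmol_L()] for osmometer readings).
#' @param true_Pf Ground-truth osmotic water permeability (um/s), >= 0.
#' @param v_w Molar volume of water (cm^3/mol).
#' @param duration Simulated time span (s).
#' @param sample_interval Sampling interval (s).
#' @param shrinkage_mode `"constant_contact_radius"` (bilayer disc pinned
#'   at its initial radius) or `"constant_contact_angle"` (droplet 1's
#'   contact angle held fixed so the disc shrinks with it).
#' @param noise_sd_radius SD of additive Gaussian measurement noise applied
#'   to all three reported radii after integration (um).
#' @param seed Integer seed for the noise draw; `NULL` for no seeding.
#' @return An object of class `dib_sim_config`.
#' @export
dib_sim_config <- function(initial_radius_1 = 50,
                           initial_radius_2 = 50,
                           initial_contact_radius = 30,
                           osmolality_1 = 0,
                           osmolality_2 = nacl_osmolarity(0.1),
                           true_Pf = 74,
                           v_w = 18,
                           duration = 60,
                           sample_interval = 1,
                           shrinkage_mode = c("constant_contact_radius",
                                              "constant_contact_angle"),
                           noise_sd_radius = 0,
                           seed = NULL) {
  shrinkage_mode <- match.arg(shrinkage_mode)
  stopif_not_scalar(initial_radius_1, "initial_radius_1", positive = TRUE)
  stopif_not_scalar(initial_radius_2, "initial_radius_2", positive = TRUE)
  stopif_not_scalar(initial_contact_radius, "initial_contact_radius",
                    nonneg = TRUE)
  if (initial_contact_radius >= min(initial_radius_1, initial_radius_2))
    stop("initial contact radius must be < min(initial radii)", call. = FALSE)
  stopif_not_scalar(osmolality_1, "osmolality_1", nonneg = TRUE)
  stopif_not_scalar(osmolality_2, "osmolality_2", nonneg = TRUE)
  stopif_not_scalar(true_Pf, "true_Pf", nonneg = TRUE)
  stopif_not_scalar(v_w, "v_w", positive = TRUE)
  stopif_not_scalar(duration, "duration", positive = TRUE)
  stopif_not_scalar(sample_interval, "sample_interval", positive = TRUE)
  stopif_not_scalar(noise_sd_radius, "noise_sd_radius", nonneg = TRUE)
  structure(list(initial_radius_1 = initial_radius_1,
                 initial_radius_2 = initial_radius_2,
                 initial_contact_radius = initial_contact_radius,
                 osmolality_1 = osmolality_1,
                 osmolality_2 = osmolality_2,
                 true_Pf = true_Pf, v_w = v_w,
                 duration = duration, sample_interval = sample_interval,
                 shrinkage_mode = shrinkage_mode,
                 noise_sd_radius = noise_sd_radius, seed = seed),
            class = "dib_sim_config")
}

# Bilayer area as a function of the droplet volumes under a shrinkage
# mode.  Closed-form in both modes, so the ODE right-hand side never
# root-solves.
dib_area_map <- function(mode, R1_0, R2_0, rc_0) {
  if (mode == "constant_contact_radius") {
    area0 <- pi * rc_0^2
    function(V1, V2) area0
  } else {
    sin_th1 <- rc_0 / R1_0
    g1 <- truncated_sphere_volume(1, sin_th1)
    function(V1, V2) pi * sin_th1^2 * (V1 / g1)^(2 / 3)
  }
}

# Map droplet-1 volume to the instantaneous pair geometry under a
# shrinkage mode.  Returns list(R1, R2, rc, area).
dib_geometry_map <- function(mode, R1_0, R2_0, rc_0) {
  if (mode == "constant_contact_radius") {
    function(V1, V2) {
      R1 <- radius_from_volume(V1, rc_0)
      R2 <- radius_from_volume(V2, rc_0)
      list(R1 = R1, R2 = R2, rc = rc_0, area = pi * rc_0^2)
    }
  } else {
    # droplet 1's contact angle asin(rc/R1) pinned at its initial value;
    # unit-sphere truncated volume factor g1 makes V1 -> R1 closed-form
    sin_th1 <- rc_0 / R1_0
    g1 <- truncated_sphere_volume(1, sin_th1)
    function(V1, V2) {
      R1 <- (V1 / g1)^(1 / 3)
      rc <- R1 * sin_th1
      R2 <- radius_from_volume(V2, rc)
      list(R1 = R1, R2 = R2, rc = rc, area = pi * rc^2)
    }
  }
}

#' Simulate a DIB droplet-pair shrinkage trajectory
#'
#' Forward-integrates the osmotic volume-flux ODE (adaptive Runge-Kutta
#' 4(5), relative tolerance 1e-8) from the configured initial geometry.
#' Solute amount in each droplet and the total water volume of the pair
#' are conserved by construction; measurement noise, when requested, is
#' added to the radii after integration, reproducibly from `seed`.
#'
#' @param config A [dib_sim_config()].
#' @return A `dib_trajectory`: a data frame with columns `time_s`,
#'   `R1_um`, `R2_um`, `rc_um`, carrying attributes `conditions` (an
#'   [osmotic_conditions()]), `config`, and `truth` (the noiseless state
#'   table with volumes and osmolarities).
#' @examples
#' traj <- simulate_dib_trajectory(dib_sim_config(duration = 10))
#' head(traj)
#' @export
simulate_dib_trajectory <- function(config) {
  stopifnot(inherits(config, "dib_sim_config"))
  rc0 <- config$initial_contact_radius
  V1_0 <- truncated_sphere_volume(config$initial_radius_1, rc0)
  V2_0 <- truncated_sphere_volume(config$initial_radius_2, rc0)
  Vtot <- V1_0 + V2_0
  n1 <- config$osmolality_1 * V1_0   # osmol um^3 / L (fixed)
  n2 <- config$osmolality_2 * V2_0
  geom <- dib_geometry_map(config$shrinkage_mode,
                           config$initial_radius_1,
                           config$initial_radius_2, rc0)
  times <- seq(0, config$duration, by = config$sample_interval)

  area_of <- dib_area_map(config$shrinkage_mode, config$initial_radius_1,
                          config$initial_radius_2, rc0)
  if (config$true_Pf == 0 || config$osmolality_1 == config$osmolality_2) {
    V1 <- rep(V1_0, length(times))
  } else {
    rhs <- function(t, V1) {
      c1 <- n1 / V1
      c2 <- n2 / (Vtot - V1)
      -config$true_Pf * config$v_w * OSMOTIC_FLUX_UNIT *
        area_of(V1, Vtot - V1) * (c2 - c1)
    }
    V1 <- drop(rk45_integrate(rhs, V1_0, times, rtol = 1e-8,
                              atol = 1e-8 * V1_0))
  }
  V2 <- Vtot - V1

  g <- lapply(seq_along(times), function(i) geom(V1[i], V2[i]))
  R1 <- vapply(g, `[[`, numeric(1), "R1")
  R2 <- vapply(g, `[[`, numeric(1), "R2")
  rc <- vapply(g, `[[`, numeric(1), "rc")

  truth <- data.frame(time_s = times, R1_um = R1, R2_um = R2, rc_um = rc,
                      V1_um3 = V1, V2_um3 = V2,
                      c1_osmol_L = ifelse(V1 > 0, n1 / V1, NA_real_),
                      c2_osmol_L = n2 / V2)

  if (config$noise_sd_radius > 0) {
    noise <- with_seed(config$seed,
                       matrix(stats::rnorm(3 * length(times), 0,
                                           config$noise_sd_radius),
                              ncol = 3))
    R1 <- R1 + noise[, 1]
    R2 <- R2 + noise[, 2]
    rc <- rc + noise[, 3]
  }

  out <- data.frame(time_s = times, R1_um = R1, R2_um = R2, rc_um = rc)
  attr(out, "conditions") <- osmotic_conditions(config$osmolality_1,
                                                config$osmolality_2,
                                                v_w = config$v_w)
  attr(out, "config") <- config
  attr(out, "truth") <- truth
  class(out) <- c("dib_trajectory", "data.frame")
  out
}
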