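# Inference of the osmotic water permeability coefficient Pf from
# droplet-pair trajectories.
#
# The observable fitted is the volume of the hypotonic (shrinking)
# droplet, reconstructed from the measured radii by truncated-sphere
# geometry; the flux law is linear in volume, which makes the inverse
# problem a one-parameter least squares.

#' Osmotic conditions of a droplet pair
#'
#' @param osmolality_1,osmolality_2 Initial osmolarities of droplets 1
#'   and 2 (osmol/L; see [mosm_kg_to_osmol_L()]).
#' @param v_w Molar volume of water (cm^3/mol).
#' @param temperature Bath temperature (degC); metadata only.
#' @return An object of class `osmotic_conditions`.
#' @export
osmotic_conditions <- function(osmolality_1, osmolality_2, v_w = 18,
                               temperature = 30) {
  stopif_not_scalar(osmolality_1, "osmolality_1", nonneg = TRUE)
  stopif_not_scalar(osmolality_2, "osmolality_2", nonneg = TRUE)
  stopif_not_scalar(v_w, "v_w", positive = TRUE)
  stopif_not_scalar(temperature, "temperature")
  structure(list(osmolality_1 = osmolality_1, osmolality_2 = osmolality_2,
                 v_w = v_w, temperature = temperature),
            class = "osmotic_conditions")
}

#' Osmotic volume flux across the bilayer disc
#'
#' Instantaneous rate of change of droplet 1's volume,
#' `dV1/dt = -Pf * v_w * A * (c2 - c1)` with `A = pi * rc^2`, in
#' um^3/s.  Antisymmetric by construction: droplet 2 gains what droplet 1
#' loses.  Water flows toward the higher osmolarity, so a hypotonic
#' droplet 1 (`c1 < c2`) shrinks.
#'
#' @param state A [droplet_pair_state()] (only `rc` enters the flux).
#' @param conditions An [osmotic_conditions()] giving the instantaneous
#'   osmolarities `c1`, `c2` (osmol/L) and `v_w`.
#' @param Pf Permeability coefficient (um/s).
#' @return `dV1/dt` (um^3/s).
#' @examples
#' st <- droplet_pair_state(50, 50, 30)
#' osmotic_flux_model(st, osmotic_conditions(0, 0.2), Pf = 74)  # ~ -753
#' @export
osmotic_flux_model <- function(state, conditions, Pf) {
  stopifnot(inherits(state, "droplet_pair_state"),
            inherits(conditions, "osmotic_conditions"))
  stopif_not_scalar(Pf, "Pf", nonneg = TRUE)
  -Pf * conditions$v_w * OSMOTIC_FLUX_UNIT * contact_area(state$rc) *
    (conditions$osmolality_2 - conditions$osmolality_1)
}

permeability_estimate <- function(Pf, stderr, method, residual_rms,
                                  n_points) {
  structure(list(Pf = Pf, stderr = stderr, method = method,
                 residual_rms = residual_rms, n_points = n_points),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("<permeability_estimate> Pf = %.3f +/- %.3f um/s (%s, n = %d, rms = %.3g um^3)\n",
              x$Pf, x$stderr, x$method, x$n_points, x$residual_rms))
  invisible(x)
}

# Reconstruct per-frame droplet volumes from a trajectory table.
# For the pinned-disc geometry the contact radius is physically constant,
# so its trajectory mean is used to suppress measurement noise.
trajectory_volumes <- function(traj, rc_mode = c("mean", "per_frame")) {
  rc_mode <- match.arg(rc_mode)
  rc <- if (rc_mode == "mean") rep(mean(traj$rc_um), nrow(traj)) else traj$rc_um
  rc <- pmin(rc, pmin(traj$R1_um, traj$R2_um) * (1 - 1e-9))
  rc <- pmax(rc, 0)
  list(V1 = truncated_sphere_volume(traj$R1_um, rc),
       V2 = truncated_sphere_volume(traj$R2_um, rc),
       rc = rc)
}

# Which trajectory column holds the hypotonic (shrinking) droplet.
hypotonic_index <- function(conditions) {
  if (conditions$osmolality_1 <= conditions$osmolality_2) 1L else 2L
}

check_trajectory <- function(traj, min_points = 2L) {
  stopifnot(is.data.frame(traj))
  need <- c("time_s", "R1_um", "R2_um", "rc_um")
  if (!all(need %in% names(traj)))
    stop("trajectory must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(traj) < min_points)
    stop("trajectory must have at least ", min_points, " points",
         call. = FALSE)
  if (is.unsorted(traj$time_s, strictly = TRUE))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  invisible(traj)
}

#' Initial-rate estimate of Pf
#'
#' Linear fit of the hypotonic droplet's volume over the first `window`
#' samples; `Pf = |slope| / (v_w * A(0) * |dc(0)|)`.  Quick and slightly
#' biased low on long windows (the osmotic gradient decays); use
#' [estimate_pf_ode_fit()] for the definitive estimate.
#'
#' @param traj A trajectory data frame (`time_s`, `R1_um`, `R2_um`,
#'   `rc_um`).
#' @param conditions An [osmotic_conditions()].
#' @param window Number of leading samples in the fit, >= 2.
#' @return A `permeability_estimate`.
#' @export
estimate_pf_initial_rate <- function(traj, conditions, window = 5L) {
  stopifnot(inherits(conditions, "osmotic_conditions"))
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  check_trajectory(traj, min_points = window)
  dc0 <- abs(conditions$osmolality_2 - conditions$osmolality_1)
  if (dc0 == 0)
    stop("Pf is undefined at zero osmotic gradient (dc(0) = 0)",
         call. = FALSE)
  vols <- trajectory_volumes(traj)
  hyp <- hypotonic_index(conditions)
  V <- if (hyp == 1L) vols$V1 else vols$V2
  idx <- seq_len(window)
  fit <- stats::lm(V[idx] ~ traj$time_s[idx])
  slope <- stats::coef(fit)[[2L]]
  se <- summary(fit)$coefficients[2L, 2L]
  denom <- conditions$v_w * OSMOTIC_FLUX_UNIT * contact_area(vols$rc[1L]) * dc0
  permeability_estimate(Pf = abs(slope) / denom,
                        stderr = se / denom,
                        method = "initial_rate",
                        residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                        n_points = window)
}

#' ODE-fit estimate of Pf
#'
#' Finds the `Pf` minimising the sum of squared differences between the
#' observed hypotonic-droplet volume and the forward-integrated osmotic
#' flux model (the same ODE as the simulator), with solute content per
#' droplet fixed by the initial volumes and osmolarities.  The search is
#' one-dimensional on `[0, 1e4]` um/s, initialised from the initial-rate
#' estimate; the standard error comes from the curvature of the residual
#' sum of squares at the optimum.
#'
#' @inheritParams estimate_pf_initial_rate
#' @param shrinkage_mode Geometry assumed during re-integration; match the
#'   acquisition geometry (`"constant_contact_radius"` default).
#' @return A `permeability_estimate`.
#' @export
estimate_pf_ode_fit <- function(traj, conditions,
                                shrinkage_mode = c("constant_contact_radius",
                                                   "constant_contact_angle")) {
  shrinkage_mode <- match.arg(shrinkage_mode)
  stopifnot(inherits(conditions, "osmotic_conditions"))
  check_trajectory(traj, min_points = 3L)
  if (conditions$osmolality_1 == conditions$osmolality_2)
    stop("Pf is undefined at zero osmotic gradient (dc(0) = 0)",
         call. = FALSE)
  vols <- trajectory_volumes(
    traj,
    rc_mode = if (shrinkage_mode == "constant_contact_radius") "mean"
              else "per_frame")
  hyp <- hypotonic_index(conditions)
  Vobs <- if (hyp == 1L) vols$V1 else vols$V2
  Vtot <- vols$V1[1L] + vols$V2[1L]
  n_hyp <- (if (hyp == 1L) conditions$osmolality_1
            else conditions$osmolality_2) * Vobs[1L]
  n_oth <- (if (hyp == 1L) conditions$osmolality_2
            else conditions$osmolality_1) * (Vtot - Vobs[1L])
  R_hyp0 <- if (hyp == 1L) traj$R1_um[1L] else traj$R2_um[1L]
  R_oth0 <- if (hyp == 1L) traj$R2_um[1L] else traj$R1_um[1L]
  area_of <- dib_area_map(shrinkage_mode, R_hyp0, R_oth0, vols$rc[1L])
  times <- traj$time_s
  t0_offset <- times - times[1L]

  forward <- function(Pf, V0) {
    if (Pf == 0) return(rep(V0, length(times)))
    rhs <- function(t, V) {
      # hypotonic droplet shrinks: its concentration n_hyp/V stays below
      # the partner's, flux sign handled by the antisymmetric law
      -Pf * conditions$v_w * OSMOTIC_FLUX_UNIT * area_of(V, Vtot - V) *
        (n_oth / (Vtot - V) - n_hyp / V)
    }
    drop(rk45_integrate(rhs, V0, t0_offset, rtol = 1e-8, atol = 1e-8 * V0))
  }
  # theta = (Pf, V0): the initial volume is a nuisance parameter -- the
  # measured V(0) carries the same noise as every other sample, and
  # anchoring the model to it would propagate that noise into Pf.
  # Unphysical trials (droplet emptied mid-integration) get a huge SSR so
  # the optimiser retreats instead of aborting.
  ssr <- function(theta) tryCatch(sum((Vobs - forward(theta[1L],
                                                      theta[2L]))^2),
                                  error = function(e) 1e300)

  # profile SSR over Pf: for each trial Pf the nuisance V0 is solved by a
  # mean-residual fixed point (dV(t)/dV0 is ~1, so the mean residual is a
  # near-exact Newton step)
  V0_cache <- Vobs[1L]
  prof <- function(Pf) {
    V0 <- V0_cache
    Vm <- NULL
    for (it in seq_len(8L)) {
      Vm <- tryCatch(forward(Pf, V0), error = function(e) NULL)
      if (is.null(Vm)) return(1e300)
      delta <- mean(Vobs - Vm)
      if (abs(delta) < 1e-9 * Vobs[1L]) break
      V0 <- min(max(V0 + delta, 0.2 * Vobs[1L]), 5 * Vobs[1L])
      if (it == 8L) Vm <- tryCatch(forward(Pf, V0), error = function(e) Vm)
    }
    V0_cache <<- V0
    sum((Vobs - Vm)^2)
  }

  init_pf <- tryCatch(
    estimate_pf_initial_rate(traj, conditions,
                             window = min(5L, nrow(traj)))$Pf,
    error = function(e) 50)
  init_pf <- min(max(init_pf, 1), 1e3)
  upper <- min(1e4, max(20 * init_pf, 200))
  # coarse log-grid bracket of the global minimum, then golden section in
  # the bracketing interval (the profile SSR can have spurious shallow
  # basins at implausibly large Pf on noisy data)
  grid <- exp(seq(log(max(0.25, init_pf / 20)), log(upper),
                  length.out = 25L))
  vals <- vapply(grid, prof, numeric(1))
  i_min <- which.min(vals)
  lo <- if (i_min == 1L) 0 else grid[i_min - 1L]
  hi <- if (i_min == length(grid)) upper else grid[i_min + 1L]
  opt <- stats::optimize(prof, interval = c(lo, hi),
                         tol = 1e-6 * max(init_pf, 1))
  Pf_hat <- opt$minimum
  if (Pf_hat > 0.999 * 1e4)
    stop("ODE fit failed to converge: Pf at the upper bound 1e4 um/s ",
         "(SSR = ", signif(opt$objective, 6), ")", call. = FALSE)

  n <- length(Vobs)
  h <- max(1e-3, 1e-3 * Pf_hat)
  curv <- (prof(Pf_hat + h) - 2 * opt$objective +
             prof(max(Pf_hat - h, 0))) / h^2
  sigma2 <- opt$objective / max(n - 2L, 1L)
  stderr <- if (is.finite(curv) && curv > 0) sqrt(2 * sigma2 / curv)
            else NA_real_
  permeability_estimate(Pf = Pf_hat, stderr = stderr, method = "ode_fit",
                        residual_rms = sqrt(opt$objective / n),
                        n_points = n)
}

#' Aggregate replicate Pf estimates for one condition
#'
#' @param estimates List of `permeability_estimate` objects (or a numeric
#'   vector of Pf values).
#' @param label Condition label (e.g. lipid system / isoflavone / mole
#'   ratio).
#' @return A `replicate_summary` with `mean_Pf`, `sem` (sample SD /
#'   sqrt(n); 0 when n = 1), `n`, `label`.
#' @export
aggregate_condition <- function(estimates, label = "") {
  if (length(estimates) == 0L)
    stop("no estimates to aggregate", call. = FALSE)
  pf <- if (is.numeric(estimates)) estimates
        else vapply(estimates, function(e) e$Pf, numeric(1))
  n <- length(pf)
  structure(list(mean_Pf = mean(pf),
                 sem = if (n == 1L) 0 else stats::sd(pf) / sqrt(n),
                 n = n, label = label),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %s: Pf = %.2f +/- %.2f um/s (mean +/- SEM, n = %d)\n",
              x$label, x$mean_Pf, x$sem, x$n))
  invisible(x)
}

#' Percent change of a permeability relative to its control
#'
#' `100 * (Pf - Pf_control) / Pf_control`; round to the nearest integer
#' for reporting at the granularity of "about 27 percent".
#'
#' @param Pf_condition,Pf_control Permeabilities (um/s); control > 0.
#'   Vectorised over `Pf_condition`.
#' @return Percent change (signed).
#' @export
percent_change <- function(Pf_condition, Pf_control) {
  stopif_not_scalar(Pf_control, "Pf_control", positive = TRUE)
  100 * (Pf_condition - Pf_control) / Pf_control
}
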