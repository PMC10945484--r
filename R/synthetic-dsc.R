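# Synthetic DSC endotherms.
#
# The generator works in molar excess heat capacity space (kcal/mol/degC),
# where the transition peak has an exactly known apex (Tm), area (dH) and
# full width at half maximum (dT_1/2), then converts to instrument heat
# flow (mW, endotherm-up) via the scan rate and sample amount and adds a
# linear instrument baseline and optional Gaussian noise.

J_PER_KCAL <- 4184

# Default sample amount: 15 uL of a 16 mg/mL DOPC suspension, molecular
# weight 786.1 g/mol -> 3.05e-7 mol.
default_dsc_moles <- function(volume_uL = 15, conc_mg_mL = 16, mw = 786.1) {
  volume_uL * 1e-3 * conc_mg_mL * 1e-3 / mw * 1e3  # (uL * mg/mL -> g) / MW
}

#' Configuration for the DSC thermogram simulator
#'
#' Defaults describe the control DOPC endotherm: main transition at
#' -17.08 degC with enthalpy 8.76 kcal/mol and width at half height
#' 2.04 degC, scanned at 5 degC/min from -40 to 0 degC on a 15 uL,
#' 16 mg/mL sample (3.05e-7 mol of lipid).
#'
#' @param Tm_true Apex temperature (degC), inside `T_range`.
#' @param dH_true Transition enthalpy (kcal/mol), > 0.
#' @param dT_half_true Full width at half maximum (degC), > 0.
#' @param peak_shape `"gaussian"` or `"skewed_gaussian"`.
#' @param skew Skew-normal shape parameter (0 = symmetric); only used for
#'   `"skewed_gaussian"`.
#' @param baseline_slope,baseline_intercept Linear instrument baseline in
#'   heat-flow units (mW/degC, mW).
#' @param scan_rate Heating rate (degC/min).
#' @param sample_moles Amount of lipid in the pan (mol).
#' @param T_range Temperature span `c(lo, hi)` (degC).
#' @param T_step Temperature grid step (degC).
#' @param noise_sd SD of additive Gaussian heat-flow noise (mW).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `dsc_sim_config`.
#' @export
dsc_sim_config <- function(Tm_true = -17.08,
                           dH_true = 8.76,
                           dT_half_true = 2.04,
                           peak_shape = c("gaussian", "skewed_gaussian"),
                           skew = 0,
                           baseline_slope = 0,
                           baseline_intercept = 0,
                           scan_rate = 5,
                           sample_moles = default_dsc_moles(),
                           T_range = c(-40, 0),
                           T_step = 0.02,
                           noise_sd = 0,
                           seed = NULL) {
  peak_shape <- match.arg(peak_shape)
  stopif_not_scalar(Tm_true, "Tm_true")
  stopif_not_scalar(dH_true, "dH_true", positive = TRUE)
  stopif_not_scalar(dT_half_true, "dT_half_true", positive = TRUE)
  stopif_not_scalar(skew, "skew")
  stopif_not_scalar(scan_rate, "scan_rate", positive = TRUE)
  stopif_not_scalar(sample_moles, "sample_moles", positive = TRUE)
  stopif_not_scalar(T_step, "T_step", positive = TRUE)
  stopif_not_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(T_range) != 2L || T_range[1L] >= T_range[2L])
    stop("T_range must be c(lo, hi) with lo < hi", call. = FALSE)
  if (Tm_true <= T_range[1L] || Tm_true >= T_range[2L])
    stop("Tm_true must lie inside T_range", call. = FALSE)
  structure(list(Tm_true = Tm_true, dH_true = dH_true,
                 dT_half_true = dT_half_true, peak_shape = peak_shape,
                 skew = skew, baseline_slope = baseline_slope,
                 baseline_intercept = baseline_intercept,
                 scan_rate = scan_rate, sample_moles = sample_moles,
                 T_range = T_range, T_step = T_step,
                 noise_sd = noise_sd, seed = seed),
            class = "dsc_sim_config")
}

# Excess-Cp peak function calibrated so apex = Tm, area = dH and
# FWHM = dT_half hold analytically (gaussian) or numerically to ~1e-10
# (skew-normal: mode and FWHM of the unit shape found by optimisation,
# then the axis is rescaled).
dsc_peak_function <- function(config) {
  Tm <- config$Tm_true; dH <- config$dH_true; fwhm <- config$dT_half_true
  if (config$peak_shape == "gaussian" || config$skew == 0) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    amp <- dH / (sigma * sqrt(2 * pi))
    return(function(T) amp * exp(-(T - Tm)^2 / (2 * sigma^2)))
  }
  a <- config$skew
  s <- function(x) 2 * stats::dnorm(x) * stats::pnorm(a * x)  # unit skew-normal
  mode <- stats::optimize(s, interval = c(-4, 4), maximum = TRUE,
                          tol = 1e-12)
  x_m <- mode$maximum; y_m <- mode$objective
  half <- function(x) s(x) - y_m / 2
  xl <- stats::uniroot(half, c(x_m - 10, x_m), tol = 1e-12)$root
  xr <- stats::uniroot(half, c(x_m, x_m + 10), tol = 1e-12)$root
  scale <- fwhm / (xr - xl)
  function(T) dH / scale * s(x_m + (T - Tm) / scale)
}

#' Simulate a DSC thermogram
#'
#' Builds the molar excess heat capacity peak from the configured
#' `(Tm, dH, dT_1/2)`, converts to endotherm-up heat flow (mW) using the
#' scan rate and sample amount, and adds the linear instrument baseline
#' and seeded Gaussian noise.  After exact baseline removal and
#' re-calibration, the noiseless peak reproduces the configured apex,
#' area and width to better than 0.1%.
#'
#' @param config A [dsc_sim_config()].
#' @return A `thermogram`: data frame with columns `temp_C`,
#'   `heatflow_mW` and attributes `scan_rate` (degC/min), `sample_moles`,
#'   `truth`, and `truncated` (TRUE with a warning when the apex or a
#'   half-height point falls outside `T_range`).
#' @export
simulate_thermogram <- function(config) {
  stopifnot(inherits(config, "dsc_sim_config"))
  temp <- seq(config$T_range[1L], config$T_range[2L], by = config$T_step)
  peak <- dsc_peak_function(config)
  cp <- peak(temp)

  truncated <- FALSE
  apex_cp <- peak(config$Tm_true)
  edge_cp <- peak(config$T_range)
  if (any(edge_cp > apex_cp / 2)) truncated <- TRUE
  if (truncated)
    warning("endotherm truncated by T_range: apex or half-height points ",
            "fall outside the scan window", call. = FALSE)

  rate_Cps <- config$scan_rate / 60
  hf <- cp * J_PER_KCAL * rate_Cps * config$sample_moles * 1e3  # mW
  hf <- hf + config$baseline_intercept + config$baseline_slope * temp
  if (config$noise_sd > 0)
    hf <- hf + with_seed(config$seed,
                         stats::rnorm(length(hf), 0, config$noise_sd))

  thermogram(temp, hf, scan_rate = config$scan_rate,
             sample_moles = config$sample_moles,
             truth = list(Tm = config$Tm_true, dH = config$dH_true,
                          dT_half = config$dT_half_true,
                          baseline = c(intercept = config$baseline_intercept,
                                       slope = config$baseline_slope)),
             truncated = truncated)
}

#' Construct a thermogram object
#'
#' @param temp_C Strictly monotone temperature grid (degC).
#' @param heatflow_mW Heat flow (mW, endotherm-up), same length.
#' @param scan_rate Scan rate (degC/min), > 0.
#' @param sample_moles Sample amount (mol), > 0.
#' @param truth Optional generator ground truth (kept as an attribute).
#' @param truncated Logical truncation flag.
#' @return A `thermogram` data frame.
#' @export
thermogram <- function(temp_C, heatflow_mW, scan_rate, sample_moles,
                       truth = NULL, truncated = FALSE) {
  if (length(temp_C) != length(heatflow_mW))
    stop("temperature and heat-flow arrays must have equal length",
         call. = FALSE)
  if (length(temp_C) < 2L || is.unsorted(temp_C, strictly = TRUE))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  stopif_not_scalar(scan_rate, "scan_rate", positive = TRUE)
  stopif_not_scalar(sample_moles, "sample_moles", positive = TRUE)
  out <- data.frame(temp_C = temp_C, heatflow_mW = heatflow_mW)
  attr(out, "scan_rate") <- scan_rate
  attr(out, "sample_moles") <- sample_moles
  attr(out, "truth") <- truth
  attr(out, "truncated") <- truncated
  class(out) <- c("thermogram", "data.frame")
  out
}
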