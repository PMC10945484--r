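# Synthetic Raman spectra.
#
# A spectrum is a sum of Gaussian/Lorentzian bands on a polynomial
# baseline plus optional Gaussian noise.  Band widths are FWHM in cm^-1.
# The polynomial baseline is evaluated in the normalised coordinate
# u = (wavenumber - midrange) / (halfspan), u in [-1, 1], so coefficients
# stay O(1).

#' Raman band table for a DOPC bilayer
#'
#' Characteristic bands of the DOPC spectrum: fingerprint-region CH2
#' twist (~1300), CH2 scissoring (~1440), C=C stretch (~1650), an
#' optional isoflavone ring mode (~1614, amplitude 0 unless requested),
#' and the C-H stretching triplet used for packing-order ratios: CH2
#' symmetric (~2848), CH2 asymmetric (~2890) and terminal CH3 (~2930).
#'
#' @param region `"ch"` (2700-3100 cm^-1 triplet only, the default),
#'   `"fingerprint"`, or `"all"`.
#' @param isoflavone_amplitude Amplitude of the 1614 cm^-1 ring mode
#'   (only present for `"fingerprint"`/`"all"`).
#' @return Data frame with columns `center`, `width`, `amplitude`,
#'   `shape`.
#' @export
dopc_band_table <- function(region = c("ch", "fingerprint", "all"),
                            isoflavone_amplitude = 0) {
  region <- match.arg(region)
  ch <- data.frame(center = c(2848, 2890, 2930),
                   width = c(15, 15, 15),
                   amplitude = c(1, 0.85, 0.8),
                   shape = "gaussian")
  fp <- data.frame(center = c(1300, 1440, 1614, 1650),
                   width = c(20, 20, 12, 20),
                   amplitude = c(0.4, 0.6, isoflavone_amplitude, 0.5),
                   shape = "gaussian")
  switch(region, ch = ch, fingerprint = fp, all = rbind(fp, ch))
}

#' Configuration for the Raman spectrum simulator
#'
#' @param band_table Data frame with columns `center` (cm^-1), `width`
#'   (FWHM, cm^-1), `amplitude` (>= 0), `shape`
#'   (`"gaussian"`/`"lorentzian"`); all centers must lie inside
#'   `wavenumber_range`.
#' @param baseline_poly_coeffs Polynomial baseline coefficients (constant
#'   first) in the normalised coordinate `u in [-1, 1]`.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param wavenumber_range `c(lo, hi)` (cm^-1).
#' @param step Grid step (cm^-1), > 0.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `raman_sim_config`.
#' @export
raman_sim_config <- function(band_table = dopc_band_table(),
                             baseline_poly_coeffs = 0,
                             noise_sd = 0,
                             wavenumber_range = c(2700, 3100),
                             step = 0.5,
                             seed = NULL) {
  stopifnot(is.data.frame(band_table),
            all(c("center", "width", "amplitude", "shape") %in%
                  names(band_table)))
  if (length(wavenumber_range) != 2L ||
      wavenumber_range[1L] >= wavenumber_range[2L])
    stop("wavenumber_range must be c(lo, hi) with lo < hi", call. = FALSE)
  stopif_not_scalar(step, "step", positive = TRUE)
  stopif_not_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(band_table$width <= 0)) stop("band widths must be > 0",
                                       call. = FALSE)
  if (any(band_table$amplitude < 0)) stop("band amplitudes must be >= 0",
                                          call. = FALSE)
  if (any(band_table$center <= wavenumber_range[1L] |
            band_table$center >= wavenumber_range[2L]))
    stop("band centers must lie inside wavenumber_range", call. = FALSE)
  if (!all(band_table$shape %in% c("gaussian", "lorentzian")))
    stop("band shapes must be 'gaussian' or 'lorentzian'", call. = FALSE)
  structure(list(band_table = band_table,
                 baseline_poly_coeffs = baseline_poly_coeffs,
                 noise_sd = noise_sd,
                 wavenumber_range = wavenumber_range,
                 step = step, seed = seed),
            class = "raman_sim_config")
}

raman_band_profile <- function(x, center, width, amplitude, shape) {
  if (shape == "gaussian") {
    sigma <- width / (2 * sqrt(2 * log(2)))
    amplitude * exp(-(x - center)^2 / (2 * sigma^2))
  } else {
    gamma <- width / 2
    amplitude / (1 + ((x - center) / gamma)^2)
  }
}

raman_baseline_eval <- function(x, coeffs, range) {
  u <- (x - mean(range)) / (diff(range) / 2)
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Simulate a Raman spectrum
#'
#' Sum of the configured bands plus the polynomial baseline and seeded
#' Gaussian noise, on a uniform wavenumber grid.
#'
#' @param config A [raman_sim_config()].
#' @return A `raman_spectrum` data frame (`wavenumber_cm1`, `intensity`)
#'   with the generator ground truth in the `truth` attribute.
#' @export
simulate_raman_spectrum <- function(config) {
  stopifnot(inherits(config, "raman_sim_config"))
  x <- seq(config$wavenumber_range[1L], config$wavenumber_range[2L],
           by = config$step)
  y <- rep(0, length(x))
  bt <- config$band_table
  for (i in seq_len(nrow(bt)))
    y <- y + raman_band_profile(x, bt$center[i], bt$width[i],
                                bt$amplitude[i], bt$shape[i])
  y <- y + raman_baseline_eval(x, config$baseline_poly_coeffs,
                               config$wavenumber_range)
  if (config$noise_sd > 0)
    y <- y + with_seed(config$seed,
                       stats::rnorm(length(y), 0, config$noise_sd))
  raman_spectrum(x, y, truth = list(band_table = bt,
                                    baseline_poly_coeffs =
                                      config$baseline_poly_coeffs))
}

#' Construct a Raman spectrum object
#'
#' @param wavenumber_cm1 Strictly increasing wavenumbers (cm^-1).
#' @param intensity Finite intensities, same length.
#' @param truth Optional generator ground truth attribute.
#' @return A `raman_spectrum` data frame.
#' @export
raman_spectrum <- function(wavenumber_cm1, intensity, truth = NULL) {
  if (length(wavenumber_cm1) != length(intensity))
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  if (is.unsorted(wavenumber_cm1, strictly = TRUE))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  out <- data.frame(wavenumber_cm1 = wavenumber_cm1, intensity = intensity)
  attr(out, "truth") <- truth
  class(out) <- c("raman_spectrum", "data.frame")
  out
}

#' Tune C-H band amplitudes to hit target intensity ratios
#'
#' The three C-H stretching bands overlap, so the measured composite peak
#' heights are not the configured amplitudes.  This helper adjusts the
#' 2890 and 2930 cm^-1 amplitudes (holding 2848 fixed) by fixed-point
#' iteration until the ratios measured by the full analysis pipeline
#' ([baseline_correct()], [normalize_at()], [band_ratios()]) on the
#' noiseless spectrum equal the targets.
#'
#' @param config A [raman_sim_config()] whose band table contains bands
#'   at 2848, 2890 and 2930 cm^-1.
#' @param target_2930_2848,target_2930_2890 Target composite ratios.
#' @param tol Convergence tolerance on both ratios.
#' @param max_iter Maximum fixed-point iterations.
#' @return The config with tuned amplitudes.
#' @export
calibrate_band_amplitudes <- function(config,
                                      target_2930_2848 = 0.84,
                                      target_2930_2890 = 0.90,
                                      tol = 1e-6, max_iter = 60L) {
  stopifnot(inherits(config, "raman_sim_config"))
  bt <- config$band_table
  i848 <- which(bt$center == 2848)
  i890 <- which(bt$center == 2890)
  i930 <- which(bt$center == 2930)
  if (length(i848) != 1L || length(i890) != 1L || length(i930) != 1L)
    stop("band table must contain exactly one band each at 2848, 2890, ",
         "2930 cm^-1", call. = FALSE)

  measure <- function(cfg) {
    cfg$noise_sd <- 0
    sp <- simulate_raman_spectrum(cfg)
    sp <- baseline_correct(sp)
    sp <- normalize_at(sp)
    br <- band_ratios(sp)
    c(br$ratio_2930_2848, br$ratio_2930_2890,
      br$I_2848, br$I_2890, br$I_2930)
  }

  cfg <- config
  for (it in seq_len(max_iter)) {
    m <- measure(cfg)
    if (abs(m[1L] - target_2930_2848) < tol &&
        abs(m[2L] - target_2930_2890) < tol) {
      cfg$seed <- config$seed
      cfg$noise_sd <- config$noise_sd
      return(cfg)
    }
    # I2930 tracks r1 * I2848; I2890 then tracks I2930 / r2
    cfg$band_table$amplitude[i930] <- cfg$band_table$amplitude[i930] *
      (target_2930_2848 * m[3L]) / m[5L]
    cfg$band_table$amplitude[i890] <- cfg$band_table$amplitude[i890] *
      (target_2930_2848 * m[3L] / target_2930_2890) / m[4L]
  }
  stop("amplitude calibration did not converge in ", max_iter,
       " iterations", call. = FALSE)
}
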