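# DSC thermogram analysis: calibration to molar excess heat capacity,
# linear two-window baseline subtraction, and transition metrics
# (Tm at the apex, dH as the integrated area, dT_1/2 as the width at
# half height).

#' Convert heat flow to molar excess heat capacity
#'
#' `Cp(T) = heatflow / scan_rate / sample_moles / 4184`, with the heat
#' flow in W and the scan rate in degC/s, giving kcal per mol per degC.
#'
#' @param tg A [thermogram()].
#' @return A `cp_trace`: data frame with `temp_C` and `cp_kcal_mol_C`.
#' @examples
#' tg <- simulate_thermogram(dsc_sim_config())
#' cp <- heatflow_to_molar_cp(tg)
#' @export
heatflow_to_molar_cp <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  rate_Cps <- attr(tg, "scan_rate") / 60
  cp <- tg$heatflow_mW * 1e-3 / rate_Cps / attr(tg, "sample_moles") /
    J_PER_KCAL
  out <- data.frame(temp_C = tg$temp_C, cp_kcal_mol_C = cp)
  attr(out, "scan_rate") <- attr(tg, "scan_rate")
  attr(out, "sample_moles") <- attr(tg, "sample_moles")
  attr(out, "truth") <- attr(tg, "truth")
  class(out) <- c("cp_trace", "data.frame")
  out
}

# Contiguous peak support around the global maximum: the run of points
# with value > frac * max that contains the argmax.
peak_support <- function(y, frac = 0.01) {
  i_max <- which.max(y)
  thr <- frac * y[i_max]
  lo <- i_max
  while (lo > 1L && y[lo - 1L] > thr) lo <- lo - 1L
  hi <- i_max
  while (hi < length(y) && y[hi + 1L] > thr) hi <- hi + 1L
  c(lo = lo, hi = hi, apex = i_max)
}

#' Subtract a linear two-window baseline
#'
#' Fits the straight line through the mean points of two peak-free
#' temperature windows flanking the transition and subtracts it.  Errors
#' if either window intersects the detected peak support (the contiguous
#' region above 1% of the provisional peak maximum).
#'
#' @param cp A `cp_trace` (see [heatflow_to_molar_cp()]).
#' @param pre_window,post_window Temperature windows `c(lo, hi)` (degC)
#'   below and above the transition.
#' @return The baseline-subtracted `cp_trace`; the fitted line is stored
#'   in the `baseline` attribute as `c(intercept, slope)`.
#' @export
subtract_baseline <- function(cp, pre_window = c(-35, -28),
                              post_window = c(-8, -2)) {
  stopifnot(inherits(cp, "cp_trace"))
  for (w in list(pre_window, post_window)) {
    if (length(w) != 2L || w[1L] >= w[2L])
      stop("baseline windows must be c(lo, hi) with lo < hi", call. = FALSE)
    if (w[1L] < min(cp$temp_C) || w[2L] > max(cp$temp_C))
      stop("baseline window [", w[1L], ", ", w[2L],
           "] falls outside the temperature grid", call. = FALSE)
  }
  in_pre <- cp$temp_C >= pre_window[1L] & cp$temp_C <= pre_window[2L]
  in_post <- cp$temp_C >= post_window[1L] & cp$temp_C <= post_window[2L]
  if (!any(in_pre) || !any(in_post))
    stop("baseline windows contain no grid points", call. = FALSE)

  x1 <- mean(cp$temp_C[in_pre]);  y1 <- mean(cp$cp_kcal_mol_C[in_pre])
  x2 <- mean(cp$temp_C[in_post]); y2 <- mean(cp$cp_kcal_mol_C[in_post])
  slope <- (y2 - y1) / (x2 - x1)
  intercept <- y1 - slope * x1
  corrected <- cp$cp_kcal_mol_C - (intercept + slope * cp$temp_C)

  sup <- peak_support(corrected)
  sup_T <- cp$temp_C[c(sup["lo"], sup["hi"])]
  overlaps <- function(w) sup_T[1L] <= w[2L] && w[1L] <= sup_T[2L]
  if (overlaps(pre_window) || overlaps(post_window))
    stop("baseline window overlaps the detected peak (support ",
         signif(sup_T[1L], 5), " to ", signif(sup_T[2L], 5), " degC)",
         call. = FALSE)

  out <- data.frame(temp_C = cp$temp_C, cp_kcal_mol_C = corrected)
  attr(out, "scan_rate") <- attr(cp, "scan_rate")
  attr(out, "sample_moles") <- attr(cp, "sample_moles")
  attr(out, "truth") <- attr(cp, "truth")
  attr(out, "baseline") <- c(intercept = intercept, slope = slope)
  class(out) <- c("cp_trace", "data.frame")
  out
}

#' Transition metrics from an excess heat capacity trace
#'
#' Locates the dominant endothermic peak and reports the apex temperature
#' `Tm` (3-point parabolic interpolation around the grid maximum), the
#' transition enthalpy `dH` (trapezoidal integral over the contiguous
#' support above 1% of the peak maximum), and the width at half height
#' `dT_half` (linear interpolation of the half-maximum crossings).
#'
#' @param cp A baseline-subtracted `cp_trace`.
#' @param min_snr Minimum ratio of peak height to flanking noise SD for a
#'   transition to be declared (default 5).
#' @return A `transition_metrics` object: list with `Tm` (degC), `dH`
#'   (kcal/mol), `dT_half` (degC), `baseline` (the parameters used, if
#'   any), and `support` (degC range integrated).
#' @export
transition_metrics <- function(cp, min_snr = 5) {
  stopifnot(inherits(cp, "cp_trace"))
  y <- cp$cp_kcal_mol_C
  temp <- cp$temp_C
  n <- length(y)
  if (n < 5L) stop("trace too short", call. = FALSE)

  # flanking noise from the outer 10% of points on each side
  k <- max(3L, floor(n * 0.1))
  flank <- c(y[seq_len(k)], y[seq.int(n - k + 1L, n)])
  noise_sd <- stats::mad(flank)

  sup <- peak_support(y)
  apex <- parabolic_vertex(temp, y, sup[["apex"]])
  if (apex[["y"]] <= 0 || (noise_sd > 0 && apex[["y"]] < min_snr * noise_sd))
    stop("no transition detected: peak height ", signif(apex[["y"]], 4),
         " below ", min_snr, "x flanking noise SD (", signif(noise_sd, 4),
         ")", call. = FALSE)

  # competing peaks: local maxima of comparable height outside the
  # support of the main peak
  inside <- seq.int(sup[["lo"]], sup[["hi"]])
  is_locmax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                   y[2:(n - 1)] >= y[3:n], FALSE)
  rivals <- setdiff(which(is_locmax & y >= 0.5 * y[sup[["apex"]]]), inside)
  if (length(rivals) > 0L)
    stop("ambiguous thermogram: competing peaks at ",
         paste(signif(temp[rivals], 5), collapse = ", "), " degC",
         call. = FALSE)

  dH <- trapz(temp[inside], y[inside])

  half <- apex[["y"]] / 2
  cross <- function(dir) {
    i <- sup[["apex"]]
    repeat {
      j <- i + dir
      if (j < 1L || j > n)
        stop("half-height point outside the temperature grid", call. = FALSE)
      if (y[j] < half) break
      i <- j
    }
    # linear interpolation between grid points i (above) and j (below)
    temp[i] + (half - y[i]) * (temp[j] - temp[i]) / (y[j] - y[i])
  }
  t_left <- cross(-1L)
  t_right <- cross(1L)

  structure(list(Tm = apex[["x"]], dH = dH, dT_half = t_right - t_left,
                 baseline = attr(cp, "baseline"),
                 support = temp[c(sup[["lo"]], sup[["hi"]])]),
            class = "transition_metrics")
}

#' @export
print.transition_metrics <- function(x, ...) {
  cat(sprintf("<transition_metrics> Tm = %.2f degC, dH = %.3f kcal/mol, dT_1/2 = %.3f degC\n",
              x$Tm, x$dH, x$dT_half))
  invisible(x)
}

#' Compare transition metrics to a control
#'
#' @param metrics,control `transition_metrics` objects; `control$dH > 0`.
#' @return A `control_comparison`: list with `dTm = Tm - Tm_control`
#'   (degC) and `dH_ratio = dH / dH_control`.
#' @export
compare_to_control <- function(metrics, control) {
  stopifnot(inherits(metrics, "transition_metrics"),
            inherits(control, "transition_metrics"))
  if (control$dH <= 0)
    stop("control enthalpy must be > 0", call. = FALSE)
  structure(list(dTm = metrics$Tm - control$Tm,
                 dH_ratio = metrics$dH / control$dH),
            class = "control_comparison")
}

#' @export
print.control_comparison <- function(x, ...) {
  cat(sprintf("<control_comparison> dTm = %.3f degC, dH/dH0 = %.4f\n",
              x$dTm, x$dH_ratio))
  invisible(x)
}
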