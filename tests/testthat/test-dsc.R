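test_that("heatflow-to-Cp calibration follows the unit chain", {
  # 1 mW at 5 degC/min over 3.05e-7 mol: 1e-3 / (5/60) / 3.05e-7 / 4184
  tg <- thermogram(c(-30, -20, -10), rep(1, 3), scan_rate = 5,
                   sample_moles = 3.05e-7)
  cp <- heatflow_to_molar_cp(tg)
  expect_equal(cp$cp_kcal_mol_C, rep(9.404, 3), tolerance = 1e-4)
  tg2 <- thermogram(c(-30, -20, -10), rep(1, 3), scan_rate = 10,
                    sample_moles = 3.05e-7)
  expect_equal(heatflow_to_molar_cp(tg2)$cp_kcal_mol_C,
               cp$cp_kcal_mol_C / 2)
  tg0 <- thermogram(c(-30, -20, -10), rep(0, 3), 5, 3.05e-7)
  expect_identical(heatflow_to_molar_cp(tg0)$cp_kcal_mol_C, rep(0, 3))
})

test_that("generator peak amplitude matches the Gaussian area/FWHM identity", {
  cfg <- dsc_sim_config(dH_true = 8.76, dT_half_true = 2.04)
  tg <- simulate_thermogram(cfg)
  cp <- heatflow_to_molar_cp(tg)
  sigma <- 2.04 / (2 * sqrt(2 * log(2)))
  expect_equal(max(cp$cp_kcal_mol_C), 8.76 / (sigma * sqrt(2 * pi)),
               tolerance = 1e-6)
  expect_equal(max(cp$cp_kcal_mol_C), 4.034, tolerance = 1e-3)
})

test_that("noiseless generator/analyzer round trip recovers the truth", {
  m <- run_dsc_pipeline(control_dsc_config())
  expect_lt(abs(m$Tm - (-17.08)), 0.02)
  expect_lt(abs(m$dH - 8.76) / 8.76, 0.005)
  expect_lt(abs(m$dT_half - 2.04), 0.02)
})

test_that("FWHM identity holds for a unit-sigma Gaussian", {
  fwhm <- 2 * sqrt(2 * log(2))
  m <- run_dsc_pipeline(dsc_sim_config(dT_half_true = fwhm))
  expect_equal(m$dT_half, 2.3548, tolerance = 1e-3)
})

test_that("apex location is robust to a half-step grid offset", {
  m1 <- run_dsc_pipeline(control_dsc_config())
  cfg2 <- control_dsc_config(T_range = c(-40.01, -0.01))
  m2 <- run_dsc_pipeline(cfg2)
  expect_lt(abs(m1$Tm - m2$Tm), 0.01)
})

test_that("sample amount scales heat flow but not recovered molar dH", {
  cfg1 <- control_dsc_config()
  cfg2 <- control_dsc_config(sample_moles = 2 * cfg1$sample_moles,
                             baseline_slope = 0, baseline_intercept = 0)
  cfg1b <- control_dsc_config(baseline_slope = 0, baseline_intercept = 0)
  tg1 <- simulate_thermogram(cfg1b)
  tg2 <- simulate_thermogram(cfg2)
  expect_equal(max(tg2$heatflow_mW), 2 * max(tg1$heatflow_mW))
  expect_equal(run_dsc_pipeline(cfg2)$dH, run_dsc_pipeline(cfg1b)$dH,
               tolerance = 1e-9)
})

test_that("skewed peaks keep the calibrated apex, area and width", {
  cfg <- control_dsc_config(peak_shape = "skewed_gaussian", skew = 3,
                            Tm_true = -17.08, dH_true = 8.76,
                            dT_half_true = 2.04)
  m <- run_dsc_pipeline(cfg)
  expect_lt(abs(m$Tm - (-17.08)), 0.02)
  expect_lt(abs(m$dH - 8.76) / 8.76, 0.005)
  expect_lt(abs(m$dT_half - 2.04), 0.02)
})

test_that("dH is invariant under random linear instrument baselines", {
  set.seed(11)
  for (i in 1:5) {
    cfg <- control_dsc_config(baseline_slope = runif(1, -0.05, 0.05),
                              baseline_intercept = runif(1, -1, 1))
    m <- run_dsc_pipeline(cfg)
    expect_lt(abs(m$dH - 8.76) / 8.76, 0.005)
  }
})

test_that("trace scaling moves dH linearly and leaves Tm, dT_half fixed", {
  tg <- simulate_thermogram(dsc_sim_config())
  cp <- heatflow_to_molar_cp(tg)
  m1 <- transition_metrics(cp)
  cp2 <- cp
  cp2$cp_kcal_mol_C <- cp$cp_kcal_mol_C * 3
  m2 <- transition_metrics(cp2)
  expect_equal(m2$Tm, m1$Tm)
  expect_equal(m2$dT_half, m1$dT_half, tolerance = 1e-9)
  expect_equal(m2$dH, 3 * m1$dH, tolerance = 1e-12)
})

test_that("metrics converge under grid refinement", {
  m_fine <- run_dsc_pipeline(control_dsc_config(T_step = 0.01))
  m_coarse <- run_dsc_pipeline(control_dsc_config(T_step = 0.05))
  expect_lt(abs(m_fine$Tm - m_coarse$Tm), 0.01)
  expect_lt(abs(m_fine$dT_half - m_coarse$dT_half), 0.01)
  expect_lt(abs(m_fine$dH - m_coarse$dH) / m_fine$dH, 0.002)
})

test_that("round-trip holds across the physiological parameter regime", {
  set.seed(5)
  for (i in 1:5) {
    Tm <- runif(1, -20, -15)
    dH <- runif(1, 4, 9)
    w <- runif(1, 1.5, 3.5)
    m <- run_dsc_pipeline(control_dsc_config(Tm_true = Tm, dH_true = dH,
                                             dT_half_true = w))
    expect_lt(abs(m$Tm - Tm), 0.02)
    expect_lt(abs(m$dH - dH) / dH, 0.005)
    expect_lt(abs(m$dT_half - w), 0.02)
  }
})

test_that("baseline windows inside the peak are rejected", {
  tg <- simulate_thermogram(control_dsc_config())
  cp <- heatflow_to_molar_cp(tg)
  expect_error(subtract_baseline(cp, pre_window = c(-18, -16),
                                 post_window = c(-8, -2)), "overlaps")
  expect_error(subtract_baseline(cp, pre_window = c(-60, -50),
                                 post_window = c(-8, -2)), "outside")
  # flat zero baseline leaves the trace unchanged
  tg0 <- simulate_thermogram(dsc_sim_config())
  cp0 <- heatflow_to_molar_cp(tg0)
  out <- subtract_baseline(cp0)
  expect_equal(out$cp_kcal_mol_C, cp0$cp_kcal_mol_C, tolerance = 1e-9)
})

test_that("truncated, absent and ambiguous peaks are flagged", {
  expect_warning(simulate_thermogram(dsc_sim_config(Tm_true = -0.5)),
                 "truncated")
  flat <- thermogram(seq(-40, 0, 0.1), rep(0, 401), 5, 3e-7)
  expect_error(transition_metrics(heatflow_to_molar_cp(flat)),
               "no transition")
  # two comparable peaks
  temp <- seq(-40, 0, 0.02)
  hf <- exp(-(temp + 25)^2 / 2) + 0.9 * exp(-(temp + 10)^2 / 2)
  two <- thermogram(temp, hf, 5, 3e-7)
  expect_error(transition_metrics(heatflow_to_molar_cp(two)), "competing")
})

test_that("compare_to_control reports dTm and the enthalpy ratio", {
  mk <- function(Tm, dH) structure(list(Tm = Tm, dH = dH, dT_half = 2),
                                   class = "transition_metrics")
  cmp <- compare_to_control(mk(-18.81, 4.91), mk(-17.08, 8.76))
  expect_equal(cmp$dTm, -1.73)
  expect_equal(cmp$dH_ratio, 0.5605, tolerance = 1e-4)
  id <- compare_to_control(mk(-17.08, 8.76), mk(-17.08, 8.76))
  expect_equal(id$dTm, 0)
  expect_equal(id$dH_ratio, 1)
  expect_error(compare_to_control(mk(-18, 5), mk(-17, 0)), "> 0")
})
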