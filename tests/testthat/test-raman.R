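one_band <- function(center, amplitude, width = 15,
                     range = c(2700, 3100), step = 0.5) {
  raman_sim_config(band_table = data.frame(center = center, width = width,
                                           amplitude = amplitude,
                                           shape = "gaussian"),
                   wavenumber_range = range, step = step)
}

test_that("a single band peaks at its centre with its amplitude", {
  sp <- simulate_raman_spectrum(one_band(2930, 0.84))
  bi <- band_intensity(sp, 2930)
  expect_false(bi$missing)
  expect_equal(bi$intensity, 0.84, tolerance = 0.005)
  expect_equal(bi$wavenumber, 2930, tolerance = 0.1)
})

test_that("normalize_at fixes the anchor window maximum to one", {
  sp <- simulate_raman_spectrum(raman_sim_config())
  nm <- normalize_at(sp)
  sel <- nm$wavenumber_cm1 >= 2838 & nm$wavenumber_cm1 <= 2858
  expect_equal(max(nm$intensity[sel]), 1)
  expect_equal(normalize_at(nm)$intensity, nm$intensity)  # idempotent
  sp7 <- raman_spectrum(sp$wavenumber_cm1, sp$intensity * 7)
  expect_equal(normalize_at(sp7)$intensity, nm$intensity)  # scale invariant
  zero <- raman_spectrum(sp$wavenumber_cm1, rep(0, nrow(sp)))
  expect_error(normalize_at(zero), "nonpositive")
})

test_that("ALS baseline correction removes smooth backgrounds", {
  # pure polynomial, no bands
  cfg <- raman_sim_config(band_table = dopc_band_table()[0, ],
                          baseline_poly_coeffs = c(0.5, 0.3, 0.4))
  sp <- simulate_raman_spectrum(cfg)
  rng <- diff(range(sp$intensity))
  corr <- baseline_correct(sp)
  expect_lt(max(abs(corr$intensity)), 0.01 * rng)

  # zero baseline: output equals input within 0.1% of the peak scale
  sp0 <- simulate_raman_spectrum(raman_sim_config())
  corr0 <- baseline_correct(sp0)
  expect_lt(max(abs(corr0$intensity - sp0$intensity)),
            0.001 * max(sp0$intensity))

  # bands + quadratic baseline: heights recovered within 1%
  cfg2 <- raman_sim_config(baseline_poly_coeffs = c(0.2, 0.05, 0.1))
  sp2 <- baseline_correct(simulate_raman_spectrum(cfg2))
  truth <- attr(sp2, "truth")$band_table
  for (k in seq_len(nrow(truth))) {
    bi <- band_intensity(sp2, truth$center[k])
    meas <- band_intensity(simulate_raman_spectrum(
      raman_sim_config(band_table = truth)), truth$center[k])
    expect_lt(abs(bi$intensity - meas$intensity) / meas$intensity, 0.01)
  }
})

test_that("calibrated control and GEN spectra hit the target ratios", {
  base <- raman_sim_config(baseline_poly_coeffs = c(0.2, 0.05, 0.1))
  for (targets in list(c(0.84, 0.90), c(0.88, 0.96))) {
    cal <- calibrate_band_amplitudes(base, targets[1], targets[2])
    br <- run_raman_pipeline(simulate_raman_spectrum(cal))
    expect_lt(abs(br$ratio_2930_2848 - targets[1]), 0.005)
    expect_lt(abs(br$ratio_2930_2890 - targets[2]), 0.005)
  }
})

test_that("three equal well-separated bands give unit ratios", {
  cfg <- raman_sim_config(
    band_table = data.frame(center = c(2848, 2890, 2930), width = 4,
                            amplitude = 1, shape = "gaussian"))
  br <- band_ratios(simulate_raman_spectrum(cfg))
  expect_equal(br$ratio_2930_2848, 1, tolerance = 1e-6)
  expect_equal(br$ratio_2930_2890, 1, tolerance = 1e-6)
})

test_that("missing peaks are flagged and named", {
  x <- seq(2700, 3100, 0.5)
  flat <- raman_spectrum(x, rep(0, length(x)))
  bi <- band_intensity(flat, 2930)
  expect_true(bi$missing)
  expect_identical(bi$intensity, 0)
  expect_error(band_ratios(flat), "missing Raman peak")
  # zero-amplitude bands on a real baseline: error downstream of the
  # correction because no genuine peak survives
  cfg <- raman_sim_config(band_table = dopc_band_table()[0, ],
                          baseline_poly_coeffs = c(0.5, 0.2, 0.3))
  corr <- baseline_correct(simulate_raman_spectrum(cfg))
  expect_error(band_ratios(corr), "missing Raman peak")
  expect_error(band_intensity(flat, 2700, window = 10), "outside")
})

test_that("ratios are invariant under scaling and normalisation", {
  cal <- calibrate_band_amplitudes(raman_sim_config(), 0.84, 0.90)
  sp <- simulate_raman_spectrum(cal)
  br <- band_ratios(sp)
  br_scaled <- band_ratios(raman_spectrum(sp$wavenumber_cm1,
                                          sp$intensity * 1234.5))
  expect_equal(br_scaled$ratio_2930_2848, br$ratio_2930_2848,
               tolerance = 1e-12)
  expect_equal(br_scaled$ratio_2930_2890, br$ratio_2930_2890,
               tolerance = 1e-12)
  br_norm <- band_ratios(normalize_at(sp))
  expect_equal(br_norm$ratio_2930_2848, br$ratio_2930_2848,
               tolerance = 1e-12)
})

test_that("quadratic baselines within generator bounds barely move ratios", {
  cal <- calibrate_band_amplitudes(raman_sim_config(), 0.84, 0.90)
  br0 <- run_raman_pipeline(simulate_raman_spectrum(cal))
  cfg2 <- cal
  cfg2$baseline_poly_coeffs <- c(0.3, -0.1, 0.15)
  br2 <- run_raman_pipeline(simulate_raman_spectrum(cfg2))
  expect_lt(abs(br2$ratio_2930_2848 - br0$ratio_2930_2848), 0.01)
  expect_lt(abs(br2$ratio_2930_2890 - br0$ratio_2930_2890), 0.01)
})

test_that("ratios agree across grid steps", {
  cal <- calibrate_band_amplitudes(raman_sim_config(), 0.84, 0.90)
  fine <- cal; fine$step <- 0.5
  coarse <- cal; coarse$step <- 2
  br_f <- band_ratios(simulate_raman_spectrum(fine))
  br_c <- band_ratios(simulate_raman_spectrum(coarse))
  expect_lt(abs(br_f$ratio_2930_2848 - br_c$ratio_2930_2848), 0.01)
  expect_lt(abs(br_f$ratio_2930_2890 - br_c$ratio_2930_2890), 0.01)
  # band heights themselves are grid robust via parabolic refinement
  b_f <- band_intensity(simulate_raman_spectrum(fine), 2848)
  b_c <- band_intensity(simulate_raman_spectrum(coarse), 2848)
  expect_lt(abs(b_f$intensity - b_c$intensity) / b_f$intensity, 0.01)
})

test_that("the isoflavone marker band does not disturb C-H ratios", {
  bt <- rbind(dopc_band_table(),
              data.frame(center = 1614, width = 12, amplitude = 0,
                         shape = "gaussian"))
  mk <- function(a) {
    bt$amplitude[bt$center == 1614] <- a
    simulate_raman_spectrum(raman_sim_config(
      band_table = bt, wavenumber_range = c(1500, 3100)))
  }
  br0 <- band_ratios(mk(0))
  br1 <- band_ratios(mk(0.6))
  expect_equal(br1$ratio_2930_2848, br0$ratio_2930_2848, tolerance = 1e-9)
  expect_equal(br1$ratio_2930_2890, br0$ratio_2930_2890, tolerance = 1e-9)
})

test_that("summarize_ratios pools regions within samples first", {
  mk_df <- function(v) data.frame(sample = rep(1:3, each = 3),
                                  ratio_2930_2848 = v,
                                  ratio_2930_2890 = v)
  same <- summarize_ratios(mk_df(rep(0.84, 9)))
  expect_identical(same$sd_2930_2848, 0)
  df <- data.frame(sample = 1:3,
                   ratio_2930_2848 = c(0.83, 0.84, 0.85),
                   ratio_2930_2890 = c(0.83, 0.84, 0.85))
  s <- summarize_ratios(df)
  expect_equal(s$mean_2930_2848, 0.84)
  expect_equal(s$sd_2930_2848, 0.01)
  expect_error(summarize_ratios(list()), "no results")
})

test_that("noisy seeded replicates recover the control ratio", {
  cal <- calibrate_band_amplitudes(raman_sim_config(), 0.84, 0.90)
  rows <- do.call(rbind, lapply(1:9, function(k) {
    cfg <- cal
    cfg$noise_sd <- 0.005   # 0.5% of the anchor peak
    cfg$seed <- k
    br <- run_raman_pipeline(simulate_raman_spectrum(cfg))
    data.frame(sample = (k - 1) %/% 3 + 1,
               ratio_2930_2848 = br$ratio_2930_2848,
               ratio_2930_2890 = br$ratio_2930_2890)
  }))
  s <- summarize_ratios(rows)
  expect_lt(abs(s$mean_2930_2848 - 0.84), 0.01)
  expect_identical(s$n_samples, 3L)
  expect_identical(s$n_regions_per_sample, 3)
})
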