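test_that("osmotic_flux_model follows the flux law", {
  st <- droplet_pair_state(50, 50, 30)
  expect_identical(osmotic_flux_model(st, osmotic_conditions(0.2, 0.2), 74),
                   0)
  # independent arithmetic: 74 * pi*30^2 * 18 * 0.2 * 1e-3
  expect_equal(osmotic_flux_model(st, osmotic_conditions(0, 0.2), 74),
               -74 * pi * 900 * 18 * 0.2 * 1e-3)
  expect_equal(abs(osmotic_flux_model(st, osmotic_conditions(0, 0.2), 74)),
               753.2, tolerance = 1e-4)
  # hypotonic droplet 1 shrinks; reversed gradient grows it
  expect_lt(osmotic_flux_model(st, osmotic_conditions(0.1, 0.3), 50), 0)
  expect_gt(osmotic_flux_model(st, osmotic_conditions(0.3, 0.1), 50), 0)
})

test_that("initial-rate estimator recovers Pf on short noiseless windows", {
  cfg <- control_dib_config(true_Pf = 74, duration = 2,
                            sample_interval = 0.1)
  traj <- simulate_dib_trajectory(cfg)
  est <- estimate_pf_initial_rate(traj, attr(traj, "conditions"),
                                  window = 5)
  expect_s3_class(est, "permeability_estimate")
  expect_equal(est$Pf, 74, tolerance = 0.02)
  expect_identical(est$method, "initial_rate")
})

test_that("initial-rate over a long window is biased low", {
  cfg <- control_dib_config(true_Pf = 74, duration = 120)
  traj <- simulate_dib_trajectory(cfg)
  est_full <- estimate_pf_initial_rate(traj, attr(traj, "conditions"),
                                       window = nrow(traj))
  expect_lt(est_full$Pf, 74)
})

test_that("estimators reject degenerate inputs", {
  cfg <- control_dib_config(duration = 5)
  traj <- simulate_dib_trajectory(cfg)
  iso <- osmotic_conditions(0.2, 0.2)
  expect_error(estimate_pf_initial_rate(traj, iso), "undefined")
  expect_error(estimate_pf_ode_fit(traj, iso), "undefined")
  expect_error(estimate_pf_initial_rate(traj, attr(traj, "conditions"),
                                        window = 1), ">= 2")
  expect_error(estimate_pf_ode_fit(traj[1:2, ], attr(traj, "conditions")),
               "at least 3")
})

test_that("ODE fit recovers the truth on noiseless data in both modes", {
  for (mode in c("constant_contact_radius", "constant_contact_angle")) {
    cfg <- control_dib_config(true_Pf = 74, shrinkage_mode = mode)
    traj <- simulate_dib_trajectory(cfg)
    est <- estimate_pf_ode_fit(traj, attr(traj, "conditions"), mode)
    expect_equal(est$Pf, 74, tolerance = 1e-3)
    expect_lt(est$residual_rms, 1)
  }
})

test_that("initial-rate approaches the ODE fit as the window shrinks", {
  cfg <- control_dib_config(true_Pf = 74, duration = 0.5,
                            sample_interval = 0.01)
  traj <- simulate_dib_trajectory(cfg)
  conds <- attr(traj, "conditions")
  ode <- estimate_pf_ode_fit(traj, conds)$Pf
  ir2 <- estimate_pf_initial_rate(traj, conds, window = 2)$Pf
  expect_equal(ir2, ode, tolerance = 1e-3)
})

test_that("aggregate_condition computes mean and SEM", {
  vals <- c(70, 74, 78)
  s <- aggregate_condition(vals, label = "DOPC")
  expect_equal(s$mean_Pf, 74)
  expect_equal(s$sem, sd(vals) / sqrt(3))
  expect_equal(s$sem, 2.309, tolerance = 1e-3)
  one <- aggregate_condition(74)
  expect_identical(one$sem, 0)
  expect_identical(one$n, 1L)
  expect_error(aggregate_condition(list()), "no estimates")
  # also accepts estimate objects
  ests <- lapply(vals, function(v)
    dibkit:::permeability_estimate(v, 1, "ode_fit", 0, 10L))
  expect_equal(aggregate_condition(ests)$mean_Pf, 74)
})

test_that("percent_change reproduces the reported relative shifts", {
  expect_equal(round(percent_change(94, 74)), 27)
  expect_equal(round(percent_change(60, 74)), -19)
  expect_equal(percent_change(94, 74), 27.027, tolerance = 1e-4)
  expect_identical(percent_change(74, 74), 0)
  expect_error(percent_change(50, 0), "Pf_control")
})
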