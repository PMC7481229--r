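test_that("capillary number is eta*v_c/sigma and linear in its drivers", {
  fs <- ref_fluid()
  expect_equal(capillary_number(fs, 9.02e-3), 0.0133 * 9.02e-3 / 0.012)
  expect_equal(capillary_number(fs, 9.02e-3), 1.00e-2, tolerance = 1e-3)
  expect_equal(capillary_number(fs, 0), 0)
  # linear in v_c and in eta
  expect_equal(capillary_number(fs, 18.04e-3),
               2 * capillary_number(fs, 9.02e-3))
  fs2 <- fluid_system(viscosity_mpas = 26.6)
  expect_equal(capillary_number(fs2, 9.02e-3),
               2 * capillary_number(fs, 9.02e-3))
  expect_error(fluid_system(viscosity_mpas = -1), "positive")
  expect_error(fluid_system(tension_mn_m = 0), "positive")
})

test_that("flow_condition derives velocities through the shared cross-section", {
  fs <- ref_fluid()
  fc <- flow_condition(fs, 4.5, 12)
  expect_equal(fc$v_tot, (16.5e-9 / 60) / 7.5e-9, tolerance = 1e-12)
  expect_equal(fc$p_aq, 4.5 / 16.5)
  expect_equal(fc$v_tot, fc$v_d + fc$v_c)
  # velocity ratio equals flow-rate ratio exactly under one cross-section
  expect_equal(fc$v_d / fc$v_tot, fc$q_aq / (fc$q_aq + fc$q_oil),
               tolerance = 1e-15)
  expect_equal(flow_condition(fs, 7, 7)$p_aq, 0.5)
  z <- flow_condition(fs, 0, 10)
  expect_equal(z$p_aq, 0)
  expect_equal(z$v_d, 0)
  cont <- flow_condition(fs, 10, 0)
  expect_true(cont$continuous_mode)
  expect_error(flow_condition(fs, 0, 0), "at least one")
})

test_that("droplet_frequency follows K*Ca^(4/3)/W * v_d/v_tot", {
  fs <- ref_fluid()
  # composite term 3e-4 with K = 3.7 m/s and W = 100 um gives 11.1 Hz
  cond <- solve_flow_for_frequency(fs, 3.7, 3.7 * 3e-4 / 1e-4, 0.25)
  expect_equal(droplet_frequency(fs, cond, 3.7), 11.1, tolerance = 1e-6)
  # direct evaluation at v_c = 10 mm/s, v_d = 5 mm/s
  fc <- cond_from_velocities(fs, 5e-3, 10e-3)
  expect_equal(droplet_frequency(fs, fc, 3.7),
               3.7 * capillary_number(fs, 10e-3)^(4 / 3) / 1e-4 * (1 / 3))
  expect_equal(droplet_frequency(fs, fc, 3.7), 30.4, tolerance = 5e-3)
  # zero dispersed flow gives zero frequency
  expect_equal(droplet_frequency(fs, flow_condition(fs, 0, 10), 3.7), 0)
  expect_error(droplet_frequency(fs, flow_condition(fs, 10, 0), 3.7),
               "continuous mode")
  expect_error(droplet_frequency(fs, fc, k = 0), "positive")
})

test_that("frequency is monotone in each phase velocity on a grid", {
  fs <- ref_fluid()
  f_of <- function(v_d, v_c) {
    droplet_frequency(fs, cond_from_velocities(fs, v_d, v_c), 3.7)
  }
  v_grid <- seq(2e-3, 20e-3, length.out = 15)
  for (v_d in c(2e-3, 8e-3)) {
    f <- vapply(v_grid, function(v_c) f_of(v_d, v_c), numeric(1))
    expect_true(all(diff(f) > 0))
  }
  for (v_c in c(5e-3, 15e-3)) {
    f <- vapply(v_grid, function(v_d) f_of(v_d, v_c), numeric(1))
    expect_true(all(diff(f) > 0))
  }
})

test_that("frequency respects the Ca^(4/3) power law at fixed flow ratio", {
  fs <- ref_fluid()
  ratio <- 0.3
  v_tot <- seq(8e-3, 25e-3, length.out = 12)
  f <- vapply(v_tot, function(v) {
    droplet_frequency(fs, cond_from_velocities(fs, v * ratio / (1 + ratio),
                                               v / (1 + ratio)), 3.7)
  }, numeric(1))
  ca <- capillary_number(fs, v_tot / (1 + ratio))
  slope <- coef(lm(log(f) ~ log(ca)))[2]
  expect_equal(unname(slope), 4 / 3, tolerance = 1e-10)
})

test_that("fit_prefactor recovers the generating K exactly on noiseless data", {
  fs <- ref_fluid()
  for (k_true in c(0.5, 1, 3.7, 10)) {
    dat <- make_frequency_dataset(fs, k_true = k_true, n_points = 30,
                                  noise_cv = 0, seed = 7)
    fit <- fit_prefactor(dat, fs)
    expect_equal(fit$k_hat, k_true, tolerance = 1e-10)
    expect_lt(fit$k_se, 1e-8 * k_true)
  }
})

test_that("fit_prefactor rejects degenerate designs", {
  fs <- ref_fluid()
  one <- data.frame(q_aq_ul_min = 4.5, q_oil_ul_min = 12, f_hz = 30,
                    n_droplets = 70)
  expect_error(fit_prefactor(one, fs), "at least 2")
  same_x <- one[c(1, 1), ]
  expect_error(fit_prefactor(same_x, fs), "identical")
  bad <- data.frame(q_aq_ul_min = c(4, 5), q_oil_ul_min = c(12, 12),
                    f_hz = c(30, 35))
  expect_error(fit_prefactor(bad, fs), "n_droplets")
})

test_that("weighted fit is calibrated: 200-replicate parameter recovery", {
  fs <- ref_fluid()
  k_hats <- numeric(200)
  k_ses <- numeric(200)
  for (r in seq_len(200)) {
    dat <- make_frequency_dataset(fs, k_true = 3.7, n_points = 70,
                                  noise_cv = 0.05, seed = 1000 + r)
    fit <- fit_prefactor(dat, fs)
    k_hats[r] <- fit$k_hat
    k_ses[r] <- fit$k_se
  }
  expect_lt(abs(mean(k_hats) - 3.7) / 3.7, 0.01)
  ratio <- sd(k_hats) / mean(k_ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("solve_flow_for_frequency round-trips and flags unreachable targets", {
  fs <- ref_fluid()
  # forward then invert recovers the flows
  fc0 <- flow_condition(fs, 4.5, 12)
  f0 <- droplet_frequency(fs, fc0, 3.7)
  sol <- solve_flow_for_frequency(fs, 3.7, f0, 4.5 / 12)
  expect_equal(m3s_to_ul_min(sol$q_aq), 4.5, tolerance = 1e-5)
  expect_equal(m3s_to_ul_min(sol$q_oil), 12, tolerance = 1e-5)
  # 10 Hz target lands at composite term f*W/K = 2.7e-4
  sol10 <- solve_flow_for_frequency(fs, 3.7, 10, 0.3)
  expect_equal(composite_term(sol10), 10 * 1e-4 / 3.7, tolerance = 1e-9)
  expect_equal(signif(composite_term(sol10), 1), 3e-4)
  # other facility repetition rates are reachable and round-trip
  for (f_target in c(30, 60, 100, 120)) {
    s <- solve_flow_for_frequency(fs, 3.7, f_target, 0.3)
    expect_equal(droplet_frequency(fs, s, 3.7), f_target,
                 tolerance = 1e-6 * f_target)
  }
  expect_error(solve_flow_for_frequency(fs, 3.7, 1e9, 0.3), "no solution")
})

test_that("droplet volume conserves the aqueous throughput", {
  expect_equal(m3_to_pl(droplet_volume(4.5, 100)), 750)
  expect_equal(m3_to_pl(droplet_volume(3, 62.5)), 800)
  # f * V = Q_aq exactly, and V halves when f doubles
  for (q in c(3, 4.5, 12, 20)) {
    for (f in c(10, 62.5, 100, 400)) {
      expect_equal(f * droplet_volume(q, f), ul_min_to_m3s(q))
    }
    expect_equal(droplet_volume(q, 20), droplet_volume(q, 10) / 2)
  }
  expect_error(droplet_volume(4.5, 0), "positive")
})
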