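test_that("noiseless square wave is segmented exactly", {
  syn <- make_trace(f_hz = 10, p_aq = 0.3, duration_s = 10, noise_sd_v = 0)
  ev <- detect_droplets(syn$trace)
  expect_false(ev$no_droplets)
  expect_equal(ev$estimated_frequency, 10, tolerance = 1e-6)
  expect_equal(ev$mean_aqueous_dwell, 0.030, tolerance = 0.02)
  expect_equal(ev$mean_oil_dwell, 0.070, tolerance = 0.02)
})

test_that("frequency recovery survives 5% noise within 1%", {
  syn <- make_trace(f_hz = 10, p_aq = 0.3, duration_s = 10,
                    amplitude_v = 1, noise_sd_v = 0.05, seed = 21)
  ev <- detect_droplets(syn$trace)
  expect_lt(abs(ev$estimated_frequency - 10) / 10, 0.01)
})

test_that("duty estimate converges to generator duty at high SNR", {
  syn <- make_trace(f_hz = 20, p_aq = 0.4, duration_s = 20,
                    amplitude_v = 1, noise_sd_v = 0.02, seed = 3)
  ev <- detect_droplets(syn$trace)
  duty <- ev$mean_aqueous_dwell /
    (ev$mean_aqueous_dwell + ev$mean_oil_dwell)
  expect_lt(abs(duty - 0.4) / 0.4, 0.01)
  # interior events tile the trace span they cover
  interior <- ev$events[-c(1, nrow(ev$events)), ]
  covered <- sum(interior$end_s - interior$start_s)
  span <- max(interior$end_s) - min(interior$start_s)
  expect_equal(covered, span, tolerance = 1e-9)
})

test_that("constant or degenerate traces are flagged, not errors", {
  flat <- detector_trace(rep(0.7, 1000), 1e4)
  ev <- detect_droplets(flat)
  expect_true(ev$no_droplets)
  expect_equal(nrow(ev$events), 0)
  expect_true(is.na(ev$estimated_frequency))
  # duty 1.0 yields a constant-level trace: flagged too
  syn <- make_trace(f_hz = 10, p_aq = 1, duration_s = 2, noise_sd_v = 0)
  expect_true(detect_droplets(syn$trace)$no_droplets)
})

test_that("frequency estimate is invariant to voltage offset and gain", {
  syn <- make_trace(f_hz = 12, p_aq = 0.35, duration_s = 8,
                    noise_sd_v = 0.03, seed = 8)
  ref <- detect_droplets(syn$trace)$estimated_frequency
  for (tf in list(c(2, 0.5), c(-1, 3), c(0.1, -2))) {
    v2 <- tf[1] + tf[2] * syn$trace$voltages
    lev <- if (tf[2] > 0) "low" else "high"
    ev2 <- detect_droplets(detector_trace(v2, syn$trace$sample_rate),
                           aqueous_level = lev)
    expect_equal(ev2$estimated_frequency, ref, tolerance = 1e-9)
  }
})

test_that("compare_to_model reports relative frequency deviation", {
  syn <- make_trace(f_hz = 10, p_aq = 0.3, duration_s = 5, noise_sd_v = 0)
  ev <- detect_droplets(syn$trace)
  expect_equal(compare_to_model(ev, 10), 0, tolerance = 1e-4)
  ev$estimated_frequency <- 11
  expect_equal(compare_to_model(ev, 10), 0.10)
  expect_error(compare_to_model(ev, 0), "positive")
})

test_that("end-to-end: trace from a modelled flow condition reads back within 2%", {
  fs <- ref_fluid()
  cond <- solve_flow_for_frequency(fs, 3.7, 25, 0.3)
  f_pred <- droplet_frequency(fs, cond, 3.7)
  syn <- make_trace(f_hz = f_pred, p_aq = cond$p_aq, duration_s = 4,
                    noise_sd_v = 0.05, seed = 13)
  ev <- detect_droplets(syn$trace)
  expect_lt(abs(compare_to_model(ev, f_pred)), 0.02)
})

test_that("panel profile projects rows, scores ridges, and is linear", {
  # constant image: every profile entry is value * width
  const <- list(matrix(2, 16, 32), matrix(2, 16, 32))
  pp <- panel_horizontal_profile(const, band = c(6, 10))
  expect_equal(pp$profile, rep(64, 16))
  expect_equal(pp$ring_score, 0)
  expect_equal(pp$n_hits, 2)
  # all-zero images: zero profile, zero score
  zz <- panel_horizontal_profile(list(matrix(0, 8, 8)))
  expect_equal(zz$profile, rep(0, 8))
  expect_equal(zz$ring_score, 0)
  # injected ridge scores far above the ridge-free stack
  with_ring <- make_panel_stack(n_images = 8, ring_row = 32, seed = 1)
  no_ring <- make_panel_stack(n_images = 8, ring_row = NULL, seed = 1)
  band <- c(25, 40)
  s1 <- panel_horizontal_profile(with_ring, band)$ring_score
  s0 <- panel_horizontal_profile(no_ring, band)$ring_score
  expect_gt(s1, 5 * s0)
  # linearity: profile(a I1 + b I2) = a profile(I1) + b profile(I2)
  i1 <- matrix(runif(64), 8, 8)
  i2 <- matrix(runif(64), 8, 8)
  lhs <- panel_horizontal_profile(list(3 * i1 + 2 * i2))$profile
  rhs <- 3 * panel_horizontal_profile(list(i1))$profile +
    2 * panel_horizontal_profile(list(i2))$profile
  expect_equal(lhs, rhs)
  # 3-D array input is accepted
  arr <- array(1, dim = c(4, 6, 3))
  expect_equal(panel_horizontal_profile(arr)$profile, rep(6, 4))
  expect_error(panel_horizontal_profile(list()), "non-empty")
  expect_error(panel_horizontal_profile(list(matrix(1, 2, 2),
                                             matrix(1, 3, 3))),
               "share dimensions")
})
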