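test_that("simulation is reproducible and degenerate cases are exact", {
  eu <- euxfel()
  tr <- droplet_train(20, 0.3)
  a <- simulate_injection(tr, eu, 0.05, 50, seed = 11)
  b <- simulate_injection(tr, eu, 0.05, 50, seed = 11)
  expect_identical(a, b)
  c <- simulate_injection(tr, eu, 0.05, 50, seed = 12)
  expect_false(identical(a, c))
  # p_aq = 1: every pulse aqueous
  all_aq <- simulate_injection(droplet_train(20, 1), eu, 0.1, 20, seed = 1)
  expect_true(all(all_aq$phase_label == "aqueous"))
  # mean_hit = 0: no hits anywhere
  none <- simulate_injection(droplet_train(20, 0.3), eu, 0, 20, seed = 1)
  expect_true(all(none$hit == 0))
  # p_aq = 0: all oil, no hits
  oil <- simulate_injection(droplet_train(20, 0), eu, 5, 20, seed = 1)
  expect_true(all(oil$phase_label == "oil"))
  expect_error(simulate_injection(tr, eu, 0.05, 10), "seed")
})

test_that("outcome table is structurally consistent with the schedule", {
  eu <- euxfel()
  out <- simulate_injection(droplet_train(20, 0.3), eu, 0.1, 25, seed = 3)
  expect_equal(nrow(out), 25 * 32)
  expect_true(all(diff(out$time_s) > 0))
  expect_equal(out$time_s, pulse_times(eu, 25))
  expect_identical(sort(unique(out$pulse_id[out$recorded])),
                   recorded_pulse_ids(eu))
  expect_true(all(out$hit[out$phase_label != "aqueous"] == 0))
  expect_true(all(out$hit >= 0))
})

test_that("unsynchronised aqueous-pulse fraction converges to p_aq", {
  # 1e5 single-pulse trains: binomial oracle at 3 sigma
  p <- 0.3
  n <- 1e5
  out <- simulate_injection(droplet_train(37, p),
                            facility_preset("swissfel"), 0, n, seed = 29)
  obs <- mean(out$phase_label == "aqueous")
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("total hits match the Poisson mean identity", {
  eu <- euxfel()
  mean_hit <- 0.2
  out <- simulate_injection(droplet_train(23, 0.4), eu, mean_hit, 2000,
                            seed = 5)
  n_aq <- sum(out$phase_label == "aqueous")
  total <- sum(out$hit)
  expect_lt(abs(total - n_aq * mean_hit), 3 * sqrt(n_aq * mean_hit))
})

test_that("per-pulse-id hits are flat under plug flow spanning the train", {
  eu <- euxfel()
  # 10 Hz plugs with p_aq = 0.3: 30 ms plug >> 27.6 us train span
  out <- simulate_injection(droplet_train(10, 0.3), eu, 0.25, 3000,
                            seed = 17)
  summ <- summarize_run(out, 4.2, 300)
  expect_gt(sum(summ$per_pulse_id_hits), 100)
  expect_gt(chisq.test(summ$per_pulse_id_hits)$p.value, 0.01)
})

test_that("period jitter and boundary window behave as configured", {
  eu <- euxfel()
  tr <- droplet_train(20, 0.3, period_jitter_cv = 0.1,
                      interface_window_s = 1e-3)
  out <- simulate_injection(tr, eu, 0.1, 400, seed = 9)
  expect_true("boundary" %in% out$phase_label)
  expect_true(all(out$hit[out$phase_label == "boundary"] == 0))
  # aqueous fraction still near p_aq with jitter on
  expect_lt(abs(mean(out$phase_label == "aqueous") - 0.3), 0.1)
})

test_that("synchronized mode gives full aqueous coverage of recorded pulses", {
  eu <- euxfel()
  # 10 Hz plugs, p_aq chosen so the plug (500 us) spans the train
  tr <- synchronized_mode(droplet_train(10, 0.005), eu)
  expect_equal(tr$frequency, 10)
  expect_true(attr(tr, "covers_train"))
  out <- simulate_injection(tr, eu, 0.3, 200, seed = 2)
  rec <- out[out$recorded, ]
  expect_equal(mean(rec$phase_label == "aqueous"), 1)
  # plug shorter than the train span warns and flags
  expect_warning(short <- synchronized_mode(droplet_train(10, 1e-7), eu),
                 "shorter")
  expect_false(attr(short, "covers_train"))
  # single-pulse facility: any plug covers the (zero-span) train
  sw <- facility_preset("swissfel")
  tr1 <- synchronized_mode(droplet_train(100, 0.01), sw)
  out1 <- simulate_injection(tr1, sw, 0.3, 100, seed = 2)
  expect_true(all(out1$phase_label == "aqueous"))
})

test_that("summarize_run aggregates volumes, hits and histograms", {
  eu <- euxfel()
  out <- simulate_injection(droplet_train(10, 0.3), eu, 0.2, 100, seed = 4)
  s <- summarize_run(out, q_aq_ul_min = 4.2, duration_s = 10)
  expect_equal(s$n_pulses, 3200)
  expect_equal(s$n_recorded, 1500)
  expect_equal(s$volume_ul, 4.2 * 10 / 60)
  expect_equal(s$total_hits, sum(out$hit[out$recorded]))
  expect_equal(s$hits_per_ul, s$total_hits / s$volume_ul)
  expect_equal(sum(s$per_pulse_id_hits), s$total_hits)
  # all-zero hits give zero hits/uL
  z <- summarize_run(simulate_injection(droplet_train(10, 0.3), eu, 0, 10,
                                        seed = 1), 4.2, 10)
  expect_equal(z$hits_per_ul, 0)
  expect_error(summarize_run(out[0, ], 4.2, 10), "non-empty")
})

test_that("segmented beats continuous by Q_tot/Q_aq in the synchronized limit", {
  # idealized: synchronized segmented flow puts every recorded pulse in
  # aqueous sample, as does continuous injection; the saving is the oil
  # share of the total flow.
  eu <- euxfel()
  mean_hit <- 0.3
  dur <- 60
  q_aq <- 4
  q_tot <- 16
  tr <- synchronized_mode(droplet_train(10, 0.005), eu)
  seg <- summarize_run(simulate_injection(tr, eu, mean_hit, 600, seed = 6),
                       q_aq, dur)
  cont <- summarize_run(simulate_injection(droplet_train(10, 1), eu,
                                           mean_hit, 600, seed = 6),
                        q_tot, dur)
  ratio <- seg$hits_per_ul / cont$hits_per_ul
  expect_equal(ratio, q_tot / q_aq, tolerance = 0.15)
})

test_that("consumption report reproduces run-accounting arithmetic", {
  tab <- data.frame(
    label = c("continuous", "segmented_subset", "segmented_all"),
    minutes = c(26, 26, 134),
    volume_ul = c(260, 110, 962),
    hits = c(577, 735, 5770)
  )
  rep <- consumption_report(tab, "continuous")
  expect_equal(round(rep$hits_per_ul[1], 1), 2.2)
  expect_equal(round(rep$hits_per_ul[3], 1), 6.0)
  expect_equal(rep$hits_per_ul[2], 735 / 110)
  expect_equal(round(rep$fold_change[2]), 3)
  expect_equal(rep$percent_reduction[2], 100 * (1 - 110 / 260))
  expect_equal(round(rep$percent_reduction[2], -1), 60)
  expect_equal(rep$q_aq_ul_min[2], 110 / 26)
  # reference against itself: fold 1, reduction 0
  expect_equal(rep$fold_change[1], 1)
  expect_equal(rep$percent_reduction[1], 0)
  expect_error(consumption_report(tab, "nope"), "not found")
  tab$volume_ul[1] <- -1
  expect_error(consumption_report(tab, "continuous"), "positive")
})
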