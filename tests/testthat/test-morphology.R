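test_that("locate_peaks recovers separated landmarks to oracle accuracy", {
  lat <- c(0.15, 0.40, 0.65)
  amp <- c(4, 4.4, 1.8)
  wid <- c(0.08, 0.10, 0.09)
  want <- oracle_apparent(lat, amp, wid)
  y <- eval_at_100 <- icpwave::make_pulse_template(
    pulse_shape(lat, amp, wid), cycle_s = 1, fs = 100)
  got <- locate_peaks(y)
  expect_false(got$merged_peaks)
  expect_lt(abs(got$p1_pos - want$p1_pos), 1 / 100 + 1e-9)
  expect_lt(abs(got$p2_pos - want$p2_pos), 1 / 100 + 1e-9)
  expect_equal(got$p1_amp, want$p1_amp, tolerance = 0.02)
  expect_equal(got$p2_amp, want$p2_amp, tolerance = 0.02)
  expect_equal(got$p2p1_ratio, want$ratio, tolerance = 0.02)
  expect_error(locate_peaks(y[1:30]), ">= 50")
})

test_that("single-bump pulse forces the P2 landmark onto the inflection", {
  sh <- pulse_shape(latencies = c(0.20, 0.45, 0.8),
                    amplitudes = c(1, 0, 0),
                    widths = c(0.14, 0.1, 0.1))
  y <- make_pulse_template(sh, cycle_s = 1, fs = 100)
  got <- locate_peaks(y, p2_window = c(0.25, 0.70))
  expect_true(got$merged_peaks)
  expect_gt(got$p2_pos, got$p1_pos)
  # inflection of a Gaussian sits one width from the centre
  expect_equal(got$p2_pos, 0.20 + 0.14, tolerance = 0.03)
})

test_that("merged rising shoulder puts P1 at the inflection with ratio > 1", {
  # strongly overlapping bumps, separation < 1 width, a2 > a1
  lat <- c(0.28, 0.36, 0.8)
  amp <- c(1, 1.3, 0)
  wid <- c(0.10, 0.10, 0.10)
  y <- make_pulse_template(pulse_shape(lat, amp, wid), cycle_s = 1, fs = 100)
  got <- locate_peaks(y)
  expect_true(got$merged_peaks)
  expect_lt(got$p1_pos, got$p2_pos)
  expect_gt(got$p2p1_ratio, 1)
  # oracle: the single true maximum lives in the P2 window
  g <- oracle_gauss_sum(lat, amp, wid)
  expect_equal(got$p2_pos, g$phase[which.max(g$y)], tolerance = 0.02)
})

test_that("compute_ratio follows its contract", {
  expect_equal(compute_ratio(1, 1), 1)
  expect_equal(compute_ratio(1, 1.2), 1.2)
  expect_equal(compute_ratio(2, 1), 0.5)
  expect_error(compute_ratio(0, 1), "P1")
  expect_error(compute_ratio(-2, 1), "P1")
})

test_that("compute_ttp is the normalized argmax position", {
  y <- exp(-0.5 * (((0:99) / 100 - 0.2) / 0.05)^2)
  expect_equal(compute_ttp(y), 0.2, tolerance = 1 / 100 + 1e-9)
  expect_equal(compute_ttp(c(5, rep(0, 99))), 0)
  expect_error(compute_ttp(rep(1, 100)), "flat")
})

test_that("estimated ratio is strictly increasing in generative a2/a1", {
  ratios <- c(0.7, 0.85, 1.0, 1.15, 1.3, 1.45)
  est <- vapply(ratios, function(r) {
    ses <- generate_session(noiseless_config(baseline_p2p1 = r,
                                             duration_s = 60))
    rep <- analyze_session(ses$recording)
    rep$per_minute$p2p1_ratio[rep$per_minute$channel == "icp"][1]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("TTP hops from the P1 to the P2 latency as the ratio crosses 1", {
  low <- generate_session(noiseless_config(baseline_p2p1 = 0.8,
                                           duration_s = 60))
  high <- generate_session(noiseless_config(baseline_p2p1 = 1.25,
                                            duration_s = 60))
  ttp_low <- analyze_session(low$recording)
  ttp_low <- ttp_low$per_minute$ttp[ttp_low$per_minute$channel == "icp"][1]
  ttp_high <- analyze_session(high$recording)
  ttp_high <- ttp_high$per_minute$ttp[ttp_high$per_minute$channel == "icp"][1]
  expect_lt(abs(ttp_low - 0.15), 0.02)
  expect_lt(abs(ttp_high - 0.40), 0.02)
})

test_that("ratio and TTP are invariant to positive channel gain", {
  ses <- generate_session(session_config(seed = 13L, duration_s = 120,
                                          compression_start_s = 0,
                                          compression_duration_s = 0))
  r1 <- ses$recording
  r2 <- r1
  r2$b4c_um <- 50 * r2$b4c_um
  m1 <- analyze_session(r1)$per_minute
  m2 <- analyze_session(r2)$per_minute
  b1 <- m1[m1$channel == "b4c", ]
  b2 <- m2[m2$channel == "b4c", ]
  expect_equal(b1$p2p1_ratio, b2$p2p1_ratio, tolerance = 1e-12)
  expect_equal(b1$ttp, b2$ttp, tolerance = 1e-12)
})

test_that("morphology_series keeps undeterminable minutes as explicit gaps", {
  ses <- generate_session(noiseless_config(duration_s = 600))
  segs <- segment_pulses(ses$recording$icp_mmHg, ses$truth$beat_onsets_s,
                         200)
  segs <- exclude_artifacts(segs)
  mp <- minute_average(segs)
  ms <- morphology_series(mp)
  expect_equal(nrow(ms), 10L)
  expect_true(all(ms$determined))

  # a minute whose pulse is flat cannot be resolved but keeps its row
  mp[[4]]$mean_pulse <- rep(0, 100)
  ms2 <- morphology_series(mp)
  expect_equal(nrow(ms2), 10L)
  expect_false(ms2$determined[4])
  expect_true(is.na(ms2$p2p1_ratio[4]))
})

test_that("compression minute shifts the ratio in the group's direction", {
  # intact: ratio rises under jugular compression
  up <- generate_session(session_config(seed = 31L, noise_sd_icp = 0.2,
                                        compression_delta_p2p1 = 0.08))
  rep_up <- analyze_session(up$recording)
  icp_up <- rep_up$per_minute[rep_up$per_minute$channel == "icp", ]
  expect_gt(icp_up$p2p1_ratio[icp_up$epoch == "compression"],
            mean(icp_up$p2p1_ratio[icp_up$epoch == "baseline"]))

  # craniectomy-like response: ratio falls
  dn <- generate_session(session_config(seed = 32L, noise_sd_icp = 0.2,
                                        group = "craniectomy",
                                        baseline_icp_mmHg = 20.8,
                                        compression_delta_icp_mmHg = 3.13,
                                        compression_delta_p2p1 = -0.08))
  rep_dn <- analyze_session(dn$recording)
  icp_dn <- rep_dn$per_minute[rep_dn$per_minute$channel == "icp", ]
  expect_lt(icp_dn$p2p1_ratio[icp_dn$epoch == "compression"],
            mean(icp_dn$p2p1_ratio[icp_dn$epoch == "baseline"]))
})
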