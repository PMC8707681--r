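test_that("session_config enforces its invariants", {
  expect_error(session_config(duration_s = 0), "duration_s")
  expect_error(session_config(fs = 20), "fs")
  expect_error(session_config(heart_rate_bpm = 10), "heart_rate")
  expect_error(session_config(compression_start_s = 580,
                              compression_duration_s = 60),
               "compression window")
  expect_error(session_config(baseline_p2p1 = 0), "baseline_p2p1")
})

test_that("beat count equals floor(duration * HR / 60) exactly", {
  cases <- list(c(600, 70), c(600, 60), c(127, 83), c(60, 200), c(45, 20))
  for (cs in cases) {
    cfg <- session_config(duration_s = cs[1], heart_rate_bpm = cs[2],
                          compression_start_s = 0,
                          compression_duration_s = 0, artifact_rate = 0,
                          seed = 3L)
    ses <- generate_session(cfg)
    expect_length(ses$truth$beat_onsets_s, floor(cs[1] * cs[2] / 60))
    expect_true(all(diff(ses$truth$beat_onsets_s) > 0))
  }
})

test_that("channels are constant when pulses, noise and modulation are off", {
  cfg <- noiseless_config(pulse_amplitude_icp = 0,
                          compression_delta_icp_mmHg = 0,
                          duration_s = 30)
  ses <- generate_session(cfg)
  expect_equal(diff(range(ses$recording$icp_mmHg)), 0)
  expect_equal(diff(range(ses$recording$b4c_um)), 0)
})

test_that("per-minute true mean ICP tracks baseline and compression plateau", {
  cfg <- session_config(baseline_icp_mmHg = 15.2,
                        compression_delta_icp_mmHg = 4.1,
                        artifact_rate = 0, seed = 5L)
  ses <- generate_session(cfg)
  tm <- ses$truth$true_mean_icp_per_minute
  expect_length(tm, 10L)
  # compression window 420-480 s sits inside minute index 8 (1-based)
  expect_equal(tm[-8], rep(15.2, 9), tolerance = 0.01)
  expect_equal(tm[8], 19.3, tolerance = 0.02 * 19.3)
  # rendered channel agrees within 3 SE outside the compression window
  t <- ses$recording$time_s
  for (mi in c(0, 3, 9)) {
    x <- ses$recording$icp_mmHg[t >= 60 * mi & t < 60 * (mi + 1)]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 15.2), 3 * max(se, 0.02))
  }
})

test_that("noiseless per-beat rendered morphology matches ground truth", {
  cfg <- noiseless_config(baseline_p2p1 = 1.1, duration_s = 60)
  ses <- generate_session(cfg)
  onsets <- ses$truth$beat_onsets_s
  fs <- ses$recording$fs
  segs <- segment_pulses(ses$recording$icp_mmHg, onsets, fs)
  for (k in c(1, 30, 60)) {
    m <- locate_peaks(segs[[k]]$samples)
    expect_equal(m$p2p1_ratio, ses$truth$true_p2p1_per_beat[k],
                 tolerance = 0.02)
  }
})

test_that("same seed gives bit-identical sessions, different seeds differ", {
  a <- generate_session(session_config(seed = 11L, duration_s = 60,
                                       compression_start_s = 0,
                                       compression_duration_s = 0))
  b <- generate_session(session_config(seed = 11L, duration_s = 60,
                                       compression_start_s = 0,
                                       compression_duration_s = 0))
  d <- generate_session(session_config(seed = 12L, duration_s = 60,
                                       compression_start_s = 0,
                                       compression_duration_s = 0))
  expect_identical(a$recording$icp_mmHg, b$recording$icp_mmHg)
  expect_identical(a$recording$b4c_um, b$recording$b4c_um)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$recording$icp_mmHg, d$recording$icp_mmHg))
})

test_that("artifact injection matches the configured rate and spike scale", {
  cfg <- session_config(artifact_rate = 0, seed = 21L)
  ses <- generate_session(cfg)
  # rate 0 leaves the recording untouched
  same <- inject_artifacts(ses$recording, ses$truth, rate = 0)
  expect_identical(same$recording$icp_mmHg, ses$recording$icp_mmHg)
  expect_length(same$truth$artifact_beat_indices, 0L)

  # rate 1/min on a 10-min session corrupts exactly 10 beats
  inj <- inject_artifacts(ses$recording, ses$truth, rate = 1, seed = 5L)
  expect_length(inj$truth$artifact_beat_indices, 10L)
  inj2 <- inject_artifacts(ses$recording, ses$truth, rate = 1, seed = 5L)
  expect_identical(inj$recording$icp_mmHg, inj2$recording$icp_mmHg)

  # spike beats reach >= 5x the median beat peak-to-trough amplitude
  fs <- ses$recording$fs
  cyc <- 60 / cfg$heart_rate_bpm
  beat_amp <- function(x, k) {
    i <- (floor(ses$truth$beat_onsets_s[k] * fs) + 1):
      min(length(x), floor((ses$truth$beat_onsets_s[k] + cyc) * fs))
    max(x[i]) - min(x[i])
  }
  med <- median(vapply(seq_along(ses$truth$beat_onsets_s),
                       function(k) beat_amp(ses$recording$icp_mmHg, k),
                       numeric(1)))
  amps <- vapply(inj$truth$artifact_beat_indices,
                 function(k) beat_amp(inj$recording$icp_mmHg, k), numeric(1))
  # half the injected beats are spikes, half dropouts; spikes are huge
  expect_true(any(amps >= 5 * med))
  expect_true(all(amps[amps > 2 * med] >= 5 * med))
})

test_that("cohort generation is deterministic with exact group counts", {
  mix <- c(intact = 12 / 41, craniotomy_fracture = 20 / 41,
           craniectomy = 9 / 41)
  coh <- generate_cohort(41, mix, seed = 9L, duration_s = 30,
                         compression_start_s = 0,
                         compression_duration_s = 0, artifact_rate = 0)
  groups <- vapply(coh, function(s) s$config$group, character(1))
  expect_equal(unname(table(groups)[c("intact", "craniotomy_fracture",
                                      "craniectomy")]),
               table(c(rep("a", 12), rep("b", 20), rep("c", 9))),
               ignore_attr = TRUE)
  coh2 <- generate_cohort(41, mix, seed = 9L, duration_s = 30,
                          compression_start_s = 0,
                          compression_duration_s = 0, artifact_rate = 0)
  expect_identical(lapply(coh, function(s) s$recording$icp_mmHg),
                   lapply(coh2, function(s) s$recording$icp_mmHg))

  one <- generate_cohort(1, c(intact = 1), seed = 2L, duration_s = 30,
                         compression_start_s = 0,
                         compression_duration_s = 0)
  expect_length(one, 1L)
  expect_identical(one[[1]]$config$group, "intact")

  expect_error(generate_cohort(0), ">= 1")
  expect_error(generate_cohort(5, c(intact = 0.5, craniectomy = 0.2)),
               "sum to 1")
})
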