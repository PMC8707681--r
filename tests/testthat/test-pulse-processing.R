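test_that("detect_beats errors on flat or too-short input", {
  expect_error(detect_beats(rep(80, 2000), fs = 200), "flat")
  expect_error(detect_beats(rnorm(100), fs = 200), "2 s")
})

test_that("detect_beats recovers the generated beat train", {
  # default 10-min session at 70 bpm: exactly 700 onsets
  ses <- generate_session(session_config(seed = 42L))
  on <- detect_beats(ses$recording$abp_mmHg, ses$recording$fs)
  expect_length(on, 700L)
  expect_true(all(diff(on) > 0))
  expect_true(all(diff(on) >= 0.25))

  # noiseless 60-s strip at 60 bpm: onsets within 1 sample of ground truth
  ses0 <- generate_session(noiseless_config(duration_s = 60,
                                            heart_rate_bpm = 60))
  on0 <- detect_beats(ses0$recording$abp_mmHg, 200)
  expect_length(on0, 60L)
  expect_true(all(abs(on0 - ses0$truth$beat_onsets_s) <= 1 / 200 + 1e-9))

  # default noise level: >= 99% of true onsets recovered within 20 ms
  recovered <- vapply(ses$truth$beat_onsets_s,
                      function(o) any(abs(on - o) <= 0.020), logical(1))
  expect_gte(mean(recovered), 0.99)
})

test_that("segment_pulses cuts onset-to-onset, re-based to zero", {
  sig <- sin(seq(0, 20, by = 1 / 200)) + 5
  expect_length(segment_pulses(sig, c(0, 1, 2), 200), 2L)
  expect_error(segment_pulses(sig, c(1, 1, 2), 200), "increasing")
  expect_error(segment_pulses(sig, 1, 200), "2 onsets")

  ses <- generate_session(noiseless_config(duration_s = 60))
  segs <- segment_pulses(ses$recording$icp_mmHg, ses$truth$beat_onsets_s,
                         200)
  expect_length(segs, 70L)  # recording ends on a beat boundary
  expect_true(all(vapply(segs, function(s) s$samples[1] == 0, logical(1))))
  lens <- vapply(segs, function(s) length(s$samples), numeric(1))
  expect_true(all(abs(lens - 200 * 60 / 70) <= 1))
})

test_that("artifact flagging catches spikes and dropouts, spares clean beats", {
  expect_error(exclude_artifacts(list()), "insufficient")

  # identical clean beats: nothing flagged
  tpl <- make_pulse_template(pulse_shape(), 60 / 70, 200)
  clean <- lapply(1:30, function(i) {
    structure(list(channel_id = "icp", onset_s = (i - 1) * 60 / 70,
                   duration_s = 60 / 70, samples = tpl, quality = "useful"),
              class = "beat_segment")
  })
  out <- exclude_artifacts(clean)
  expect_true(all(vapply(out, function(s) s$quality == "useful",
                         logical(1))))

  # simulator-injected artifacts on a noiseless run: exact recovery
  cfg <- noiseless_config(duration_s = 300)
  ses <- generate_session(cfg)
  inj <- inject_artifacts(ses$recording, ses$truth, rate = 2, seed = 8L)
  segs <- segment_pulses(inj$recording$icp_mmHg, inj$truth$beat_onsets_s,
                         200)
  segs <- exclude_artifacts(segs)
  flagged <- which(vapply(segs, function(s) s$quality == "artifact",
                          logical(1)))
  truth_idx <- inj$truth$artifact_beat_indices
  truth_idx <- truth_idx[truth_idx <= length(segs)]
  expect_setequal(flagged, truth_idx)

  # a flat dropout beat fails the template-correlation criterion even when
  # its duration and (tiny) amplitude could pass the robust bounds
  segs2 <- clean
  segs2[[7]]$samples <- rep(0, length(tpl))
  out2 <- exclude_artifacts(segs2)
  expect_identical(out2[[7]]$quality, "artifact")
})

test_that("minute_average pools useful beats with correct bookkeeping", {
  tpl <- make_pulse_template(pulse_shape(), 60 / 70, 200)
  mk <- function(i, samples, quality = "useful") {
    structure(list(channel_id = "icp", onset_s = (i - 1) * 60 / 70,
                   duration_s = 60 / 70, samples = samples,
                   quality = quality),
              class = "beat_segment")
  }
  segs <- lapply(1:20, function(i) mk(i, tpl))
  mp <- minute_average(segs)
  expect_length(mp, 1L)
  expect_equal(mp[[1]]$n_useful, 20L)
  expect_equal(max(abs(mp[[1]]$per_sample_sd)), 0, tolerance = 1e-12)
  # the mean of identical pulses is the pulse (up to resampling)
  expect_equal(mp[[1]]$mean_pulse,
               approx((seq_along(tpl) - 1) / length(tpl), tpl,
                      xout = (0:99) / 100, rule = 2)$y,
               tolerance = 1e-12)

  # two populations p and p + delta in equal number: mean is p + delta/2
  delta <- 0.5
  segs2 <- c(lapply(1:10, function(i) mk(i, tpl)),
             lapply(11:20, function(i) mk(i, tpl + delta)))
  mp2 <- minute_average(segs2)
  base <- approx((seq_along(tpl) - 1) / length(tpl), tpl,
                 xout = (0:99) / 100, rule = 2)$y
  expect_equal(mp2[[1]]$mean_pulse, base + delta / 2, tolerance = 1e-12)

  # order permutation within the minute changes nothing
  set.seed(4)
  mp3 <- minute_average(segs2[sample(20)])
  expect_equal(mp3[[1]]$mean_pulse, mp2[[1]]$mean_pulse)

  # flagged beats are excluded but counted
  segs4 <- segs
  segs4[[3]]$quality <- "artifact"
  mp4 <- minute_average(segs4)
  expect_equal(mp4[[1]]$n_useful, 19L)
  expect_equal(mp4[[1]]$n_excluded, 1L)
  expect_equal(mp4[[1]]$n_useful + mp4[[1]]$n_excluded, 20L)
})

test_that("a noiseless 10-min session yields 10 minutes of 70 useful beats", {
  ses <- generate_session(noiseless_config(duration_s = 600))
  segs <- segment_pulses(ses$recording$icp_mmHg, ses$truth$beat_onsets_s,
                         200)
  segs <- exclude_artifacts(segs)
  mp <- minute_average(segs)
  expect_length(mp, 10L)
  expect_true(all(vapply(mp, function(m) m$n_useful, numeric(1)) == 70))
  expect_false(any(vapply(mp, function(m) m$low_support, logical(1))))
})
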