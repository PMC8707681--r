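# Shared fixtures, all generated in code.

# A session config with every stochastic/modulation term switched off: the
# rendered channels are then exact analytic pulse trains.
noiseless_config <- function(baseline_p2p1 = 1.0, duration_s = 120,
                             heart_rate_bpm = 70, ...) {
  session_config(duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
                 baseline_p2p1 = baseline_p2p1,
                 noise_sd_icp = 0, noise_sd_b4c = 0, noise_sd_abp = 0,
                 drift_amplitude_b4c = 0, artifact_rate = 0,
                 resp_mod_frac = 0, resp_baseline_mmHg = 0,
                 compression_start_s = 0, compression_duration_s = 0,
                 seed = 1L, ...)
}

# Independent brute-force oracle for the apparent morphology of a sum of
# three Gaussian bumps: direct evaluation on a fine grid plus a naive scan
# for local maxima. Written against the analytic definition, not against
# any package internals.
oracle_gauss_sum <- function(lat, amp, wid, n_grid = 200001L) {
  p <- seq(0, 1, length.out = n_grid)
  y <- amp[1] * exp(-0.5 * ((p - lat[1]) / wid[1])^2) +
    amp[2] * exp(-0.5 * ((p - lat[2]) / wid[2])^2) +
    amp[3] * exp(-0.5 * ((p - lat[3]) / wid[3])^2)
  y <- y - (y[1] + (y[n_grid] - y[1]) * p)   # endpoints to zero
  list(phase = p, y = y)
}

oracle_local_maxima <- function(y) {
  idx <- integer(0)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) idx <- c(idx, i)
  }
  idx
}

# Apparent P1/P2 of the analytic sum via the brute-force grid: highest local
# maxima in the two standard windows.
oracle_apparent <- function(lat, amp, wid) {
  g <- oracle_gauss_sum(lat, amp, wid)
  mx <- oracle_local_maxima(g$y)
  w1 <- mx[g$phase[mx] >= 0.05 & g$phase[mx] < 0.30]
  w2 <- mx[g$phase[mx] >= 0.25 & g$phase[mx] < 0.60]
  i1 <- w1[which.max(g$y[w1])]
  i2 <- w2[which.max(g$y[w2])]
  list(p1_pos = g$phase[i1], p1_amp = g$y[i1] - g$y[1],
       p2_pos = g$phase[i2], p2_amp = g$y[i2] - g$y[1],
       ratio = (g$y[i2] - g$y[1]) / (g$y[i1] - g$y[1]),
       ttp = g$phase[which.max(g$y)])
}

# Correlated Gaussian pairs (rho = 0.6) of size n under a fixed seed.
with_seed_xy <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  list(x = x, y = y)
}

# Brute-force Mann-Whitney AUC written independently in the test suite.
oracle_auc <- function(scores, labels) {
  sp <- scores[as.logical(labels)]
  sn <- scores[!as.logical(labels)]
  s <- 0
  for (a in sp) for (b in sn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(sp) * length(sn))
}
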