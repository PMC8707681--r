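#' Configuration for one simulated monitoring session
#'
#' Describes a single paired-recording session: a 10-minute (default)
#' multichannel recording with an internal-jugular-vein compression plateau
#' starting at minute 7 and lasting 60 s. The generator renders three
#' synchronized channels — invasive ICP (mmHg), noninvasive cranial
#' micro-displacement (micrometres) and arterial blood pressure (mmHg) —
#' sharing one cardiac pulse morphology.
#'
#' `baseline_p2p1` is the generative component-amplitude ratio a2/a1 of the
#' pulse model; during the compression window it is shifted by
#' `compression_delta_p2p1` (negative for the craniectomy group).
#' `baseline_icp_mmHg` is the mean ICP of the channel including the pulsatile
#' component, i.e. the quantity a bedside monitor trends.
#'
#' @param duration_s session length in seconds (default 600).
#' @param fs sampling rate, samples/s (default 200, must be >= 50).
#' @param heart_rate_bpm constant heart rate, 20-200 (default 70: a 600-s
#'   session then holds exactly 700 beats).
#' @param resp_rate_bpm respiratory rate (default 15).
#' @param group one of `"intact"`, `"craniotomy_fracture"`, `"craniectomy"`.
#' @param baseline_icp_mmHg mean ICP outside compression.
#' @param compression_start_s,compression_duration_s the compression window
#'   (defaults 420 and 60 s).
#' @param compression_delta_icp_mmHg plateau height added to the ICP baseline
#'   during compression.
#' @param baseline_p2p1 generative a2/a1 outside compression (> 0).
#' @param compression_delta_p2p1 shift of a2/a1 during compression.
#' @param noise_sd_icp,noise_sd_b4c,noise_sd_abp white sensor noise SDs in
#'   channel units.
#' @param drift_amplitude_b4c amplitude (micrometres) of the slow sinusoidal
#'   baseline drift of the displacement channel.
#' @param artifact_rate motion/dropout artifacts per minute (default 2).
#' @param seed integer RNG seed; the session is a pure function of the config.
#' @param pulse_amplitude_icp P1 component height on the ICP channel, mmHg.
#' @param b4c_gain_um_per_mmHg displacement-channel gain. Absolute
#'   displacement values are arbitrary (the real device does not disclose
#'   calibrated pressure); morphology ratios are gain-invariant.
#' @param latencies,widths pulse component latencies and widths as fractions
#'   of the cycle (see [pulse_shape()]).
#' @param p3_rel P3 amplitude relative to P1.
#' @param resp_mod_frac depth of the per-beat respiratory amplitude
#'   modulation (0 disables).
#' @param resp_baseline_mmHg amplitude of the additive respiratory baseline
#'   wave on the ICP channel (0 disables).
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration_s = 600,
                           fs = 200,
                           heart_rate_bpm = 70,
                           resp_rate_bpm = 15,
                           group = c("intact", "craniotomy_fracture",
                                     "craniectomy"),
                           baseline_icp_mmHg = 15.2,
                           compression_start_s = 420,
                           compression_duration_s = 60,
                           compression_delta_icp_mmHg = 4.1,
                           baseline_p2p1 = 1.0,
                           compression_delta_p2p1 = 0.08,
                           noise_sd_icp = 0.5,
                           noise_sd_b4c = 0.3,
                           noise_sd_abp = 1.0,
                           drift_amplitude_b4c = 2.0,
                           artifact_rate = 2,
                           seed = 1L,
                           pulse_amplitude_icp = 4,
                           b4c_gain_um_per_mmHg = 1,
                           latencies = c(0.15, 0.40, 0.65),
                           widths = c(0.08, 0.10, 0.09),
                           p3_rel = 0.45,
                           resp_mod_frac = 0.1,
                           resp_baseline_mmHg = 0.5) {
  group <- match.arg(group)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fs, "fs", min = 50)
  check_number(heart_rate_bpm, "heart_rate_bpm", min = 20, max = 200)
  check_number(resp_rate_bpm, "resp_rate_bpm", min = 0, strict_min = TRUE)
  check_number(compression_start_s, "compression_start_s", min = 0)
  check_number(compression_duration_s, "compression_duration_s", min = 0)
  if (compression_start_s + compression_duration_s > duration_s) {
    stop("compression window must end within the session", call. = FALSE)
  }
  check_number(baseline_p2p1, "baseline_p2p1", min = 0, strict_min = TRUE)
  check_number(noise_sd_icp, "noise_sd_icp", min = 0)
  check_number(noise_sd_b4c, "noise_sd_b4c", min = 0)
  check_number(noise_sd_abp, "noise_sd_abp", min = 0)
  check_number(artifact_rate, "artifact_rate", min = 0)
  check_number(pulse_amplitude_icp, "pulse_amplitude_icp", min = 0)
  check_number(b4c_gain_um_per_mmHg, "b4c_gain_um_per_mmHg",
               min = 0, strict_min = TRUE)
  cfg <- list(duration_s = duration_s, fs = fs,
              heart_rate_bpm = heart_rate_bpm,
              resp_rate_bpm = resp_rate_bpm, group = group,
              baseline_icp_mmHg = baseline_icp_mmHg,
              compression_start_s = compression_start_s,
              compression_duration_s = compression_duration_s,
              compression_delta_icp_mmHg = compression_delta_icp_mmHg,
              baseline_p2p1 = baseline_p2p1,
              compression_delta_p2p1 = compression_delta_p2p1,
              noise_sd_icp = noise_sd_icp, noise_sd_b4c = noise_sd_b4c,
              noise_sd_abp = noise_sd_abp,
              drift_amplitude_b4c = drift_amplitude_b4c,
              artifact_rate = artifact_rate, seed = as.integer(seed),
              pulse_amplitude_icp = pulse_amplitude_icp,
              b4c_gain_um_per_mmHg = b4c_gain_um_per_mmHg,
              latencies = latencies, widths = widths, p3_rel = p3_rel,
              resp_mod_frac = resp_mod_frac,
              resp_baseline_mmHg = resp_baseline_mmHg)
  structure(cfg, class = "session_config")
}

# Pulse shape for a given generative a2/a1 under a session config.
config_shape <- function(config, ratio) {
  a1 <- config$pulse_amplitude_icp
  pulse_shape(latencies = config$latencies,
              amplitudes = c(a1, ratio * a1, config$p3_rel * a1),
              widths = config$widths)
}

# Raised-cosine plateau profile in [0, 1] with `ramp_s` edges.
plateau_profile <- function(t, lo, hi, ramp_s = 2) {
  if (hi <= lo) return(numeric(length(t)))
  ramp_s <- min(ramp_s, (hi - lo) / 2)
  p <- numeric(length(t))
  core <- t >= (lo + ramp_s) & t <= (hi - ramp_s)
  p[core] <- 1
  up <- t >= lo & t < lo + ramp_s
  p[up] <- 0.5 * (1 - cos(pi * (t[up] - lo) / ramp_s))
  down <- t > hi - ramp_s & t <= hi
  p[down] <- 0.5 * (1 - cos(pi * (hi - t[down]) / ramp_s))
  p
}

# ABP beat shape: gamma-like pulse rising from exactly 0 at the beat onset
# to a systolic peak at ~22% of the cycle, with a small dicrotic bump and a
# monotone diastolic decay that stays above 0 through end-diastole. The
# onset sample is therefore the unique within-cycle minimum — an unambiguous
# diastolic trough immediately preceding the upstroke.
abp_wave <- function(phase) {
  w <- (phase / 0.26)^1.3 * exp(-(phase - 0.26) / 0.20)
  w + 0.12 * exp(-0.5 * ((phase - 0.50) / 0.045)^2)
}

#' Generate one paired invasive/noninvasive recording
#'
#' Renders a synchronized three-channel recording under `config` together
#' with beat-level ground truth. The ICP channel is mean-centred pulse train
#' plus respiratory modulation, compression plateau and white noise; the
#' displacement channel renders the identical per-beat morphology through an
#' independent gain with its own drift and noise; the ABP channel carries an
#' unambiguous systolic upstroke anchoring every beat. With
#' `artifact_rate > 0`, motion spikes and flat dropouts are injected into the
#' ICP and displacement channels (never ABP) via [inject_artifacts()].
#'
#' Ground truth holds, per beat: onset time, apparent P2/P1 ratio and
#' time-to-peak of the noiseless analytic pulse (dense-grid definition, see
#' [apparent_morphology()]), plus per-minute true mean ICP and the injected
#' artifact beat indices.
#'
#' @param config a [session_config()] object.
#' @return List with elements `recording` (class `paired_recording`: `time_s`,
#'   `icp_mmHg`, `b4c_um`, `abp_mmHg`, `fs`, `metadata`) and `truth` (class
#'   `ground_truth`).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "session_config")) {
    stop("`config` must be a session_config object", call. = FALSE)
  }
  out <- with_seed(config$seed, {
    fs <- config$fs
    dur <- config$duration_s
    cycle <- 60 / config$heart_rate_bpm
    n_beats <- floor(dur * config$heart_rate_bpm / 60)
    if (n_beats < 1L) stop("session too short for one beat", call. = FALSE)
    onsets <- (seq_len(n_beats) - 1) * cycle
    n <- round(dur * fs)
    t <- (seq_len(n) - 1) / fs

    comp_lo <- config$compression_start_s
    comp_hi <- comp_lo + config$compression_duration_s
    in_comp <- onsets >= comp_lo & onsets < comp_hi
    ratio_beat <- config$baseline_p2p1 +
      ifelse(in_comp, config$compression_delta_p2p1, 0)

    # per-beat respiratory amplitude factor, frozen at beat onset
    f_resp <- config$resp_rate_bpm / 60
    m_beat <- 1 + config$resp_mod_frac * sin(2 * pi * f_resp * onsets)

    # beat index / phase for every sample (trailing partial beat, if any,
    # reuses the last beat's morphology)
    b <- floor(t / cycle + 1e-12)
    phase <- t / cycle - b
    bi <- pmin(b + 1L, n_beats)

    # analytic pulse for each distinct generative ratio
    ratios <- sort(unique(ratio_beat))
    shapes <- lapply(ratios, function(r) config_shape(config, r))
    names(shapes) <- as.character(ratios)
    pulse <- numeric(n)
    centred <- numeric(n)
    for (k in seq_along(ratios)) {
      sel <- ratio_beat[bi] == ratios[k]
      y <- eval_pulse_phase(phase[sel], shapes[[k]])
      pulse[sel] <- y
      centred[sel] <- y - pulse_cycle_mean(shapes[[k]])
    }
    m <- m_beat[bi]

    plateau <- config$compression_delta_icp_mmHg *
      plateau_profile(t, comp_lo, comp_hi)
    resp_base <- config$resp_baseline_mmHg * sin(2 * pi * f_resp * t)

    icp_clean <- config$baseline_icp_mmHg + plateau + resp_base + m * centred
    icp <- icp_clean + stats::rnorm(n, 0, config$noise_sd_icp)

    drift_phase <- stats::runif(1, 0, 2 * pi)
    drift <- config$drift_amplitude_b4c * sin(2 * pi * t / 100 + drift_phase)
    gain <- config$b4c_gain_um_per_mmHg
    b4c <- gain * m * pulse + drift + stats::rnorm(n, 0, config$noise_sd_b4c)

    abp <- 80 + 40 * abp_wave(phase) + stats::rnorm(n, 0, config$noise_sd_abp)

    # dense-grid apparent morphology per distinct ratio (NA when the pulse
    # is degenerate, e.g. zero amplitude)
    app <- lapply(shapes, function(sh) {
      tryCatch(apparent_morphology(sh),
               error = function(e) list(p2p1_ratio = NA_real_,
                                        ttp = NA_real_))
    })
    idx <- match(as.character(ratio_beat), names(app))
    true_p2p1 <- vapply(app, function(a) a$p2p1_ratio, numeric(1))[idx]
    true_ttp <- vapply(app, function(a) a$ttp, numeric(1))[idx]

    n_min <- floor(dur / 60)
    minute_of <- findInterval(t, seq(0, n_min) * 60, rightmost.closed = FALSE)
    full <- minute_of >= 1 & minute_of <= n_min
    true_mean_icp <- as.numeric(tapply(icp_clean[full], minute_of[full], mean))

    recording <- structure(
      list(time_s = t, icp_mmHg = icp, b4c_um = b4c, abp_mmHg = abp,
           fs = fs, metadata = config),
      class = "paired_recording")
    truth <- structure(
      list(beat_onsets_s = onsets,
           true_p2p1_per_beat = as.numeric(true_p2p1),
           true_ttp_per_beat = as.numeric(true_ttp),
           true_mean_icp_per_minute = true_mean_icp,
           artifact_beat_indices = integer(0)),
      class = "ground_truth")
    art_seed <- sample.int(.Machine$integer.max - 1L, 1)
    list(recording = recording, truth = truth, art_seed = art_seed)
  })
  if (config$artifact_rate > 0) {
    inject_artifacts(out$recording, out$truth,
                     rate = config$artifact_rate, seed = out$art_seed)
  } else {
    list(recording = out$recording, truth = out$truth)
  }
}

#' Inject motion-spike and dropout artifacts into a recording
#'
#' Corrupts `round(rate * minutes)` randomly chosen beats on the ICP and
#' displacement channels (the arterial line is a separate transducer and is
#' left clean). A motion spike adds a narrow transient of 8x the channel's
#' median beat peak-to-trough amplitude; a dropout flattens the beat to its
#' onset value. Corrupted beat indices are recorded in the ground truth;
#' nothing is deleted.
#'
#' @param recording a `paired_recording`.
#' @param truth the matching `ground_truth`.
#' @param rate artifacts per minute (>= 0).
#' @param seed integer seed for beat/type selection.
#' @return List `(recording, truth)` with corrupted channels and updated
#'   `artifact_beat_indices`.
#' @export
inject_artifacts <- function(recording, truth, rate, seed = 1L) {
  if (!inherits(recording, "paired_recording")) {
    stop("`recording` must be a paired_recording", call. = FALSE)
  }
  check_number(rate, "rate", min = 0)
  n_art <- round(rate * recording$metadata$duration_s / 60)
  if (n_art == 0) {
    return(list(recording = recording, truth = truth))
  }
  with_seed(seed, {
    fs <- recording$fs
    onsets <- truth$beat_onsets_s
    n_beats <- length(onsets)
    cycle <- 60 / recording$metadata$heart_rate_bpm
    n <- length(recording$time_s)
    n_art <- min(n_art, n_beats)
    beats <- sort(sample.int(n_beats, n_art))
    types <- sample(c("spike", "dropout"), n_art, replace = TRUE)

    beat_idx <- function(k) {
      i0 <- floor(onsets[k] * fs) + 1L
      i1 <- min(n, floor((onsets[k] + cycle) * fs))
      i0:i1
    }
    # channel-wise median beat peak-to-trough, the spike reference scale
    amp_ref <- function(x) {
      stats::median(vapply(seq_len(n_beats), function(k) {
        v <- x[beat_idx(k)]
        max(v) - min(v)
      }, numeric(1)))
    }
    ref <- c(icp_mmHg = amp_ref(recording$icp_mmHg),
             b4c_um = amp_ref(recording$b4c_um))
    for (j in seq_len(n_art)) {
      idx <- beat_idx(beats[j])
      tc <- onsets[beats[j]] + cycle / 2
      sgn <- sample(c(-1, 1), 1)
      for (ch in c("icp_mmHg", "b4c_um")) {
        if (types[j] == "spike") {
          bump <- 8 * ref[[ch]] *
            exp(-0.5 * ((recording$time_s[idx] - tc) / 0.012)^2)
          recording[[ch]][idx] <- recording[[ch]][idx] + sgn * bump
        } else {
          recording[[ch]][idx] <- recording[[ch]][idx[1]]
        }
      }
    }
    truth$artifact_beat_indices <-
      sort(unique(c(truth$artifact_beat_indices, beats)))
    list(recording = recording, truth = truth)
  })
}
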