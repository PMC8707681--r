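# P1/P2 landmark reading shared by the estimator (resampled averaged pulses)
# and the dense-grid ground-truth oracle (analytic pulses). P1 is the highest
# local maximum in the early window, P2 the highest in the mid window to the
# right of P1. When a window holds no local maximum (merged shoulder), the
# landmark falls back to the inflection point — zero crossing of the
# (optionally Savitzky-Golay smoothed) second derivative — inside the window
# nearest the other landmark, or nearest the window centre if the other
# landmark is also missing.
find_landmarks <- function(y, phase,
                           p1_window = c(0.05, 0.30),
                           p2_window = c(0.25, 0.60),
                           smooth = TRUE, sg_n = 11L) {
  n <- length(y)
  span <- max(y) - min(y)
  if (!is.finite(span) || span < 1e-12 * max(abs(y), 1e-300)) {
    stop("morphology undetermined: flat pulse", call. = FALSE)
  }
  maxima <- local_maxima(y)

  in_win <- function(idx, win) idx[phase[idx] >= win[1] & phase[idx] < win[2]]
  pick_highest <- function(idx) if (length(idx)) idx[which.max(y[idx])] else NA_integer_

  i1 <- pick_highest(in_win(maxima, p1_window))
  cand2 <- in_win(maxima, p2_window)
  if (!is.na(i1)) cand2 <- cand2[cand2 > i1]
  i2 <- pick_highest(cand2)

  merged <- FALSE
  if (is.na(i1) || is.na(i2)) {
    ys <- if (smooth && n >= sg_n) signal::sgolayfilt(y, p = 3, n = sg_n) else y
    d2 <- diff(ys, differences = 2)          # d2[j] ~ curvature at j + 1
    cross <- which(d2[-length(d2)] * d2[-1] < 0)
    infl <- vapply(cross, function(j) {
      if (abs(d2[j]) <= abs(d2[j + 1])) j + 1L else j + 2L
    }, integer(1))
    nearest <- function(idx, target) idx[which.min(abs(phase[idx] - target))]
    if (is.na(i2)) {
      cc <- in_win(infl, p2_window)
      if (!is.na(i1)) cc <- cc[cc > i1]
      if (length(cc)) {
        target <- if (!is.na(i1)) phase[i1] else mean(p2_window)
        i2 <- nearest(cc, target)
        merged <- TRUE
      }
    }
    if (is.na(i1)) {
      cc <- in_win(infl, p1_window)
      if (!is.na(i2)) cc <- cc[cc < i2]
      if (length(cc)) {
        target <- if (!is.na(i2)) phase[i2] else mean(p1_window)
        i1 <- nearest(cc, target)
        merged <- TRUE
      }
    }
  }
  if (is.na(i1) || is.na(i2)) {
    stop("morphology undetermined: no landmark in search window",
         call. = FALSE)
  }
  base <- y[1]
  p1_amp <- y[i1] - base
  p2_amp <- y[i2] - base
  if (p1_amp <= 0) {
    stop("morphology undetermined: nonpositive P1 amplitude", call. = FALSE)
  }
  list(p1_pos = phase[i1], p1_amp = p1_amp,
       p2_pos = phase[i2], p2_amp = p2_amp,
       p2p1_ratio = p2_amp / p1_amp,
       ttp = phase[which.max(y)],
       merged_peaks = merged)
}

#' Locate P1 and P2 on an averaged pulse
#'
#' Reads the two landmark peaks off a per-minute ensemble-averaged pulse.
#' P1 is searched in the early-cycle window, P2 in the mid-cycle window; when
#' peaks have merged into a shoulder the missing landmark is placed at the
#' smoothed-second-derivative inflection inside its window (and
#' `merged_peaks` is set). Amplitudes are measured above the pulse-onset
#' value. All operations are scale-relative: multiplying the channel by any
#' positive gain changes neither positions nor the amplitude ratio.
#'
#' @param pulse a `minute_pulse` or a numeric averaged pulse (>= 50 samples,
#'   sample k at cycle phase (k-1)/length).
#' @param p1_window,p2_window search windows as fractions of the cycle.
#' @param sg_n Savitzky-Golay window (samples) for the shoulder fallback.
#' @return List with `p1_pos`, `p1_amp`, `p2_pos`, `p2_amp`, `p2p1_ratio`,
#'   `ttp`, `merged_peaks`.
#' @export
locate_peaks <- function(pulse, p1_window = c(0.05, 0.30),
                         p2_window = c(0.25, 0.60), sg_n = 11L) {
  y <- if (inherits(pulse, "minute_pulse")) pulse$mean_pulse else pulse
  if (is.null(y) || !is.numeric(y)) {
    stop("`pulse` must carry a numeric averaged pulse", call. = FALSE)
  }
  if (length(y) < 50) {
    stop("averaged pulse must have >= 50 samples", call. = FALSE)
  }
  phase <- (seq_along(y) - 1) / length(y)
  find_landmarks(y, phase, p1_window = p1_window, p2_window = p2_window,
                 smooth = TRUE, sg_n = sg_n)
}

#' P2/P1 amplitude ratio
#'
#' @param p1_amp,p2_amp landmark amplitudes above the pulse-onset value;
#'   `p1_amp` must be > 0.
#' @return `p2_amp / p1_amp`.
#' @export
compute_ratio <- function(p1_amp, p2_amp) {
  if (!is.numeric(p1_amp) || !is.numeric(p2_amp)) {
    stop("amplitudes must be numeric", call. = FALSE)
  }
  if (any(p1_amp <= 0)) {
    stop("undefined ratio: P1 amplitude must be > 0", call. = FALSE)
  }
  p2_amp / p1_amp
}

#' Normalized time-to-peak of an averaged pulse
#'
#' Position of the global maximum measured from pulse onset, as a fraction of
#' the cardiac cycle in [0, 1). When the P2/P1 ratio crosses 1 the global
#' peak hops from the P1 to the P2 latency, so TTP is a coarse compliance
#' marker in its own right.
#'
#' @param pulse a `minute_pulse` or numeric averaged pulse.
#' @return TTP as a fraction of the cycle.
#' @export
compute_ttp <- function(pulse) {
  y <- if (inherits(pulse, "minute_pulse")) pulse$mean_pulse else pulse
  if (is.null(y) || !is.numeric(y) || length(y) < 2) {
    stop("`pulse` must carry a numeric averaged pulse", call. = FALSE)
  }
  if (max(y) - min(y) < 1e-12 * max(abs(y), 1e-300)) {
    stop("time-to-peak undefined: flat pulse", call. = FALSE)
  }
  (which.max(y) - 1) / length(y)
}

#' Morphology series over per-minute averaged pulses
#'
#' Applies [locate_peaks()] and [compute_ttp()] to every minute; minutes
#' where no landmark is resolvable (or with zero useful beats) are carried as
#' explicit `NA` rows with `determined = FALSE` rather than dropped.
#'
#' @param minutes list of `minute_pulse` objects.
#' @param p1_window,p2_window landmark search windows.
#' @return data.frame with one row per minute: `minute_index`, `p1_pos`,
#'   `p1_amp`, `p2_pos`, `p2_amp`, `p2p1_ratio`, `ttp`, `pulse_amplitude`,
#'   `merged_peaks`, `n_useful`, `n_excluded`, `low_support`, `determined`.
#' @export
morphology_series <- function(minutes, p1_window = c(0.05, 0.30),
                              p2_window = c(0.25, 0.60)) {
  rows <- lapply(minutes, function(mp) {
    out <- data.frame(minute_index = mp$minute_index,
                      p1_pos = NA_real_, p1_amp = NA_real_,
                      p2_pos = NA_real_, p2_amp = NA_real_,
                      p2p1_ratio = NA_real_, ttp = NA_real_,
                      pulse_amplitude = NA_real_,
                      merged_peaks = NA, n_useful = mp$n_useful,
                      n_excluded = mp$n_excluded,
                      low_support = mp$low_support, determined = FALSE)
    if (is.null(mp$mean_pulse)) return(out)
    lm <- tryCatch(locate_peaks(mp, p1_window = p1_window,
                                p2_window = p2_window),
                   error = function(e) NULL)
    if (is.null(lm)) return(out)
    out$p1_pos <- lm$p1_pos; out$p1_amp <- lm$p1_amp
    out$p2_pos <- lm$p2_pos; out$p2_amp <- lm$p2_amp
    out$p2p1_ratio <- lm$p2p1_ratio
    out$ttp <- lm$ttp
    out$pulse_amplitude <- max(mp$mean_pulse) - min(mp$mean_pulse)
    out$merged_peaks <- lm$merged_peaks
    out$determined <- TRUE
    out
  })
  do.call(rbind, rows)
}
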