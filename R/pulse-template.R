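#' Pulse shape parameters
#'
#' Parameterizes one intracranial pulse as the sum of three positive Gaussian
#' component bumps: P1 (arterial percussion), P2 (cerebral blood-volume /
#' tidal component) and P3 (dicrotic component after aortic valve closure).
#' Latencies and widths are expressed as fractions of the cardiac cycle, so
#' the shape is heart-rate independent.
#'
#' @param latencies numeric length 3, component centres as fractions of the
#'   cycle, strictly increasing in (0, 1). Default `c(0.15, 0.40, 0.65)`.
#' @param amplitudes numeric length 3, non-negative component peak heights in
#'   channel units (mmHg for the ICP channel, micrometres for the cranial
#'   displacement channel).
#' @param widths numeric length 3, positive Gaussian standard deviations as
#'   fractions of the cycle.
#' @return An object of class `pulse_shape`.
#' @examples
#' sh <- pulse_shape(amplitudes = c(1, 1.2, 0.45))
#' tpl <- make_pulse_template(sh, cycle_s = 60 / 70, fs = 200)
#' @export
pulse_shape <- function(latencies = c(0.15, 0.40, 0.65),
                        amplitudes = c(1, 0.9, 0.45),
                        widths = c(0.08, 0.10, 0.09)) {
  if (length(latencies) != 3L || length(amplitudes) != 3L || length(widths) != 3L) {
    stop("`latencies`, `amplitudes` and `widths` must each have length 3",
         call. = FALSE)
  }
  if (any(!is.finite(latencies)) || any(!is.finite(amplitudes)) ||
      any(!is.finite(widths))) {
    stop("pulse shape parameters must be finite", call. = FALSE)
  }
  if (!(latencies[1] > 0 && latencies[1] < latencies[2] &&
        latencies[2] < latencies[3] && latencies[3] < 1)) {
    stop("latencies must satisfy 0 < t1 < t2 < t3 < 1", call. = FALSE)
  }
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(widths <= 0)) stop("widths must be > 0", call. = FALSE)
  structure(list(latencies = as.numeric(latencies),
                 amplitudes = as.numeric(amplitudes),
                 widths = as.numeric(widths)),
            class = "pulse_shape")
}

# Evaluate the analytic component sum at cycle phases in [0, 1], with the
# chord between the endpoint values subtracted so the pulse starts and ends
# at exactly 0. Used by the template builder, the session renderer and the
# dense-grid ground-truth oracle alike; everything downstream sees the same
# analytic waveform.
eval_pulse_phase <- function(phase, shape) {
  tt <- shape$latencies; aa <- shape$amplitudes; ww <- shape$widths
  g <- function(p) {
    aa[1] * exp(-0.5 * ((p - tt[1]) / ww[1])^2) +
      aa[2] * exp(-0.5 * ((p - tt[2]) / ww[2])^2) +
      aa[3] * exp(-0.5 * ((p - tt[3]) / ww[3])^2)
  }
  f0 <- g(0)
  f1 <- g(1)
  g(phase) - (f0 + (f1 - f0) * phase)
}

# Cycle-mean of the endpoint-corrected pulse, used to centre the ICP pulse
# train so that config baseline ICP is the mean ICP (pulse included).
pulse_cycle_mean <- function(shape, n_grid = 2048L) {
  mean(eval_pulse_phase((seq_len(n_grid) - 1) / n_grid, shape))
}

#' Sample one cardiac cycle of the three-component pulse
#'
#' Renders the analytic component sum over one cycle at sampling rate `fs`.
#' The waveform starts and ends at 0 (the chord between the analytic endpoint
#' values is removed).
#'
#' @param shape a [pulse_shape()] object.
#' @param cycle_s cycle length in seconds (> 0).
#' @param fs sampling rate in samples per second.
#' @return Numeric vector of `round(cycle_s * fs)` samples, one cycle, sample
#'   k at phase (k-1)/n.
#' @export
make_pulse_template <- function(shape, cycle_s, fs) {
  if (!inherits(shape, "pulse_shape")) {
    stop("`shape` must be a pulse_shape object", call. = FALSE)
  }
  check_number(cycle_s, "cycle_s", min = 0, strict_min = TRUE)
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  n <- round(cycle_s * fs)
  if (n < 4L) stop("cycle too short at this sampling rate", call. = FALSE)
  eval_pulse_phase((seq_len(n) - 1) / n, shape)
}

#' Dense-grid apparent morphology of an analytic pulse
#'
#' Ground-truth oracle: evaluates the analytic pulse on a dense phase grid and
#' reads off the apparent P1/P2 landmarks as local maxima inside the standard
#' search windows, plus the global time-to-peak. Because the Gaussian
#' components overlap, the apparent peak heights (and hence the apparent P2/P1
#' ratio) differ slightly from the generative amplitude ratio a2/a1; the
#' simulator's ground truth is defined on this apparent morphology.
#'
#' @param shape a [pulse_shape()] object.
#' @param n_grid grid resolution over one cycle (default 8192).
#' @param p1_window,p2_window phase windows searched for the P1 and P2 local
#'   maxima, as `c(lo, hi)` fractions of the cycle.
#' @return List with `p1_pos`, `p1_amp`, `p2_pos`, `p2_amp`, `p2p1_ratio`,
#'   `ttp` (all positions as fractions of the cycle, amplitudes above the
#'   onset value) and `merged_peaks` (TRUE when a window held no local
#'   maximum and the landmark sits on a shoulder).
#' @export
apparent_morphology <- function(shape, n_grid = 8192L,
                                p1_window = c(0.05, 0.30),
                                p2_window = c(0.25, 0.60)) {
  if (!inherits(shape, "pulse_shape")) {
    stop("`shape` must be a pulse_shape object", call. = FALSE)
  }
  phase <- (seq_len(n_grid) - 1) / n_grid
  y <- eval_pulse_phase(phase, shape)
  find_landmarks(y, phase,
                 p1_window = p1_window, p2_window = p2_window,
                 smooth = FALSE)
}
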