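#' Detect beat onsets from the arterial blood pressure channel
#'
#' Finds one onset per cardiac cycle, placed at the diastolic trough
#' immediately preceding the systolic upstroke. Systolic peaks are located on
#' a lightly smoothed copy of the signal as local maxima above an
#' amplitude-relative threshold, de-duplicated under a 0.25-s refractory
#' period; the onset is the last minimum between consecutive peaks. Both ICP
#' and displacement channels are segmented against these onsets, which is
#' what makes their morphologies comparable beat by beat.
#'
#' @param abp numeric ABP samples (>= 2 s worth).
#' @param fs sampling rate, samples/s.
#' @param refractory_s minimum peak separation in seconds (default 0.25).
#' @return Numeric vector of strictly increasing onset times in seconds.
#' @export
detect_beats <- function(abp, fs, refractory_s = 0.25) {
  if (!is.numeric(abp)) stop("`abp` must be numeric", call. = FALSE)
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  n <- length(abp)
  if (n < 2 * fs) stop("need at least 2 s of ABP samples", call. = FALSE)
  rng <- range(abp)
  if (!is.finite(diff(rng)) ||
      diff(rng) < 1e-10 * max(1, abs(mean(abp)))) {
    stop("no beats detected: ABP channel is flat", call. = FALSE)
  }

  # light moving-average smoothing (centred, ~20 ms)
  k <- max(3L, 2L * floor(0.01 * fs) + 1L)
  sm <- stats::filter(abp, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  half <- (k - 1L) %/% 2L
  sm[seq_len(half)] <- sm[half + 1L]
  sm[(n - half + 1L):n] <- sm[n - half]

  # one systolic peak per contiguous run above the mid-range threshold;
  # noise cannot split a run unless it spans half the pulse amplitude
  q <- stats::quantile(sm, c(0.05, 0.95), names = FALSE)
  thr <- q[1] + 0.5 * (q[2] - q[1])
  above <- sm > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1L)
  ends <- which(edges == -1L) - 1L
  peaks <- vapply(seq_along(starts), function(i) {
    starts[i] - 1L + which.max(sm[starts[i]:ends[i]])
  }, integer(1))
  if (length(peaks) == 0) {
    stop("no beats detected: no systolic peaks above threshold",
         call. = FALSE)
  }
  # screen out low secondary peaks (noise-split runs on the dicrotic edge):
  # systolic peaks cluster near the median peak height
  med_pk <- stats::median(sm[peaks])
  peaks <- peaks[sm[peaks] >= q[1] + 0.7 * (med_pk - q[1])]
  # refractory enforcement: of any pair closer than refractory_s keep taller
  min_gap <- round(refractory_s * fs)
  repeat {
    gaps <- diff(peaks)
    j <- which(gaps < min_gap)
    if (length(j) == 0) break
    j <- j[1]
    drop <- if (sm[peaks[j]] >= sm[peaks[j + 1]]) j + 1L else j
    peaks <- peaks[-drop]
  }

  # trough on the raw signal: the end-diastolic corner is sharp there,
  # whereas smoothing blurs it across neighbouring samples
  spacing <- if (length(peaks) > 1) stats::median(diff(peaks)) else n
  lookback <- round(0.9 * spacing)
  onsets_idx <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1) max(1L, peaks[1] - lookback) else peaks[i - 1] + 1L
    w <- abp[lo:peaks[i]]
    onsets_idx[i] <- lo - 1L + max(which(w == min(w)))
  }
  onsets_idx <- unique(onsets_idx)
  (onsets_idx - 1) / fs
}

#' Cut a channel into beat segments at given onsets
#'
#' Segment i spans onset i (inclusive) to onset i+1 (exclusive). The span
#' after the last onset is emitted as a final segment only when it covers at
#' least 95\% of the median beat length (i.e. the recording ends on a beat
#' boundary); a genuinely partial trailing beat is dropped. Each segment is
#' re-based to start at 0 by subtracting its first sample, which removes
#' baseline drift and the respiratory baseline wave from the per-beat
#' morphology.
#'
#' @param signal numeric channel samples.
#' @param onsets strictly increasing onset times in seconds (>= 2).
#' @param fs sampling rate, samples/s.
#' @param channel_id `"icp"` or `"b4c"`, carried on each segment.
#' @return List of `beat_segment` objects with fields `channel_id`,
#'   `onset_s`, `duration_s`, `samples` (first sample 0), `quality`
#'   (initially `"useful"`).
#' @export
segment_pulses <- function(signal, onsets, fs, channel_id = "icp") {
  if (length(onsets) < 2) stop("need at least 2 onsets", call. = FALSE)
  if (any(diff(onsets) <= 0)) {
    stop("`onsets` must be strictly increasing", call. = FALSE)
  }
  n <- length(signal)
  idx <- round(onsets * fs) + 1L
  if (idx[length(idx)] > n) stop("onsets beyond signal end", call. = FALSE)
  m <- length(idx)
  bounds <- cbind(idx[-m], idx[-1L] - 1L)
  med_len <- stats::median(bounds[, 2] - bounds[, 1] + 1L)
  tail_len <- n - idx[m] + 1L
  if (tail_len >= 0.95 * med_len && tail_len <= 1.05 * med_len) {
    bounds <- rbind(bounds, c(idx[m], n))
  }
  lapply(seq_len(nrow(bounds)), function(i) {
    i0 <- bounds[i, 1]
    i1 <- bounds[i, 2]
    s <- signal[i0:i1]
    structure(list(channel_id = channel_id,
                   onset_s = onsets[i],
                   duration_s = (i1 - i0 + 1L) / fs,
                   samples = s - s[1],
                   quality = "useful"),
              class = "beat_segment")
  })
}
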