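#' Flag artifact beats
#'
#' Robust session-level screening before ensemble averaging. A beat is
#' flagged `"artifact"` when any of:
#' \itemize{
#'   \item peak-to-trough amplitude outside median +/- `k_amp` robust SDs
#'     (MAD-scaled, with a 5\%-of-median floor so tight sessions do not
#'     collapse the band),
#'   \item duration outside median +/- `k_dur` robust SDs (same floor),
#'   \item correlation with the session's per-sample median pulse template
#'     (all beats resampled to a common length) below `cor_min`, or
#'     undefined (flat dropout).
#' }
#' All criteria are scale-relative, so flags are invariant to channel gain.
#' Beats are flagged, never deleted.
#'
#' @param segments list of `beat_segment`s (>= 5).
#' @param k_amp,k_dur robust-SD multipliers (default 3).
#' @param cor_min template-correlation floor (default 0.6).
#' @param resample_n common length for template correlation (default 100).
#' @return The segments with `quality` set to `"useful"` or `"artifact"`.
#' @export
exclude_artifacts <- function(segments, k_amp = 3, k_dur = 3,
                              cor_min = 0.6, resample_n = 100L) {
  if (length(segments) < 5) {
    stop("insufficient beats: need >= 5 segments", call. = FALSE)
  }
  amp <- vapply(segments, function(s) {
    r <- range(s$samples)
    r[2] - r[1]
  }, numeric(1))
  dur <- vapply(segments, function(s) s$duration_s, numeric(1))

  robust_band <- function(x, k) {
    med <- stats::median(x)
    s <- max(stats::mad(x), 0.05 * abs(med), 1e-12 * max(abs(x), 1e-300))
    c(med - k * s, med + k * s)
  }
  band_a <- robust_band(amp, k_amp)
  band_d <- robust_band(dur, k_dur)

  res <- vapply(segments, function(s) resample_beat(s$samples, resample_n),
                numeric(resample_n))
  template <- apply(res, 1, stats::median)
  cors <- vapply(seq_along(segments), function(i) {
    x <- res[, i]
    if (stats::sd(x) < 1e-12 * max(abs(x), 1e-300) || stats::sd(template) == 0) {
      return(NA_real_)
    }
    stats::cor(x, template)
  }, numeric(1))

  bad <- amp < band_a[1] | amp > band_a[2] |
    dur < band_d[1] | dur > band_d[2] |
    is.na(cors) | cors < cor_min
  for (i in seq_along(segments)) {
    segments[[i]]$quality <- if (bad[i]) "artifact" else "useful"
  }
  segments
}

#' Per-minute ensemble-averaged pulses
#'
#' Assigns each beat to minute `floor((onset - session_start_s) / 60)`,
#' resamples the useful beats of a minute to a common length and takes the
#' pointwise mean and SD. Minutes with fewer than `min_support` useful beats
#' are still emitted, carrying a low-support flag.
#'
#' @param segments list of flagged `beat_segment`s.
#' @param session_start_s session time origin (default 0).
#' @param resample_n common resampled beat length (default 100); positions on
#'   the averaged pulse are thereby fractions of the cardiac cycle.
#' @param min_support minimum useful beats for full support (default 10).
#' @return List of `minute_pulse` objects: `minute_index` (0-based),
#'   `mean_pulse`, `per_sample_sd`, `n_useful`, `n_excluded`, `low_support`.
#'   Minutes with zero useful beats have `mean_pulse = NULL`.
#' @export
minute_average <- function(segments, session_start_s = 0,
                           resample_n = 100L, min_support = 10L) {
  if (length(segments) == 0) return(list())
  onset <- vapply(segments, function(s) s$onset_s, numeric(1))
  useful <- vapply(segments, function(s) identical(s$quality, "useful"),
                   logical(1))
  minute <- floor((onset - session_start_s) / 60)
  lapply(sort(unique(minute)), function(mi) {
    in_min <- minute == mi
    use <- in_min & useful
    n_useful <- sum(use)
    n_excluded <- sum(in_min) - n_useful
    if (n_useful == 0) {
      mean_pulse <- NULL
      sd_pulse <- NULL
    } else {
      res <- vapply(segments[use],
                    function(s) resample_beat(s$samples, resample_n),
                    numeric(resample_n))
      res <- matrix(res, nrow = resample_n)
      mean_pulse <- rowMeans(res)
      sd_pulse <- if (n_useful > 1) apply(res, 1, stats::sd) else
        numeric(resample_n)
    }
    structure(list(minute_index = mi,
                   mean_pulse = mean_pulse,
                   per_sample_sd = sd_pulse,
                   n_useful = n_useful,
                   n_excluded = n_excluded,
                   low_support = n_useful < min_support),
              class = "minute_pulse")
  })
}
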