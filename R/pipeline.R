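#' Analysis parameters
#'
#' Bundles the tunable knobs of the per-session pipeline. Defaults are the
#' package's standard operating point; every threshold that is a judgement
#' call (landmark windows, artifact bounds, support floor) is exposed here.
#'
#' @param p1_window,p2_window landmark search windows, fractions of the cycle.
#' @param resample_n common resampled beat length (samples per cycle).
#' @param min_support minimum useful beats for a fully supported minute.
#' @param k_amp,k_dur,cor_min artifact-flagging bounds (see
#'   [exclude_artifacts()]).
#' @param refractory_s beat-detection refractory period, seconds.
#' @param icp_threshold_mmHg intracranial-hypertension label cut-off on the
#'   invasive minute mean (default 20).
#' @param n_boot bootstrap replicates for correlation/AUC CIs.
#' @param seed integer seed for the bootstrap stages.
#' @return List of class `icpw_params`.
#' @export
analysis_params <- function(p1_window = c(0.05, 0.30),
                            p2_window = c(0.25, 0.60),
                            resample_n = 100L,
                            min_support = 10L,
                            k_amp = 3, k_dur = 3, cor_min = 0.6,
                            refractory_s = 0.25,
                            icp_threshold_mmHg = 20,
                            n_boot = 2000L,
                            seed = 1L) {
  structure(list(p1_window = p1_window, p2_window = p2_window,
                 resample_n = as.integer(resample_n),
                 min_support = as.integer(min_support),
                 k_amp = k_amp, k_dur = k_dur, cor_min = cor_min,
                 refractory_s = refractory_s,
                 icp_threshold_mmHg = icp_threshold_mmHg,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "icpw_params")
}

# Compression epoch of a recording, from its metadata (ground truth), never
# inferred from the signal.
compression_window <- function(recording) {
  md <- recording$metadata
  lo <- if (!is.null(md$compression_start_s)) md$compression_start_s else 420
  du <- if (!is.null(md$compression_duration_s)) md$compression_duration_s else 60
  c(lo, lo + du)
}

#' Analyse one paired recording end to end
#'
#' Runs the full per-session pipeline: beat detection on the ABP channel,
#' beat segmentation of the ICP and displacement channels against those
#' onsets, artifact flagging, per-minute ensemble averaging and landmark
#' extraction. Also computes the invasive per-minute mean ICP used for
#' intracranial-hypertension labelling, and a baseline-versus-compression
#' summary (epoch boundaries come from the recording's metadata, not from
#' change-point detection). Deterministic: the same recording always yields
#' the same report.
#'
#' @param recording a `paired_recording` with `icp_mmHg`, `b4c_um`,
#'   `abp_mmHg` channels.
#' @param params an [analysis_params()] object.
#' @return Object of class `icpw_session` with elements `per_minute`
#'   (morphology rows for both channels), `minute_icp` (invasive minute means
#'   and hypertension labels), `summary` (per-channel baseline/compression
#'   means and deltas), `flags`, `n_beats`, `params`.
#' @export
analyze_session <- function(recording, params = analysis_params()) {
  if (!inherits(recording, "paired_recording")) {
    stop("`recording` must be a paired_recording", call. = FALSE)
  }
  fs <- recording$fs
  onsets <- detect_beats(recording$abp_mmHg, fs,
                         refractory_s = params$refractory_s)
  channels <- c(icp = "icp_mmHg", b4c = "b4c_um")
  per_minute <- do.call(rbind, lapply(names(channels), function(id) {
    segs <- segment_pulses(recording[[channels[[id]]]], onsets, fs,
                           channel_id = id)
    segs <- exclude_artifacts(segs, k_amp = params$k_amp,
                              k_dur = params$k_dur,
                              cor_min = params$cor_min,
                              resample_n = params$resample_n)
    mins <- minute_average(segs, resample_n = params$resample_n,
                           min_support = params$min_support)
    morph <- morphology_series(mins, p1_window = params$p1_window,
                               p2_window = params$p2_window)
    morph$channel <- id
    morph
  }))
  per_minute <- per_minute[, c("channel", setdiff(names(per_minute),
                                                 "channel"))]

  t <- recording$time_s
  mins_present <- sort(unique(per_minute$minute_index))
  minute_icp <- data.frame(
    minute_index = mins_present,
    mean_icp_mmHg = vapply(mins_present, function(mi) {
      mean(recording$icp_mmHg[t >= 60 * mi & t < 60 * (mi + 1)])
    }, numeric(1)))
  minute_icp$ich <- minute_icp$mean_icp_mmHg > params$icp_threshold_mmHg

  win <- compression_window(recording)
  minute_epoch <- function(mi) {
    if (60 * mi < win[2] && 60 * (mi + 1) > win[1]) "compression"
    else if (60 * (mi + 1) <= win[1]) "baseline"
    else "recovery"
  }
  per_minute$epoch <- vapply(per_minute$minute_index, minute_epoch,
                             character(1))
  minute_icp$epoch <- vapply(minute_icp$minute_index, minute_epoch,
                             character(1))

  summ <- do.call(rbind, lapply(names(channels), function(id) {
    m <- per_minute[per_minute$channel == id & per_minute$determined, ]
    base <- m[m$epoch == "baseline", ]
    comp <- m[m$epoch == "compression", ]
    data.frame(channel = id,
               p2p1_baseline = mean(base$p2p1_ratio),
               p2p1_compression = mean(comp$p2p1_ratio),
               p2p1_delta = mean(comp$p2p1_ratio) - mean(base$p2p1_ratio),
               ttp_baseline = mean(base$ttp),
               ttp_compression = mean(comp$ttp),
               ttp_delta = mean(comp$ttp) - mean(base$ttp))
  }))
  icp_base <- mean(recording$icp_mmHg[t < win[1]])
  icp_comp <- mean(recording$icp_mmHg[t >= win[1] & t < win[2]])

  structure(list(per_minute = per_minute,
                 minute_icp = minute_icp,
                 summary = summ,
                 mean_icp_baseline = icp_base,
                 mean_icp_compression = icp_comp,
                 flags = list(
                   low_support_minutes =
                     unique(per_minute$minute_index[per_minute$low_support]),
                   undetermined_minutes =
                     unique(per_minute$minute_index[!per_minute$determined])),
                 n_beats = length(onsets),
                 group = recording$metadata$group,
                 params = params),
            class = "icpw_session")
}

#' @export
print.icpw_session <- function(x, ...) {
  cat("ICP waveform session report\n")
  cat(sprintf("  beats detected: %d; minutes analysed: %d\n", x$n_beats,
              length(unique(x$per_minute$minute_index))))
  cat(sprintf("  mean ICP: %.1f mmHg baseline, %.1f mmHg during compression\n",
              x$mean_icp_baseline, x$mean_icp_compression))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf(
      "  %s: P2/P1 %.3f -> %.3f (delta %+.3f); TTP %.3f -> %.3f\n",
      s$channel, s$p2p1_baseline, s$p2p1_compression, s$p2p1_delta,
      s$ttp_baseline, s$ttp_compression))
  }
  if (length(x$flags$low_support_minutes)) {
    cat("  low-support minutes:",
        paste(x$flags$low_support_minutes, collapse = ", "), "\n")
  }
  if (length(x$flags$undetermined_minutes)) {
    cat("  undetermined minutes:",
        paste(x$flags$undetermined_minutes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.icpw_session <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Monitoring-style plot of a session report
#'
#' Four stacked panels over minutes: P2/P1 ratio, time-to-peak, pulse
#' amplitude and useful-pulse count, for both channels, with the compression
#' epoch shaded.
#'
#' @param x an `icpw_session`.
#' @param ... unused.
#' @export
plot.icpw_session <- function(x, ...) {
  pm <- x$per_minute
  comp_min <- sort(unique(pm$minute_index[pm$epoch == "compression"]))
  panels <- list(
    list(var = "p2p1_ratio", lab = "P2/P1 ratio"),
    list(var = "ttp", lab = "TTP (cycle fraction)"),
    list(var = "pulse_amplitude", lab = "Pulse amplitude"),
    list(var = "n_useful", lab = "Useful pulses"))
  old <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  cols <- c(icp = "firebrick", b4c = "steelblue")
  for (p in panels) {
    rng <- range(pm[[p$var]], na.rm = TRUE)
    graphics::plot(NA, xlim = range(pm$minute_index), ylim = rng,
                   xlab = "minute", ylab = p$lab)
    if (length(comp_min)) {
      graphics::rect(min(comp_min) - 0.5, rng[1] - diff(rng),
                     max(comp_min) + 0.5, rng[2] + diff(rng),
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
    }
    for (id in unique(pm$channel)) {
      d <- pm[pm$channel == id, ]
      graphics::lines(d$minute_index, d[[p$var]], col = cols[[id]], type = "b",
                      pch = 16)
    }
  }
  invisible(x)
}

#' Validate a cohort of paired sessions
#'
#' Analyses every session, pairs the invasive and noninvasive minute-level
#' morphology metrics, and computes the agreement layer per cranial-status
#' group and pooled: Bland-Altman limits of agreement, Pearson correlation
#' with bootstrap CI, an OLS fit, and ROC of the noninvasive P2/P1 ratio
#' against intracranial hypertension (invasive minute mean above the
#' configured cut-off). Also builds the group-wise baseline/compression
#' delta table (mean delta and percent change per channel).
#'
#' @param cohort list of sessions as returned by [generate_cohort()] (each
#'   holding at least `recording`), or a list of `paired_recording`s.
#' @param params an [analysis_params()] object.
#' @return Object of class `icpw_cohort_validation` with `minutes` (the
#'   pooled paired minute table), `pooled` and `per_group` result lists, and
#'   `delta_table`.
#' @export
validate_cohort <- function(cohort, params = analysis_params()) {
  if (length(cohort) < 2) stop("need >= 2 sessions", call. = FALSE)
  recs <- lapply(cohort, function(s) {
    if (inherits(s, "paired_recording")) s else s$recording
  })
  reports <- lapply(recs, analyze_session, params = params)

  minutes <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rep <- reports[[i]]
    pm <- rep$per_minute
    wide <- merge(
      pm[pm$channel == "icp",
         c("minute_index", "epoch", "p2p1_ratio", "ttp", "determined")],
      pm[pm$channel == "b4c",
         c("minute_index", "p2p1_ratio", "ttp", "determined")],
      by = "minute_index", suffixes = c("_inv", "_non"))
    wide <- merge(wide, rep$minute_icp[, c("minute_index", "mean_icp_mmHg",
                                           "ich")],
                  by = "minute_index")
    wide$session <- i
    wide$group <- if (!is.null(rep$group)) rep$group else "unknown"
    wide
  }))

  seeds <- spawn_seeds(params$seed, 4L)
  metric_block <- function(rows) {
    ok <- rows$determined_inv & rows$determined_non
    r <- rows[ok, ]
    out <- list(n_minutes = nrow(r))
    out$bland_altman_p2p1 <- try_or_null(
      bland_altman(r$p2p1_ratio_inv, r$p2p1_ratio_non))
    out$bland_altman_ttp <- try_or_null(
      bland_altman(r$ttp_inv, r$ttp_non))
    out$correlation_p2p1 <- try_or_null(
      pearson_bootstrap(r$p2p1_ratio_inv, r$p2p1_ratio_non,
                        n_boot = params$n_boot, seed = seeds[1]))
    out$correlation_ttp <- try_or_null(
      pearson_bootstrap(r$ttp_inv, r$ttp_non,
                        n_boot = params$n_boot, seed = seeds[2]))
    out$linear_fit_p2p1 <- try_or_null(
      linear_fit(r$p2p1_ratio_inv, r$p2p1_ratio_non))
    sc <- rows[rows$determined_non, ]
    out$roc <- tryCatch(roc_curve(sc$p2p1_ratio_non, sc$ich),
                        error = function(e) {
                          warning("ROC skipped: ", conditionMessage(e),
                                  call. = FALSE)
                          NULL
                        })
    out
  }
  pooled <- metric_block(minutes)
  groups <- unique(minutes$group)
  per_group <- lapply(groups, function(g) {
    metric_block(minutes[minutes$group == g, ])
  })
  names(per_group) <- groups

  # Table-2-style deltas: session-level baseline/compression means first,
  # then group means of those
  delta_table <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("inv", "non"), function(side) {
      col <- paste0("p2p1_ratio_", side)
      m <- minutes[minutes$group == g, ]
      per_sess <- do.call(rbind, lapply(unique(m$session), function(s) {
        ms <- m[m$session == s, ]
        data.frame(
          base = mean(ms[[col]][ms$epoch == "baseline"], na.rm = TRUE),
          comp = mean(ms[[col]][ms$epoch == "compression"], na.rm = TRUE))
      }))
      base_mean <- mean(per_sess$base, na.rm = TRUE)
      delta <- mean(per_sess$comp - per_sess$base, na.rm = TRUE)
      data.frame(group = g,
                 channel = if (side == "inv") "icp" else "b4c",
                 n_sessions = nrow(per_sess),
                 p2p1_baseline = base_mean,
                 p2p1_compression = mean(per_sess$comp, na.rm = TRUE),
                 delta = delta,
                 pct = 100 * delta / base_mean)
    }))
  }))
  icp_epochs <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(vapply(reports, function(r)
      identical(r$group, g), logical(1)))
    data.frame(group = g,
               icp_baseline = mean(vapply(reports[idx], function(r)
                 r$mean_icp_baseline, numeric(1))),
               icp_compression = mean(vapply(reports[idx], function(r)
                 r$mean_icp_compression, numeric(1))))
  }))

  structure(list(minutes = minutes, pooled = pooled, per_group = per_group,
                 delta_table = delta_table, icp_epochs = icp_epochs,
                 n_sessions = length(recs), params = params),
            class = "icpw_cohort_validation")
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' @export
print.icpw_cohort_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d sessions, %d paired minutes\n",
              x$n_sessions, nrow(x$minutes)))
  cat("Differences oriented invasive - noninvasive.\n\n")
  if (!is.null(x$pooled$bland_altman_p2p1)) {
    cat("Pooled P2/P1 ")
    print(x$pooled$bland_altman_p2p1)
  }
  if (!is.null(x$pooled$correlation_p2p1)) {
    cat("Pooled P2/P1 ")
    print(x$pooled$correlation_p2p1)
  }
  if (!is.null(x$pooled$roc)) {
    cat("Pooled noninvasive P2/P1 vs intracranial hypertension ")
    print(x$pooled$roc)
  }
  cat("\nGroup-wise compression response (P2/P1):\n")
  print(x$delta_table, row.names = FALSE, digits = 3)
  invisible(x)
}
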