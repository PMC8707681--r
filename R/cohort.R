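#' Group-level generative parameters for synthetic cohorts
#'
#' One row per cranial-status group (intact skull, craniotomy or large
#' fracture, craniectomy) giving the distribution from which per-session
#' configs are drawn. Baseline mean ICP and the compression responses use the
#' study-reported group means: baseline ICP 15.2/15.6/20.8 mmHg (SD
#' 7.1/7.4/9.4), compression Delta-ICP +4.1/+4.1/+3.13 mmHg, compression
#' Delta-P2/P1 +0.08/+0.07/-0.04 (negative for craniectomy: with the bone
#' flap removed, volume loading no longer stiffens the compartment).
#'
#' Baseline P2/P1 is drawn with a compliance coupling to the session's
#' baseline ICP (`p2p1_icp_coupling`, ratio units per mmHg): higher-pressure
#' patients sit lower on the pressure-volume reserve and show larger P2
#' relative to P1. This cross-session coupling is what gives the P2/P1 ratio
#' its power to discriminate intracranial hypertension in cohort ROC runs.
#'
#' @return data.frame with one row per group.
#' @seealso [null_effect_parameters()] for the no-association null.
#' @export
group_parameters <- function() {
  data.frame(
    group = c("intact", "craniotomy_fracture", "craniectomy"),
    baseline_icp_mean = c(15.2, 15.6, 20.8),
    baseline_icp_sd = c(7.1, 7.4, 9.4),
    delta_icp_mean = c(4.1, 4.1, 3.13),
    delta_icp_sd = c(1.5, 1.5, 1.5),
    baseline_p2p1_mean = c(1.00, 1.05, 1.10),
    baseline_p2p1_sd = c(0.15, 0.15, 0.15),
    delta_p2p1_mean = c(0.08, 0.07, -0.04),
    delta_p2p1_sd = c(0.05, 0.05, 0.05),
    p2p1_icp_coupling = c(0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
}

#' Null-effect cohort parameters
#'
#' Group table for the no-association null: pulse morphology carries no
#' information about pressure. All compression P2/P1 deltas, the
#' ICP-to-P2/P1 coupling, and the group-level P2/P1 offsets are zeroed
#' (baseline P2/P1 ~ N(1.05, 0.15) in every group); ICP parameters are
#' untouched, so intracranial-hypertension labels still vary. Cohort ROC on
#' such data has no signal to find and its AUC concentrates around 0.5.
#'
#' @return data.frame like [group_parameters()].
#' @export
null_effect_parameters <- function() {
  p <- group_parameters()
  p$delta_p2p1_mean <- 0
  p$delta_p2p1_sd <- 0
  p$baseline_p2p1_mean <- 1.05
  p$p2p1_icp_coupling <- 0
  p
}

#' Generate a cohort of paired sessions
#'
#' Draws per-session configs from the group parameter table and renders each
#' session. Group counts follow `group_mix` by largest remainder, so e.g.
#' `n_sessions = 41` with mix 12/41, 20/41, 9/41 yields exactly 12/20/9
#' sessions. Deterministic given `seed` (per-session seeds are spawned from
#' it).
#'
#' @param n_sessions number of sessions (>= 1).
#' @param group_mix named numeric vector of group proportions summing to 1;
#'   names from `group_parameters()$group`.
#' @param seed integer cohort seed.
#' @param parameters group parameter table (default [group_parameters()]).
#' @param ... further arguments passed to every [session_config()] (e.g.
#'   `duration_s`, `compression_start_s`, `artifact_rate`).
#' @return List of sessions, each a list `(recording, truth, config)`.
#' @export
generate_cohort <- function(n_sessions,
                            group_mix = c(intact = 12 / 41,
                                          craniotomy_fracture = 20 / 41,
                                          craniectomy = 9 / 41),
                            seed = 1L,
                            parameters = group_parameters(),
                            ...) {
  if (!is.numeric(n_sessions) || n_sessions < 1) {
    stop("`n_sessions` must be >= 1", call. = FALSE)
  }
  n_sessions <- as.integer(n_sessions)
  if (is.null(names(group_mix)) ||
      !all(names(group_mix) %in% parameters$group)) {
    stop("`group_mix` must be named with known groups", call. = FALSE)
  }
  if (abs(sum(group_mix) - 1) > 1e-8) {
    stop("`group_mix` proportions must sum to 1", call. = FALSE)
  }
  # largest-remainder apportionment of sessions to groups
  raw <- group_mix * n_sessions
  counts <- floor(raw)
  rem <- n_sessions - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  groups <- rep(names(group_mix), counts)

  seeds <- spawn_seeds(seed, n_sessions + 1L)
  draw <- with_seed(seeds[n_sessions + 1L], {
    lapply(seq_len(n_sessions), function(i) {
      p <- parameters[parameters$group == groups[i], ]
      icp0 <- min(60, max(3, stats::rnorm(1, p$baseline_icp_mean,
                                          p$baseline_icp_sd)))
      dicp <- max(0, stats::rnorm(1, p$delta_icp_mean, p$delta_icp_sd))
      p2p1 <- p$baseline_p2p1_mean +
        p$p2p1_icp_coupling * (icp0 - p$baseline_icp_mean) +
        stats::rnorm(1, 0, p$baseline_p2p1_sd)
      p2p1 <- min(2.2, max(0.4, p2p1))
      dp2p1 <- stats::rnorm(1, p$delta_p2p1_mean, p$delta_p2p1_sd)
      list(group = groups[i], baseline_icp_mmHg = icp0,
           compression_delta_icp_mmHg = dicp,
           baseline_p2p1 = p2p1, compression_delta_p2p1 = dp2p1)
    })
  })
  lapply(seq_len(n_sessions), function(i) {
    d <- draw[[i]]
    cfg <- session_config(group = d$group,
                          baseline_icp_mmHg = d$baseline_icp_mmHg,
                          compression_delta_icp_mmHg =
                            d$compression_delta_icp_mmHg,
                          baseline_p2p1 = d$baseline_p2p1,
                          compression_delta_p2p1 = d$compression_delta_p2p1,
                          seed = seeds[i], ...)
    ses <- generate_session(cfg)
    list(recording = ses$recording, truth = ses$truth, config = cfg)
  })
}
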