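# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points route
# through this so that simulation is a pure function of its config.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` child seeds (< 2^31) from a parent seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  if (x > max) {
    stop(sprintf("`%s` must be <= %g", name, max), call. = FALSE)
  }
  invisible(x)
}

# Indices of strict-then-weak interior local maxima of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# Linear resampling of a beat onto `n_out` samples at phases k/n_out,
# k = 0..n_out-1 (phase 0 = onset, phase 1 = next onset).
resample_beat <- function(samples, n_out) {
  n_in <- length(samples)
  if (n_in < 2L) stop("beat too short to resample", call. = FALSE)
  phase_in <- (seq_len(n_in) - 1) / n_in
  phase_out <- (seq_len(n_out) - 1) / n_out
  stats::approx(phase_in, samples, xout = phase_out, rule = 2)$y
}
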