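# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "axonsynkit_invalid_argument")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_bad_arg(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_bad_arg(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Apply a seed locally (RNG state restored on exit); seed = NULL leaves the
# current RNG stream untouched so callers can manage randomness themselves.
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# Robust noise scale: median absolute deviation scaled to the SD of a
# Gaussian (MAD / 0.6745), insensitive to sparse large excursions (spikes,
# bright tracks).
robust_sd <- function(x) {
  stats::median(abs(x - stats::median(x))) / 0.6745
}
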