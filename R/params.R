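#' Detector and resampling parameters
#'
#' Bundles the tuning parameters of the stability analysis: the number of
#' resampling replicates used to average the prevalence curve, and the three
#' thresholds of the windowed flatness detector.  All prevalence quantities
#' are on the percent scale (0--100), so the two thresholds are in
#' percentage points.
#'
#' @param n_replicates Number of independent subsampling replicates averaged
#'   at each sample size `k` (default 50).
#' @param successive_points Number of successive curve means that must be
#'   flat for stability to be declared (the window length `x`, default 10;
#'   must be at least 2).
#' @param mean_diff_threshold Threshold `y`, in percentage points, on each
#'   successive difference of window means (default 2).  The comparison is
#'   performed against `y / sqrt(k)` to correct for the shrinking scale of
#'   the differences as the sample size grows.
#' @param delta_threshold Threshold `z`, in percentage points, on the range
#'   (max minus min) of the window means (default 1; uncorrected).
#' @param seed Optional integer seed.  When supplied, every analysis using
#'   these parameters is reproducible and derives independent sub-streams
#'   per group/species pair.
#'
#' @return An object of class `"stability_params"`.
#' @examples
#' stability_params()
#' stability_params(n_replicates = 100, seed = 1)
#' @export
stability_params <- function(n_replicates = 50, successive_points = 10,
                             mean_diff_threshold = 2, delta_threshold = 1,
                             seed = NULL) {
  stop_if_not_count(n_replicates, "n_replicates")
  stop_if_not_count(successive_points, "successive_points")
  if (successive_points < 2)
    stop("`successive_points` must be at least 2", call. = FALSE)
  for (nm in c("mean_diff_threshold", "delta_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(
    list(n_replicates = as.integer(n_replicates),
         successive_points = as.integer(successive_points),
         mean_diff_threshold = as.numeric(mean_diff_threshold),
         delta_threshold = as.numeric(delta_threshold),
         seed = seed),
    class = "stability_params"
  )
}

stop_if_not_count <- function(v, nm) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
      v != floor(v))
    stop(sprintf("`%s` must be a single positive integer", nm), call. = FALSE)
}

as_stability_params <- function(x) {
  if (inherits(x, "stability_params")) return(x)
  if (is.list(x)) return(do.call(stability_params, x))
  stop("`params` must be created by stability_params()", call. = FALSE)
}

#' @export
print.stability_params <- function(x, ...) {
  cat("Stability-analysis parameters\n")
  cat(sprintf("  replicates (n):          %d\n", x$n_replicates))
  cat(sprintf("  successive points (x):   %d\n", x$successive_points))
  cat(sprintf("  mean-diff threshold (y): %g pp (compared as y/sqrt(k))\n",
              x$mean_diff_threshold))
  cat(sprintf("  delta threshold (z):     %g pp\n", x$delta_threshold))
  cat(sprintf("  seed:                    %s\n",
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Display rounding: 1 decimal, half away from zero (never applied internally).
format_prevalence <- function(v, digits = 1) {
  out <- rep(NA_character_, length(v))
  ok <- !is.na(v)
  f <- 10^digits
  r <- sign(v[ok]) * floor(abs(v[ok]) * f + 0.5) / f
  out[ok] <- formatC(r, format = "f", digits = digits)
  out
}
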