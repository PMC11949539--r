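#' Mean prevalence accumulation curve by subsampling without replacement
#'
#' For every sample size `k` from 1 to `k_MAX` (the number of scored units),
#' draws a uniform random subset of `k` units without replacement, records
#' the percentage of presences, and averages over `n_replicates` replicates.
#' The value at `k = k_MAX` equals the observed full-sample prevalence
#' exactly, since the only size-`k_MAX` subsample is the sample itself.
#'
#' Two resampling modes are available.  In the default `"nested"` mode each
#' replicate is a random permutation of the units and the size-`k` subsample
#' is its first `k` elements, so within a replicate the subsamples grow by
#' accumulation, exactly as sampling effort accumulates in the field.  Every
#' m(k) still averages `n_replicates` exact uniform SRSWOR draws, but
#' successive curve values are positively correlated and their differences
#' shrink like 1/k; the default detector thresholds (see
#' [detect_stability()]) are calibrated for this geometry.  In
#' `"independent"` mode a fresh subsample is drawn at every `k`; marginal
#' distributions are identical but the curve is much rougher, successive
#' differences shrink only like 1/sqrt(k), and the default thresholds are
#' not appropriate.
#'
#' @param column Binary vector (0/1, `NA` allowed) of presences for one
#'   group/species pair; missing entries are dropped before sampling.
#' @param params A [stability_params()] object; its `n_replicates` and
#'   `seed` are used here.
#' @param mode `"nested"` (default) or `"independent"`; see Details.
#' @param group,species Optional labels carried into the result.
#' @param seed Seed for this curve; defaults to `params$seed`.
#'
#' @return An object of class `"prevalence_curve"`: list with `group`,
#'   `species`, `k_max`, `means` (percent, length `k_max`),
#'   `observed_prevalence` (percent), `n_replicates` and `mode`.
#' @examples
#' curve <- resample_prevalence_curve(c(1, 0, 0, 1, 0),
#'                                    stability_params(seed = 1))
#' curve$means[curve$k_max]  # exactly the observed 40%
#' @export
resample_prevalence_curve <- function(column, params = stability_params(),
                                      mode = c("nested", "independent"),
                                      group = NA_character_,
                                      species = NA_character_,
                                      seed = params$seed) {
  params <- as_stability_params(params)
  mode <- match.arg(mode)
  if (!is.numeric(column) && !is.logical(column))
    stop("`column` must be a numeric 0/1 vector", call. = FALSE)
  column <- as.numeric(column)
  bad <- which(!is.na(column) & column != 0 & column != 1)
  if (length(bad) > 0L)
    stop(sprintf("non-binary value '%s' at position %d",
                 column[bad[1L]], bad[1L]), call. = FALSE)
  column <- column[!is.na(column)]
  if (length(column) == 0L)
    stop("no data for this group/species: all entries missing",
         call. = FALSE)

  means <- local_seed(seed,
                      curve_means(column, params$n_replicates, mode))
  obs <- 100 * sum(column) / length(column)
  means[length(column)] <- obs  # census subsample: exact by construction

  structure(
    list(group = group, species = species, k_max = length(column),
         means = means, observed_prevalence = obs,
         n_replicates = params$n_replicates, mode = mode),
    class = "prevalence_curve"
  )
}

curve_means <- function(column, n_replicates, mode) {
  N <- length(column)
  if (mode == "nested") {
    tot <- numeric(N)
    inv <- seq_len(N)
    for (r in seq_len(n_replicates))
      tot <- tot + cumsum(sample(column)) / inv
    100 * tot / n_replicates
  } else {
    vapply(seq_len(N), function(k) {
      acc <- 0
      for (r in seq_len(n_replicates))
        acc <- acc + sum(sample(column, k)) / k
      100 * acc / n_replicates
    }, numeric(1))
  }
}

#' @export
print.prevalence_curve <- function(x, ...) {
  lab <- if (is.na(x$group)) "" else sprintf(" [%s / %s]", x$group, x$species)
  cat(sprintf("Prevalence curve%s: k_max = %d, %d replicates, %s mode\n",
              lab, x$k_max, x$n_replicates, x$mode))
  cat(sprintf("  observed prevalence: %s%%\n",
              format_prevalence(x$observed_prevalence)))
  show <- x$means[unique(pmin(x$k_max, c(1, 2, 5, 10, 20, 50, x$k_max)))]
  cat("  means (subset):", paste(format_prevalence(show), collapse = " "),
      "\n")
  invisible(x)
}

#' Successive differences of a prevalence curve
#'
#' Absolute differences `d(k) = |m(k) - m(k-1)|`, in percentage points, for
#' `k = 2 .. k_max`; these are the quantities the stability detector
#' compares against the corrected mean-difference threshold `y / sqrt(k)`.
#'
#' @param curve A `"prevalence_curve"` or a bare numeric vector of means.
#' @return Numeric vector of length `k_max - 1`, named by `k`; empty for a
#'   single-point curve.
#' @examples
#' successive_differences(c(60, 55, 53))  # 5, 2
#' @export
successive_differences <- function(curve) {
  m <- if (inherits(curve, "prevalence_curve")) curve$means else
    as.numeric(curve)
  if (length(m) < 2L) return(setNames(numeric(0), character(0)))
  d <- abs(diff(m))
  names(d) <- seq(2L, length(m))
  d
}
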