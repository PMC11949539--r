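#' Synthetic population with known prevalence
#'
#' Builds a binary population of `population_size` units containing exactly
#' `round(population_size * true_prevalence)` presences.  Order is
#' immaterial because all downstream subsampling is uniform.
#'
#' @param population_size Positive integer.
#' @param true_prevalence Proportion in `[0, 1]`.
#' @return Binary vector of length `population_size`.
#' @examples
#' sum(make_population(1000, 0.5))  # exactly 500
#' @export
make_population <- function(population_size, true_prevalence) {
  stop_if_not_count(population_size, "population_size")
  if (!is.numeric(true_prevalence) || length(true_prevalence) != 1L ||
      is.na(true_prevalence) || true_prevalence < 0 || true_prevalence > 1)
    stop("`true_prevalence` must be a proportion in [0, 1]", call. = FALSE)
  ones <- round(population_size * true_prevalence)
  c(rep(1, ones), rep(0, population_size - ones))
}

#' Run the estimator once on a synthetic population
#'
#' Builds the population, resamples its prevalence curve, detects the
#' stability point and records the absolute estimation error in percentage
#' points.  The whole population is handed to the estimator (`k_max =
#' population_size`), mirroring a census-style validation run.
#'
#' @param population_size,true_prevalence Population definition, see
#'   [make_population()].
#' @param params A [stability_params()]; its seed (if any) drives the run.
#' @param mode Resampling mode, see [resample_prevalence_curve()].
#' @param run_index Bookkeeping index stored in the record.
#' @return One-row data frame with the population definition, effective
#'   parameters, `stability_point`, `estimated_prevalence` and
#'   `abs_error_pp` (defined only for determined stability points).
#' @examples
#' run_single(100, 0.3, stability_params(seed = 1))
#' @export
run_single <- function(population_size, true_prevalence,
                       params = stability_params(),
                       mode = c("nested", "independent"), run_index = 1L) {
  params <- as_stability_params(params)
  mode <- match.arg(mode)
  pop <- make_population(population_size, true_prevalence)
  cv <- resample_prevalence_curve(pop, params, mode = mode)
  res <- detect_stability(cv, params)
  data.frame(
    population_size = population_size, true_prevalence = true_prevalence,
    n_replicates = params$n_replicates,
    successive_points = params$successive_points,
    mean_diff_threshold = params$mean_diff_threshold,
    delta_threshold = params$delta_threshold,
    run_index = as.integer(run_index),
    stability_point = res$stability_point,
    estimated_prevalence = res$estimated_prevalence,
    abs_error_pp = if (is.na(res$stability_point)) NA_real_ else
      abs(res$estimated_prevalence - 100 * true_prevalence),
    stringsAsFactors = FALSE)
}

#' Factorial validation grid over population size, prevalence and replicates
#'
#' The default grid crosses population sizes 100, 1000 and 10000 with true
#' prevalences 10\%--90\% in steps of 10\% and replicate counts 10--100 in
#' steps of 10 plus 200 and 500, all with the default detector thresholds:
#' 324 cells.  Each cell runs the full estimator once on its own
#' reproducible sub-stream.
#'
#' @param seed Optional integer seed; each cell derives an independent
#'   child seed from it, so cells are individually replayable.
#' @param sizes,prevalences,replicates Grid axes.
#' @param successive_points,mean_diff_threshold,delta_threshold Detector
#'   parameters applied to every cell.
#' @param mode Resampling mode; the nested (permutation-prefix) default
#'   keeps even the 10000-unit cells fast.
#' @return Data frame with one row per cell (class `"grid_result"` is
#'   attached, and the resampling mode is stored in attribute `"mode"`).
#' @examples
#' run_default_grid(seed = 1, sizes = 100, prevalences = 0.5,
#'                  replicates = 10)
#' @export
run_default_grid <- function(seed = NULL,
                             sizes = c(100, 1000, 10000),
                             prevalences = seq(0.1, 0.9, by = 0.1),
                             replicates = c(seq(10, 100, by = 10), 200, 500),
                             successive_points = 10,
                             mean_diff_threshold = 2,
                             delta_threshold = 1,
                             mode = c("nested", "independent")) {
  mode <- match.arg(mode)
  cells <- expand.grid(population_size = sizes,
                       true_prevalence = prevalences,
                       n_rep = replicates, KEEP.OUT.ATTRS = FALSE)
  recs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- stability_params(
      n_replicates = cells$n_rep[i],
      successive_points = successive_points,
      mean_diff_threshold = mean_diff_threshold,
      delta_threshold = delta_threshold,
      seed = if (is.null(seed)) NULL else child_seed(seed, i))
    recs[[i]] <- run_single(cells$population_size[i],
                            cells$true_prevalence[i], p, mode = mode,
                            run_index = i)
  }
  out <- do.call(rbind, recs)
  attr(out, "mode") <- mode
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Sweep the detector parameters on a fixed focal population
#'
#' Crosses window lengths 2, 10 and 50 with mean-difference thresholds 1,
#' 2, 5 and 10 and range thresholds 0.5, 1 and 2 (36 combinations) on a
#' population of 1000 units at 50\% prevalence with 50 replicates,
#' quantifying how stringency drives the required sample size.
#'
#' @param seed Optional integer seed (per-cell child streams).
#' @param population_size,true_prevalence,n_replicates Focal population and
#'   replicate count shared by all cells.
#' @param successive_points,mean_diff_threshold,delta_threshold Vectors of
#'   parameter values to cross.
#' @param mode Resampling mode.
#' @return Data frame with one row per parameter combination, same schema
#'   as [run_default_grid()].
#' @export
run_parameter_sweep <- function(seed = NULL,
                                population_size = 1000,
                                true_prevalence = 0.5,
                                n_replicates = 50,
                                successive_points = c(2, 10, 50),
                                mean_diff_threshold = c(1, 2, 5, 10),
                                delta_threshold = c(0.5, 1, 2),
                                mode = c("nested", "independent")) {
  mode <- match.arg(mode)
  cells <- expand.grid(x = successive_points, y = mean_diff_threshold,
                       z = delta_threshold, KEEP.OUT.ATTRS = FALSE)
  recs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- stability_params(
      n_replicates = n_replicates, successive_points = cells$x[i],
      mean_diff_threshold = cells$y[i], delta_threshold = cells$z[i],
      seed = if (is.null(seed)) NULL else child_seed(seed, i))
    recs[[i]] <- run_single(population_size, true_prevalence, p,
                            mode = mode, run_index = i)
  }
  out <- do.call(rbind, recs)
  attr(out, "mode") <- mode
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Repeat the estimator to gauge its run-to-run stochasticity
#'
#' Runs the full estimator `runs` times on the same synthetic population
#' with independent random streams, summarising the spread of the detected
#' stability point.  Because the analysis is stochastic, a single run can
#' land far from the long-run mean; at least five runs are recommended
#' before settling on a required sample size.
#'
#' @param population_size,true_prevalence Population definition.
#' @param params A [stability_params()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param runs Number of independent runs (at least 1).
#' @param seed Optional integer seed; run `i` uses an independent child
#'   stream.
#' @param mode Resampling mode.
#' @return Object of class `"repeat_summary"`: list with
#'   `mean_stability_point`, `sd_stability_point` (0 by convention, and
#'   flagged, when `runs = 1`), `runs`, `na_count`, and the per-run vectors
#'   `stability_points` and `estimated_prevalences`.
#' @examples
#' repeat_runs(200, 0.2, runs = 3, seed = 1)
#' @export
repeat_runs <- function(population_size, true_prevalence,
                        params = stability_params(), runs = 10,
                        seed = NULL, mode = c("nested", "independent")) {
  params <- as_stability_params(params)
  mode <- match.arg(mode)
  stop_if_not_count(runs, "runs")
  pts <- integer(runs)
  est <- numeric(runs)
  for (i in seq_len(runs)) {
    p <- stability_params(params$n_replicates, params$successive_points,
                          params$mean_diff_threshold,
                          params$delta_threshold,
                          seed = if (is.null(seed)) NULL else
                            child_seed(seed, i))
    rec <- run_single(population_size, true_prevalence, p, mode = mode,
                      run_index = i)
    pts[i] <- rec$stability_point
    est[i] <- rec$estimated_prevalence
  }
  ok <- !is.na(pts)
  structure(
    list(mean_stability_point = if (any(ok)) mean(pts[ok]) else NA_real_,
         sd_stability_point = if (sum(ok) > 1L) sd(pts[ok]) else 0,
         degenerate_sd = sum(ok) <= 1L,
         runs = as.integer(runs), na_count = sum(!ok),
         stability_points = pts, estimated_prevalences = est,
         population_size = population_size,
         true_prevalence = true_prevalence),
    class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf(
    "Repeat-run summary (N = %d, true prevalence = %g%%, %d runs)\n",
    x$population_size, 100 * x$true_prevalence, x$runs))
  cat(sprintf("  stability point: mean %s ± sd %s%s\n",
              format_prevalence(x$mean_stability_point),
              format_prevalence(x$sd_stability_point),
              if (x$degenerate_sd) " (sd from <2 runs, reported as 0)" else ""))
  if (x$na_count > 0)
    cat(sprintf("  undetermined (na) runs: %d of %d\n", x$na_count, x$runs))
  invisible(x)
}

#' Closed-form sampling error of a subsample prevalence
#'
#' Standard error, in percentage points, of the proportion of presences in
#' a size-`k` simple random sample drawn without replacement from a
#' population of `N` units with true proportion `p`:
#' `100 * sqrt(p (1 - p) / k * (N - k) / (N - 1))`.  The
#' `(N - k) / (N - 1)` factor is the finite-population correction; at
#' `k = N` the subsample is a census and the error is exactly zero.
#'
#' @param p True proportion in `[0, 1]`.
#' @param k Subsample size, `1 <= k <= N`.
#' @param N Population size.
#' @return Standard error in percentage points (vectorised).
#' @examples
#' expected_se(0.5, 1, 1e6)   # ~50: a single Bernoulli draw
#' expected_se(0.4, 50, 50)   # 0: census
#' @export
expected_se <- function(p, k, N) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(k < 1)) stop("`k` must be at least 1", call. = FALSE)
  if (any(k > N)) stop("`k` cannot exceed the population size `N`",
                       call. = FALSE)
  fpc <- ifelse(N == 1, 0, (N - k) / (N - 1))
  100 * sqrt(p * (1 - p) / k * fpc)
}
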