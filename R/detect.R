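#' Detect the stability point of a prevalence curve
#'
#' Scans the curve for the first window of `x = successive_points`
#' consecutive means that is flat under two simultaneous criteria:
#' \enumerate{
#'   \item every successive difference within the window satisfies
#'     `|m(k) - m(k-1)| < y / sqrt(k)` (strict), where `y` is
#'     `mean_diff_threshold` and the square-root correction accounts for the
#'     shrinking scale of the differences as `k` grows;
#'   \item the range of the window means, `Delta = max - min`, satisfies
#'     `Delta < z` (strict, uncorrected), where `z` is `delta_threshold`.
#' }
#' The stability point is reported, by default, as the last sample size of
#' the first qualifying window (`point = "window_end"`): the number of
#' samples by which the curve has been observed to be stable for `x`
#' successive means, i.e. the minimum sufficient sampling effort.  Set
#' `point = "window_start"` to report the first mean of the window instead.
#' If the curve is shorter than the window, or no window qualifies, the
#' stability point is `NA`: the available effort does not yet support a
#' stable estimate.
#'
#' @param curve A `"prevalence_curve"` from [resample_prevalence_curve()],
#'   or a bare numeric vector of percent means.
#' @param params A [stability_params()] object.
#' @param point Reporting convention, `"window_end"` (default) or
#'   `"window_start"`; see Details.
#' @param correction_index Whether `sqrt(k)` in the mean-difference
#'   criterion uses the later (default) or earlier member of each difference
#'   pair.
#' @param window_unit `"means"` (default): the window holds `x` means and
#'   `x - 1` differences.  `"differences"`: the window holds `x` successive
#'   differences, hence `x + 1` means, and `Delta` spans those `x + 1`
#'   means.
#'
#' @return An object of class `"stability_result"`: list with `group`,
#'   `species`, `stability_point` (integer or `NA`), `estimated_prevalence`
#'   (curve value at the stability point, percent; `NA` when undetermined),
#'   `tail_prevalence` (`m(k_max)`), `k_max`, `window_start`,
#'   `window_delta`, `params`, `point` and `diagnostic` (`"ok"`,
#'   `"no_window"`, `"short_curve"` or `"no_data"`).
#' @examples
#' cv <- resample_prevalence_curve(rep(c(1, 0), 50),
#'                                 stability_params(seed = 4))
#' detect_stability(cv)
#' @export
detect_stability <- function(curve, params = stability_params(),
                             point = c("window_end", "window_start"),
                             correction_index = c("later", "earlier"),
                             window_unit = c("means", "differences")) {
  params <- as_stability_params(params)
  point <- match.arg(point)
  correction_index <- match.arg(correction_index)
  window_unit <- match.arg(window_unit)

  if (inherits(curve, "prevalence_curve")) {
    m <- curve$means
    group <- curve$group; species <- curve$species
  } else {
    m <- as.numeric(curve)
    group <- NA_character_; species <- NA_character_
  }
  if (length(m) == 0L) stop("empty curve", call. = FALSE)

  x <- params$successive_points
  y <- params$mean_diff_threshold
  z <- params$delta_threshold
  L <- if (window_unit == "means") x else x + 1L  # means per window
  N <- length(m)

  res <- list(group = group, species = species,
              stability_point = NA_integer_,
              estimated_prevalence = NA_real_,
              tail_prevalence = m[N], k_max = N,
              window_start = NA_integer_, window_delta = NA_real_,
              params = params, point = point, diagnostic = "no_window")
  if (N < L) {
    res$diagnostic <- "short_curve"
    return(structure(res, class = "stability_result"))
  }

  nW <- N - L + 1L
  d <- abs(diff(m))                       # d[j] = |m(j+1) - m(j)|
  kk <- if (correction_index == "later") seq(2L, N) else seq(1L, N - 1L)
  ok <- d < y / sqrt(kk)
  # run test: window s needs ok[s .. s+L-2] all TRUE
  cs <- cumsum(c(0, ok))
  run_ok <- (cs[seq(L, N)] - cs[seq_len(nW)]) == (L - 1L)
  shifted <- lapply(seq_len(L) - 1L, function(j) m[seq_len(nW) + j])
  wmax <- do.call(pmax, shifted)
  wmin <- do.call(pmin, shifted)
  hit <- which(run_ok & (wmax - wmin < z))

  if (length(hit) > 0L) {
    s <- hit[1L]
    res$window_start <- s
    res$window_delta <- wmax[s] - wmin[s]
    res$stability_point <- if (point == "window_end") s + L - 1L else s
    res$estimated_prevalence <- m[res$stability_point]
    res$diagnostic <- "ok"
  }
  structure(res, class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  lab <- if (is.na(x$group)) "" else sprintf(" [%s / %s]", x$group, x$species)
  cat(sprintf("Stability result%s (k_max = %d)\n", lab, x$k_max))
  if (is.na(x$stability_point)) {
    cat(sprintf("  stability point: na (%s) -- sampling effort insufficient\n",
                x$diagnostic))
  } else {
    cat(sprintf("  stability point: %d samples (%s of window starting at %d)\n",
                x$stability_point, x$point, x$window_start))
    cat(sprintf("  estimated prevalence: %s%%  (window delta %s pp)\n",
                format_prevalence(x$estimated_prevalence),
                format_prevalence(x$window_delta, 3)))
  }
  cat(sprintf("  full-sample prevalence: %s%%\n",
              format_prevalence(x$tail_prevalence)))
  invisible(x)
}
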