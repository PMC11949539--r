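#' Run the stability analysis for every group/species pair
#'
#' Builds a prevalence curve and detects its stability point for each
#' combination of group (in order of first appearance) and species column
#' (in table order).  Missing entries are dropped per pair, so each pair has
#' its own `k_max`.  When `params$seed` is set, every pair analyses its own
#' reproducible random sub-stream derived from the seed and the pair's
#' labels, so adding or removing a species column never perturbs the
#' other results.
#'
#' @param table An [occurrence_table()].
#' @param params A [stability_params()] object.
#' @param mode Resampling mode, see [resample_prevalence_curve()].
#' @param drop_empty Drop pairs with zero scored entries (default).  When
#'   `FALSE` such pairs are kept as `NA` results flagged `"no_data"`.
#' @param ... Further arguments passed to [detect_stability()] (reporting
#'   convention and correction switches).
#'
#' @return An object of class `"stability_scan"`: list with parallel lists
#'   `results` (one `"stability_result"` per pair) and `curves` (the
#'   matching `"prevalence_curve"`, or `NULL` for `"no_data"` pairs), plus
#'   `params` and `mode`.  Convert with `as.data.frame()` for the tidy
#'   results schema.
#' @examples
#' tab <- make_fixture_table(
#'   data.frame(group = "H", species = c("a", "b"),
#'              k_max = 40, ones = c(10, 30)), seed = 1)
#' scan <- estimate_all(tab, stability_params(seed = 1))
#' as.data.frame(scan)
#' @export
estimate_all <- function(table, params = stability_params(),
                         mode = c("nested", "independent"),
                         drop_empty = TRUE, ...) {
  if (!inherits(table, "occurrence_table"))
    stop("`table` must be an occurrence_table", call. = FALSE)
  params <- as_stability_params(params)
  mode <- match.arg(mode)

  groups <- unique(table$group)
  results <- list()
  curves <- list()
  for (g in groups) {
    rows <- table$group == g
    for (sp in table$species) {
      col <- table$values[rows, sp]
      if (all(is.na(col))) {
        if (drop_empty) next
        res <- structure(
          list(group = g, species = sp, stability_point = NA_integer_,
               estimated_prevalence = NA_real_, tail_prevalence = NA_real_,
               k_max = 0L, window_start = NA_integer_,
               window_delta = NA_real_, params = params,
               point = "window_end", diagnostic = "no_data"),
          class = "stability_result")
        results[[length(results) + 1L]] <- res
        curves[length(curves) + 1L] <- list(NULL)
        next
      }
      seed <- if (is.null(params$seed)) NULL else
        pair_seed(params$seed, g, sp)
      cv <- resample_prevalence_curve(col, params, mode = mode,
                                      group = g, species = sp, seed = seed)
      results[[length(results) + 1L]] <- detect_stability(cv, params, ...)
      curves[[length(curves) + 1L]] <- cv
    }
  }
  structure(list(results = results, curves = curves, params = params,
                 mode = mode),
            class = "stability_scan")
}

#' @export
as.data.frame.stability_scan <- function(x, ...) {
  p <- x$params
  rows <- lapply(x$results, function(r) {
    data.frame(group = r$group, species = r$species, k_max = r$k_max,
               stability_point = r$stability_point,
               estimated_prevalence = r$estimated_prevalence,
               tail_prevalence = r$tail_prevalence,
               n_replicates = p$n_replicates,
               successive_points = p$successive_points,
               mean_diff_threshold = p$mean_diff_threshold,
               delta_threshold = p$delta_threshold,
               seed = if (is.null(p$seed)) NA_integer_ else p$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.stability_scan <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Stability scan: %d group/species pair(s), %s resampling\n",
              nrow(df), x$mode))
  show <- data.frame(
    group = df$group, species = df$species, k_max = df$k_max,
    stability_point = ifelse(is.na(df$stability_point), "na",
                             as.character(df$stability_point)),
    estimated_prevalence = format_prevalence(df$estimated_prevalence),
    tail_prevalence = format_prevalence(df$tail_prevalence),
    stringsAsFactors = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
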