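#' Panel figure of prevalence curves with stability annotations
#'
#' One panel per group (titled with the group label), one curve per species
#' in its legend colour.  For a determined stability point a vertical
#' dotted line marks it and its integer value is printed at the top of the
#' panel in the species colour; an undetermined result prints `na` instead
#' (and no line).  When several species of a panel share a stability point
#' only one dotted line is drawn but every number is printed.  The
#' estimated prevalence is printed at the tail end of each curve, to one
#' decimal place.  A shared species legend sits at the bottom.
#'
#' @param scan A `"stability_scan"` from [estimate_all()] (curves must have
#'   been kept, which is the default).
#' @param colors Optional vector of colours recycled over species in column
#'   order.
#' @return A ggplot object.
#' @seealso [plot_panels()] to write the figure to a file.
#' @export
panel_figure <- function(scan, colors = NULL) {
  if (!inherits(scan, "stability_scan"))
    stop("`scan` must be a stability_scan", call. = FALSE)
  keep <- !vapply(scan$curves, is.null, TRUE)
  curves <- scan$curves[keep]
  results <- scan$results[keep]
  if (length(curves) == 0L) stop("no curves to plot", call. = FALSE)
  for (i in seq_along(curves)) {
    if (!identical(curves[[i]]$group, results[[i]]$group) ||
        !identical(curves[[i]]$species, results[[i]]$species))
      stop("curve/result mismatch at position ", i, call. = FALSE)
  }

  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(group = cv$group, species = cv$species,
               k = seq_len(cv$k_max), mean = cv$means,
               stringsAsFactors = FALSE)))
  res_df <- do.call(rbind, lapply(results, function(r)
    data.frame(group = r$group, species = r$species,
               stability_point = r$stability_point,
               estimated_prevalence = r$estimated_prevalence,
               tail_prevalence = r$tail_prevalence, k_max = r$k_max,
               stringsAsFactors = FALSE)))

  groups <- unique(curve_df$group)
  species <- unique(curve_df$species)
  curve_df$group <- factor(curve_df$group, levels = groups)
  res_df$group <- factor(res_df$group, levels = groups)
  curve_df$species <- factor(curve_df$species, levels = species)
  res_df$species <- factor(res_df$species, levels = species)

  if (is.null(colors))
    colors <- grDevices::hcl.colors(max(3L, length(species)), "Dark 3")
  colors <- setNames(rep_len(colors, length(species)), species)

  # staggered top labels: one row per species slot so numbers never collide
  res_df$slot <- as.integer(res_df$species)
  res_df$top_label <- ifelse(is.na(res_df$stability_point), "na",
                             as.character(res_df$stability_point))
  res_df$top_x <- ifelse(is.na(res_df$stability_point), res_df$k_max / 2,
                         res_df$stability_point)
  # coincident stability points: a single dotted line per (group, k)
  vline_df <- res_df[!is.na(res_df$stability_point), , drop = FALSE]
  vline_df <- vline_df[!duplicated(vline_df[c("group", "stability_point")]), ,
                       drop = FALSE]
  tail_df <- res_df[!is.na(res_df$tail_prevalence), , drop = FALSE]
  tail_df$lab <- format_prevalence(tail_df$tail_prevalence)
  est <- !is.na(tail_df$stability_point)
  tail_df$lab[est] <- format_prevalence(tail_df$estimated_prevalence[est])

  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$k, y = .data$mean,
                                         colour = .data$species)) +
    ggplot2::geom_vline(data = vline_df,
                        ggplot2::aes(xintercept = .data$stability_point,
                                     colour = .data$species),
                        linetype = "dotted", show.legend = FALSE) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_text(data = res_df,
                       ggplot2::aes(x = .data$top_x, y = Inf,
                                    label = .data$top_label,
                                    vjust = .data$slot + 0.4),
                       size = 3, fontface = "bold", show.legend = FALSE) +
    ggplot2::geom_text(data = tail_df,
                       ggplot2::aes(x = .data$k_max, y = .data$tail_prevalence,
                                    label = .data$lab),
                       hjust = -0.15, size = 3, show.legend = FALSE) +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::scale_colour_manual(values = colors, name = NULL, drop = FALSE) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.12))) +
    ggplot2::coord_cartesian(ylim = c(0, 100), clip = "off") +
    ggplot2::labs(x = "Number of samples (k)",
                  y = "Mean prevalence (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom",
                   legend.text = ggplot2::element_text(face = "italic"),
                   strip.text = ggplot2::element_text(face = "italic"))
}

#' Write the panel figure to an image file
#'
#' Renders [panel_figure()] to PNG (default, 300 dpi), PDF or SVG, chosen
#' from the file extension.
#'
#' @param scan A `"stability_scan"` from [estimate_all()].
#' @param path Output path ending in `.png`, `.pdf` or `.svg`.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution (PNG only).
#' @param colors Passed to [panel_figure()].
#' @return Invisibly, `path`.
#' @export
plot_panels <- function(scan, path, width = 9, height = 6, dpi = 300,
                        colors = NULL) {
  fig <- panel_figure(scan, colors = colors)
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    png = function(f, ...) grDevices::png(f, width = width, height = height,
                                          units = "in", res = dpi),
    pdf = function(f, ...) grDevices::pdf(f, width = width, height = height),
    svg = function(f, ...) grDevices::svg(f, width = width, height = height),
    stop("unsupported figure format: .", ext, call. = FALSE))
  dev(path)
  on.exit(grDevices::dev.off())
  print(fig)
  invisible(path)
}

#' @export
plot.stability_scan <- function(x, ...) print(panel_figure(x, ...))

#' @importFrom ggplot2 .data
NULL
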