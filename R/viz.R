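#' Configure a parallel-coordinate plot
#'
#' @param axis_order Objective keys in display order (default: the
#'   canonical order cost, pain change, function change, supervised
#'   sessions, period). Must be a permutation of the result's objectives.
#' @param orient_better_up If `TRUE` (default), every axis is oriented so
#'   that better values point up (minimized objectives are inverted), which
#'   makes fully satisfying alternatives visually dominant.
#' @param highlight_colors Colors cycled over group I polylines.
#' @param shade_color,shade_alpha Style of group II polylines.
#' @param band_fill Fill color of the preferred-range band on each axis.
#' @param format `"svg"` or `"png"`.
#' @return A list of class `plot_config`.
#' @export
plot_config <- function(axis_order = NULL, orient_better_up = TRUE,
                        highlight_colors = c("#D55E00", "#0072B2", "#009E73",
                                             "#CC79A7", "#E69F00"),
                        shade_color = "grey55", shade_alpha = 0.35,
                        band_fill = "grey80", format = c("svg", "png")) {
  format <- match.arg(format)
  structure(list(axis_order = axis_order, orient_better_up = orient_better_up,
                 highlight_colors = highlight_colors, shade_color = shade_color,
                 shade_alpha = shade_alpha, band_fill = band_fill,
                 format = format),
            class = "plot_config")
}

# map objective values to [0, 1] axis positions (better = 1 when oriented up)
axis_position <- function(values, ideal, nadir, direction, orient_better_up) {
  width <- ideal - nadir
  if (width == 0) return(rep(0.5, length(values)))
  pos <- (values - nadir) / width   # 1 at ideal, 0 at nadir
  if (!orient_better_up && direction == "minimize") pos <- 1 - pos
  if (!orient_better_up && direction == "maximize") pos
  pos
}

#' Draw manifest for a parallel-coordinate rendering
#'
#' Computes everything [render_parallel_coordinates()] draws, without
#' touching a graphics device: one polyline per selected alternative across
#' the objective axes, axis endpoints equal to the dataset's ideal/nadir
#' values, and the preferred-range band on each axis. Tests assert on this
#' manifest instead of comparing pixels.
#'
#' @param result A [select_compromises()] / [run_iteration()] result with a
#'   nonempty selection.
#' @param config A [plot_config()].
#' @return A list of class `draw_manifest` with tibbles `polylines` (id,
#'   group, highlighted, color, alpha), `points` (id, axis key, axis index,
#'   raw value, y position), `axes` (objective, top/bottom raw values), and
#'   `bands` (objective, ymin, ymax on the unit axis).
#' @export
draw_manifest <- function(result, config = plot_config()) {
  stopifnot(inherits(result, "compromise_selection"), inherits(config, "plot_config"))
  sel <- result$selection
  if (!nrow(sel)) stop("selection is empty; nothing to draw", call. = FALSE)
  norm <- result$ideal_nadir
  keys <- norm$objective
  order_keys <- config$axis_order %||% keys
  if (!setequal(order_keys, keys) || length(order_keys) != length(keys)) {
    stop("axis_order must be a permutation of the objective keys", call. = FALSE)
  }
  g1_ids <- sel$id[sel$group == "I"]
  colors <- rep(config$highlight_colors, length.out = max(1L, length(g1_ids)))
  polylines <- tibble::tibble(
    id = sel$id, group = sel$group,
    highlighted = sel$group == "I",
    color = ifelse(sel$group == "I",
                   colors[match(sel$id, g1_ids)], config$shade_color),
    alpha = ifelse(sel$group == "I", 1, config$shade_alpha)
  )
  pts <- do.call(rbind, lapply(seq_along(order_keys), function(j) {
    key <- order_keys[j]
    nr <- norm[norm$objective == key, ]
    tibble::tibble(
      id = sel$id, axis = key, axis_index = j, value = sel[[key]],
      y = axis_position(sel[[key]], nr$ideal, nr$nadir, nr$direction,
                        config$orient_better_up)
    )
  }))
  axes <- do.call(rbind, lapply(seq_along(order_keys), function(j) {
    key <- order_keys[j]
    nr <- norm[norm$objective == key, ]
    top <- if (config$orient_better_up) nr$ideal else
      if (nr$direction == "maximize") nr$ideal else nr$nadir
    bottom <- if (config$orient_better_up) nr$nadir else
      if (nr$direction == "maximize") nr$nadir else nr$ideal
    tibble::tibble(objective = key, axis_index = j,
                   top_value = top, bottom_value = bottom)
  }))
  bands <- do.call(rbind, lapply(seq_along(order_keys), function(j) {
    key <- order_keys[j]
    nr <- norm[norm$objective == key, ]
    r <- result$prefs[[key]]
    ys <- axis_position(c(r$lower, r$upper), nr$ideal, nr$nadir, nr$direction,
                        config$orient_better_up)
    tibble::tibble(objective = key, axis_index = j,
                   ymin = max(0, min(ys)), ymax = min(1, max(ys)))
  }))
  structure(list(polylines = polylines, points = pts, axes = axes, bands = bands,
                 orient_better_up = config$orient_better_up),
            class = "draw_manifest")
}

#' Parallel-coordinate plot of an iteration's compromises
#'
#' Builds a ggplot with one vertical axis per objective (endpoints at the
#' dataset's ideal/nadir values), the preferred range drawn as a band on
#' each axis, group I alternatives as full-opacity colored polylines, and
#' group II alternatives shaded in low-opacity grey. The legend maps lines
#' to record ids (study labels).
#'
#' @inheritParams draw_manifest
#' @return A ggplot object, with the [draw_manifest()] attached as
#'   attribute `"manifest"`.
#' @export
parallel_coordinates_plot <- function(result, config = plot_config()) {
  man <- draw_manifest(result, config)
  pts <- merge(man$points, man$polylines, by = "id")
  pts <- pts[order(pts$id, pts$axis_index), ]
  axis_labels <- sprintf("%s\n[%g, %g]", man$axes$objective,
                         man$axes$bottom_value, man$axes$top_value)
  line_colors <- stats::setNames(man$polylines$color, man$polylines$id)
  line_alpha <- stats::setNames(man$polylines$alpha, man$polylines$id)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = man$bands,
      ggplot2::aes(xmin = .data$axis_index - 0.06, xmax = .data$axis_index + 0.06,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = config$band_fill, alpha = 0.6
    ) +
    ggplot2::geom_vline(xintercept = man$axes$axis_index, color = "grey40") +
    ggplot2::geom_line(
      data = pts,
      ggplot2::aes(x = .data$axis_index, y = .data$y, group = .data$id,
                   color = .data$id, alpha = .data$id),
      linewidth = 0.9
    ) +
    ggplot2::scale_color_manual(values = line_colors, name = "alternative") +
    ggplot2::scale_alpha_manual(values = line_alpha, guide = "none") +
    ggplot2::scale_x_continuous(breaks = man$axes$axis_index, labels = axis_labels) +
    ggplot2::scale_y_continuous(limits = c(-0.02, 1.02)) +
    ggplot2::labs(x = NULL,
                  y = if (man$orient_better_up) "worst → best" else "axis position") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
  attr(p, "manifest") <- man
  p
}

#' Render a parallel-coordinate plot to a file
#'
#' @inheritParams draw_manifest
#' @param path Output file; its extension should match `config$format`
#'   (`svg` default, or `png`).
#' @param width,height Device size in inches.
#' @return The [draw_manifest()], invisibly.
#' @export
render_parallel_coordinates <- function(result, path, config = plot_config(),
                                        width = 8, height = 5) {
  p <- parallel_coordinates_plot(result, config)
  dev <- switch(config$format,
                svg = grDevices::svg,
                png = function(filename, width, height) {
                  grDevices::png(filename, width = width, height = height,
                                 units = "in", res = 150)
                })
  dev(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(attr(p, "manifest"))
}
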