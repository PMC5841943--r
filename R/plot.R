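# Plotting: ggplot2 autoplot methods for tissues and simulation runs, and a
# dependency-free SVG frame writer for animations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tissue
#'
#' Cell outlines as polygons, optionally with a random subsample of the
#' transversal springs overlaid (all springs drawn would hide the cells, so
#' by default half are shown, active ones in red).
#'
#' @param object A `tissue` object.
#' @param springs Fraction of springs to draw (0 disables; subsampling is
#'   deterministic).
#' @param fill Aesthetic for cells: `"none"`, or the name of a per-cell
#'   metric column computed on the fly (`"lobeyness"`, `"area"`,
#'   `"aspect_ratio"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue <- function(object, springs = 0.5, fill = "none", ...) {
  ctr <- tissue_contours(object)
  gg <- ggplot2::ggplot()
  if (fill == "none") {
    gg <- gg + ggplot2::geom_polygon(
      data = ctr,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$cell_id),
      fill = "grey92", colour = "black", linewidth = 0.3)
  } else {
    met <- contour_metrics(ctr, lec = FALSE)
    ctr2 <- dplyr::left_join(ctr, met[, c("cell_id", fill)], by = "cell_id")
    gg <- gg + ggplot2::geom_polygon(
      data = ctr2,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$cell_id,
                   fill = .data[[fill]]),
      colour = "black", linewidth = 0.3) +
      ggplot2::scale_fill_viridis_c(name = fill)
  }
  if (springs > 0 && nrow(object$springs) > 0) {
    s <- object$springs
    keep <- .lcg_unif(nrow(s)) < springs
    if (any(keep)) {
      s <- s[keep, , drop = FALSE]
      len <- .edge_lengths(object$nodes, s$a, s$b)
      seg <- tibble::tibble(x = object$nodes[s$a, 1], y = object$nodes[s$a, 2],
                            xend = object$nodes[s$b, 1],
                            yend = object$nodes[s$b, 2],
                            active = len > s$ref)
      gg <- gg + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$active),
        linewidth = 0.25, alpha = 0.7) +
        ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                                `FALSE` = "steelblue"),
                                     name = "taut")
    }
  }
  gg + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Plot the lobeyness trajectory of a run
#'
#' Interior-cell mean lobeyness (with the per-cell cloud) against simulation
#' step.
#'
#' @param object A `puzzle_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.puzzle_sim <- function(object, ...) {
  m <- tidy(object)
  avg <- m |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(lobeyness = mean(.data$lobeyness), .groups = "drop")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$step, y = .data$lobeyness)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_line(data = avg, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "simulation step", y = "lobeyness",
                  title = paste0(object$scenario, " scenario")) +
    ggplot2::theme_minimal()
}

#' Write a tissue frame as SVG
#'
#' Minimal, dependency-free SVG output for animation frames: cells drawn as
#' black-outlined polygons, a deterministic 50 percent subsample of active
#' transversal springs in red.
#'
#' @param t A `tissue` object.
#' @param path Output file.
#' @param springs Fraction of springs drawn (default 0.5).
#' @param width_px Image width in pixels (height follows the aspect ratio).
#' @return `t`, invisibly.
#' @export
write_tissue_svg <- function(t, path, springs = 0.5, width_px = 800) {
  stopifnot(inherits(t, "tissue"))
  xr <- range(t$nodes[, 1]); yr <- range(t$nodes[, 2])
  pad <- 0.02 * max(diff(xr), diff(yr))
  sc <- width_px / (diff(xr) + 2 * pad)
  h <- round((diff(yr) + 2 * pad) * sc)
  px <- function(x) (x - xr[1] + pad) * sc
  py <- function(y) h - (y - yr[1] + pad) * sc # SVG y grows downwards
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width_px, h, width_px, h),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width_px, h))
  for (l in t$cells) {
    pts <- paste(sprintf("%.2f,%.2f", px(t$nodes[l, 1]), py(t$nodes[l, 2])),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="none" stroke="black" stroke-width="1"/>', pts))
  }
  if (springs > 0 && nrow(t$springs) > 0) {
    s <- t$springs
    len <- .edge_lengths(t$nodes, s$a, s$b)
    keep <- (.lcg_unif(nrow(s)) < springs) & len > s$ref
    if (any(keep)) {
      s <- s[keep, , drop = FALSE]
      lines <- c(lines, sprintf(
        '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="red" stroke-width="0.7"/>',
        px(t$nodes[s$a, 1]), py(t$nodes[s$a, 2]),
        px(t$nodes[s$b, 1]), py(t$nodes[s$b, 2])))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(t)
}
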