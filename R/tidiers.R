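# broom-style accessors for simulation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x A `puzzle_sim` object from [run_scenario()].
#' @param interior_only Keep interior cells only (default `TRUE`; boundary
#'   cells are clamped to the imposed growth and artefactual).
#' @param ... Unused.
#' @return The per-cell per-step metrics tibble.
#' @export
tidy.puzzle_sim <- function(x, interior_only = TRUE, ...) {
  m <- x$metrics
  if (interior_only) m <- dplyr::filter(m, .data$interior)
  m
}

#' One-row summary of a simulation result
#'
#' @param x A `puzzle_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: scenario, sizes, cumulative growth and the final
#'   interior-cell shape summary (mean lobeyness, mean aspect ratio, LEC
#'   radius percentiles).
#' @export
glance.puzzle_sim <- function(x, ...) {
  fin <- dplyr::filter(x$metrics, .data$step == max(.data$step), .data$interior)
  tibble::tibble(
    scenario = x$scenario,
    n_steps = x$n_steps,
    n_cells = length(x$tissue$cells),
    n_interior = sum(interior_cells(x$tissue)),
    growth_x = x$params$g_x^x$n_steps,
    growth_y = if (is.null(x$params$gradient)) x$params$g_y^x$n_steps else NA_real_,
    mean_lobeyness = mean(fin$lobeyness),
    mean_aspect_ratio = mean(fin$aspect_ratio),
    lec_p50 = stats::median(fin$lec_radius, na.rm = TRUE),
    lec_p90 = as.numeric(stats::quantile(fin$lec_radius, 0.9, na.rm = TRUE)),
    mean_active_springs = mean(fin$active_springs)
  )
}
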