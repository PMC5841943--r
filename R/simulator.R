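# The three-phase growth loop: (1) reassign transversal connections from the
# current cell shapes, (2) scale the tissue by the imposed growth and relax
# wall springs (transversal references are untouched -- the reinforcement does
# not grow), (3) find mechanical equilibrium. Lobes emerge because phase 3
# pulls over-extended spans back while phase 2 keeps expanding the tissue.

# Per-node growth factors; gradient runs interpolate the y factor linearly
# across the current tissue width so the displacement map stays continuous.
.growth_factors <- function(nodes, bbox, p) {
  gx <- rep(p$g_x, nrow(nodes))
  if (is.null(p$gradient)) {
    gy <- rep(p$g_y, nrow(nodes))
  } else {
    tx <- (nodes[, 1] - bbox[1]) / max(bbox[2] - bbox[1], 1e-300)
    gy <- p$gradient[1] + (p$gradient[2] - p$gradient[1]) * pmin(1, pmax(0, tx))
  }
  matrix(c(gx, gy), ncol = 2)
}

#' Grow a tissue by one step
#'
#' Applies the imposed tissue-scale growth map to every node, relaxes the
#' wall springs (rest length := post-growth length), leaves transversal
#' spring references untouched, and subdivides walls that exceed
#' `p$max_segment`. Growth can be isotropic, anisotropic (`g_y = 1`), or a
#' left-to-right gradient of anisotropy (`p$gradient`).
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object (`g_x`, `g_y` / `gradient` `>= 1`).
#' @return The grown `tissue`.
#' @export
grow_tissue <- function(t, p) {
  stopifnot(inherits(t, "tissue"))
  g <- .growth_factors(t$nodes, t$bbox, p)
  if (any(g < 1)) stop("growth factors must be >= 1", call. = FALSE)
  t$nodes <- t$nodes * g
  t$bbox <- c(t$bbox[1] * p$g_x, t$bbox[2] * p$g_x,
              t$bbox[3] * min(g[, 2]), t$bbox[4] * max(g[, 2]))
  # relax *stretched* wall springs: rest length tracks growth but never
  # shrinks, so transiently compressed segments keep pushing back
  t$walls$rest <- pmax(t$walls$rest,
                       .edge_lengths(t$nodes, t$walls$a, t$walls$b))
  .subdivide_walls(t, p$max_segment)
}

#' Advance the simulation by one step
#'
#' Executes connection placement (at steps where
#' `(step_index - 1) %% reset_period == 0`), growth and equilibration, in
#' that order.
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object.
#' @param step_index 1-based step counter (controls connection resets).
#' @return The updated `tissue` (with `equilibrate()`'s attributes).
#' @export
sim_step <- function(t, p, step_index = 1L) {
  if ((step_index - 1L) %% p$reset_period == 0L) {
    t <- place_connections(t, p)
  }
  t <- grow_tissue(t, p)
  equilibrate(t, p)
}

#' Per-cell metrics of a tissue state
#'
#' Computes the standard shape metrics for every cell of a tissue, plus the
#' per-cell count of active (taut) transversal springs and an `interior`
#' flag. The largest empty circle is the costly metric and is optional.
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object (for spring activity).
#' @param step Step label stored in the output.
#' @param lec Compute LEC radius/area (and the stress proxy)?
#' @param spacing LEC resampling interval; `NULL` for the per-cell default.
#' @return A tibble, one row per cell: `step`, `cell_id`, `interior`, the
#'   [contour_metrics()] columns and `active_springs`.
#' @export
measure_tissue <- function(t, p, step = 0L, lec = FALSE, spacing = NULL) {
  stopifnot(inherits(t, "tissue"))
  met <- contour_metrics(tissue_contours(t), lec = lec, spacing = spacing)
  act <- rep(0L, length(t$cells))
  if (nrow(t$springs) > 0) {
    st <- spring_state(t, p)
    tab <- table(st$cell[st$active])
    act[as.integer(names(tab))] <- as.integer(tab)
  }
  dplyr::bind_cols(
    tibble::tibble(step = as.integer(step),
                   interior = interior_cells(t)),
    met
  ) |>
    dplyr::mutate(active_springs = act) |>
    dplyr::relocate("step", "cell_id", "interior")
}

.scenarios <- c("isotropic", "anisotropic", "gradient", "spk1",
                "no_restriction")

# Scenario presets layered over base parameters. spk1: convexity inhibition
# off, stiffer connections and walls, less frequent connection resets.
.apply_scenario <- function(p, scenario) {
  switch(scenario,
    isotropic = p,
    anisotropic = { p$g_y <- 1; p$gradient <- NULL; p },
    gradient = { p$gradient <- c(1, p$g_x); p },
    spk1 = {
      # lobe inhibition off; grossly rigidified walls (stretching and
      # bending) and slightly stronger, less frequently re-set connections
      # stand in for impaired ROP-mediated cytoskeletal remodelling
      p$spk1_mode <- TRUE
      p$k_m <- 1.15 * p$k_m
      p$k_s <- 40 * p$k_s
      p$k_b <- 40 * p$k_b
      p$reset_period <- max(2L, 2L * p$reset_period)
      p
    },
    no_restriction = { p$k_m <- 0; p },
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' Run a named growth scenario
#'
#' Runs the full growth loop under one of the package's scenario presets:
#' \describe{
#'   \item{isotropic}{equal growth in x and y; puzzle cells emerge.}
#'   \item{anisotropic}{growth along x only (`g_y = 1`); cells elongate, no
#'     lobes.}
#'   \item{gradient}{per-step y growth interpolates from 1 (left edge) to
#'     `g_x` (right edge): a spatial gradient from elongated to lobed cells.}
#'   \item{spk1}{lobe formation disabled at the rule level (no convexity
#'     inhibition) with stiffer walls/connections and rarer connection
#'     resets; cells interdigitate into worm-like shapes instead of lobing.}
#'   \item{no_restriction}{`k_m = 0` control: growth alone, cells stay affine
#'     images of the template.}
#' }
#'
#' @param scenario One of `"isotropic"`, `"anisotropic"`, `"gradient"`,
#'   `"spk1"`, `"no_restriction"`.
#' @param params Base [sim_params()]; scenario presets are layered on top.
#' @param n_steps Number of steps (default `params$n_steps`).
#' @param template Starting `tissue`; by default generated with
#'   [generate_tissue()] from `params$seed` (and a wider box for the
#'   gradient scenario).
#' @param lec_every Compute LEC metrics every this many steps (`0` = at the
#'   first and final step only). Cheap metrics are recorded every step.
#' @param snapshot_every Keep tissue snapshots every this many steps (`0` =
#'   initial and final only).
#' @param quiet Suppress progress messages.
#' @return A `puzzle_sim` object: list with `scenario`, `params`, `metrics`
#'   (per-cell per-step tibble), `tissue` (final state), `initial`,
#'   `snapshots` (named list of tissues) and `log` (per-step solver
#'   diagnostics).
#' @examples
#' \donttest{
#' sim <- run_scenario("isotropic", sim_params(n_steps = 5, seed = 1),
#'                     template = generate_tissue(n_cells = 9, width = 30,
#'                                                height = 30, seed = 1))
#' glance(sim)
#' }
#' @export
run_scenario <- function(scenario = "isotropic", params = sim_params(),
                         n_steps = NULL, template = NULL, lec_every = 0L,
                         snapshot_every = 0L, quiet = TRUE) {
  scenario <- match.arg(scenario, .scenarios)
  p <- .apply_scenario(params, scenario)
  if (is.null(n_steps)) n_steps <- p$n_steps
  if (is.null(template)) {
    if (scenario == "gradient") {
      template <- generate_tissue(n_cells = 48, width = 90, height = 60,
                                  spacing = p$max_segment, seed = p$seed)
    } else {
      template <- generate_tissue(spacing = p$max_segment, seed = p$seed)
    }
  }
  t <- template
  records <- vector("list", n_steps + 1L)
  logs <- vector("list", n_steps)
  records[[1]] <- measure_tissue(t, p, step = 0L, lec = TRUE)
  snapshots <- list(step0 = t)
  for (s in seq_len(n_steps)) {
    # solver non-convergence is summarized once at the end from the log,
    # not warned forty times mid-run
    t <- withCallingHandlers(
      sim_step(t, p, step_index = s),
      warning = function(w) {
        if (grepl("^equilibrate:", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    do_lec <- (lec_every > 0L && s %% lec_every == 0L) || s == n_steps
    records[[s + 1L]] <- measure_tissue(t, p, step = s, lec = do_lec)
    logs[[s]] <- tibble::tibble(step = s,
                                residual = attr(t, "residual"),
                                iterations = attr(t, "iterations"),
                                converged = attr(t, "converged"),
                                energy = total_energy(t, p),
                                n_nodes = n_nodes(t),
                                n_springs = nrow(t$springs))
    if ((snapshot_every > 0L && s %% snapshot_every == 0L) || s == n_steps) {
      snapshots[[paste0("step", s)]] <- t
    }
    if (!quiet) {
      message(sprintf("step %d/%d: %d nodes, %d springs, residual %.2g",
                      s, n_steps, n_nodes(t), nrow(t$springs),
                      attr(t, "residual")))
    }
  }
  log <- dplyr::bind_rows(logs)
  if (any(!log$converged)) {
    warning(sprintf(
      "%d of %d steps stopped above solver_tol (worst residual %.3g); see $log",
      sum(!log$converged), n_steps, max(log$residual)), call. = FALSE)
  }
  structure(list(scenario = scenario, params = p, n_steps = n_steps,
                 metrics = dplyr::bind_rows(records),
                 tissue = t, initial = template, snapshots = snapshots,
                 log = log),
            class = "puzzle_sim")
}

#' @export
print.puzzle_sim <- function(x, ...) {
  fin <- dplyr::filter(x$metrics, .data$step == max(.data$step), .data$interior)
  cat("<puzzle_sim> scenario:", x$scenario, "-", x$n_steps, "steps,",
      length(x$tissue$cells), "cells\n")
  cat(sprintf("  final interior mean lobeyness %.3f, mean aspect ratio %.2f\n",
              mean(fin$lobeyness), mean(fin$aspect_ratio)))
  invisible(x)
}

#' Sweep one model parameter across a range
#'
#' Re-runs a scenario once per value of one parameter and summarizes the
#' final interior cells, demonstrating that lobing has no sharp onset
#' threshold but varies continuously. `"isotropy"` scales the per-step y
#' growth rate relative to x (`1` = isotropic reference, `0.5` = half the
#' y rate).
#'
#' @param parameter One of `"isotropy"`, `"k_b"`, `"k_m"`, `"k_s"`,
#'   `"min_micro"`, `"theta_micro"`. All but `"isotropy"` are multiples of
#'   the reference value in `base`.
#' @param values Numeric vector of parameter values (fractions of reference).
#' @param base Base [sim_params()].
#' @param n_steps,template Passed to [run_scenario()].
#' @return A tibble with one row per value: final interior mean lobeyness,
#'   mean aspect ratio and LEC radius percentiles (10/50/90).
#' @export
sweep_parameter <- function(parameter, values, base = sim_params(),
                            n_steps = NULL, template = NULL) {
  parameter <- match.arg(parameter, c("isotropy", "k_b", "k_m", "k_s",
                                      "min_micro", "theta_micro"))
  purrr::map_dfr(values, function(v) {
    p <- base
    if (parameter == "isotropy") {
      p$g_y <- 1 + v * (p$g_x - 1)
    } else {
      p[[parameter]] <- v * base[[parameter]]
    }
    sim <- run_scenario("isotropic", p, n_steps = n_steps, template = template)
    fin <- dplyr::filter(sim$metrics, .data$step == max(.data$step),
                         .data$interior)
    tibble::tibble(
      parameter = parameter, value = v,
      mean_lobeyness = mean(fin$lobeyness),
      mean_aspect_ratio = mean(fin$aspect_ratio),
      lec_p10 = stats::quantile(fin$lec_radius, 0.1, na.rm = TRUE),
      lec_p50 = stats::quantile(fin$lec_radius, 0.5, na.rm = TRUE),
      lec_p90 = stats::quantile(fin$lec_radius, 0.9, na.rm = TRUE)
    )
  })
}
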