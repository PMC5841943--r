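# Tissue state container and model parameters.
#
# A tissue is a shared-node polygonal cell complex: cell outlines are loops of
# node indices into one common node table, so an interior wall (and every node
# on it) is shared by exactly two cells and lobes in one cell are indentations
# in its neighbour. Mechanically each wall segment is a linear spring, each
# node carries a bending hinge per owning cell, and transversal springs span
# cell interiors.

#' Simulation parameters
#'
#' Constructs the full parameter set of the growth model. Stiffnesses are in
#' force units per unit strain (walls), per unit extension (transversal
#' springs) and per radian (hinges); lengths in micrometres; growth factors
#' are per-step scale factors.
#'
#' Defaults are calibrated to the regime where isotropic tissue growth
#' produces lobed (puzzle) cells and anisotropic growth produces elongated
#' ones; see the package vignette for the calibration rationale.
#'
#' @param k_s Wall stretching stiffness (strain-based: subdividing a wall does
#'   not change its mechanics).
#' @param k_b Bending stiffness of wall hinges.
#' @param k_m Stiffness of transversal (cellulose/microtubule) springs;
#'   tension-only.
#' @param min_micro Target length of a transversal connection (micrometres):
#'   springs only exert force beyond it, so it sets the largest open span --
#'   roughly the LEC diameter -- a cell tolerates before restricting growth.
#' @param theta_micro Half-angle (radians) of the cone around the outward node
#'   normal within which a connection may be made.
#' @param kappa_convex Convexity threshold (radians) on the total turning
#'   angle of the local wall arc (over `+/- convex_window` nodes) beyond
#'   which a node counts as part of a lobe and is excluded from connections.
#' @param convex_window Half-width (nodes) of the arc over which turning is
#'   accumulated for the convexity test.
#' @param s_min Minimum separation (in contour nodes) between the two
#'   endpoints of a connection, so chords actually cross the cell.
#' @param reset_period Steps between connection reassignments (1 = every
#'   step).
#' @param g_x,g_y Per-step tissue growth factors along x and y (`>= 1`).
#' @param gradient Either `NULL` or a length-2 vector `c(left, right)` of
#'   per-step y-growth factors interpolated linearly across the tissue width
#'   (overrides `g_y`), producing a spatial gradient of growth anisotropy.
#' @param max_segment Maximum wall segment length (micrometres); longer walls
#'   are subdivided after growth.
#' @param solver_tol Equilibration stops when the largest net force on any
#'   free node falls below this.
#' @param max_iter Maximum minimizer iterations per equilibration.
#' @param n_steps Default number of simulation steps for scenario runs.
#' @param seed Random seed; randomness enters only through template
#'   generation, the growth loop itself is deterministic.
#' @param spk1_mode Disable the convexity inhibition (connections may attach
#'   inside lobes), as in the *spk1* scenario.
#' @return An object of class `sim_params` (a named list).
#' @export
sim_params <- function(k_s = 5, k_b = 0.3, k_m = 5,
                       min_micro = 10, theta_micro = 0.35,
                       kappa_convex = 0.5, convex_window = 2L, s_min = 5L,
                       reset_period = 1L,
                       g_x = 1.03, g_y = 1.03, gradient = NULL,
                       max_segment = 2.5,
                       solver_tol = 0.05, max_iter = 500L,
                       n_steps = 45L, seed = 1L, spk1_mode = FALSE) {
  p <- list(k_s = k_s, k_b = k_b, k_m = k_m, min_micro = min_micro,
            theta_micro = theta_micro, kappa_convex = kappa_convex,
            convex_window = as.integer(convex_window),
            s_min = as.integer(s_min),
            reset_period = as.integer(reset_period),
            g_x = g_x, g_y = g_y, gradient = gradient,
            max_segment = max_segment, solver_tol = solver_tol,
            max_iter = as.integer(max_iter), n_steps = as.integer(n_steps),
            seed = as.integer(seed), spk1_mode = isTRUE(spk1_mode))
  stopifnot(p$k_s >= 0, p$k_b >= 0, p$k_m >= 0, p$min_micro > 0,
            p$theta_micro > 0, p$theta_micro < pi / 2,
            p$g_x >= 1, p$g_y >= 1, p$reset_period >= 1,
            p$max_segment > 0, p$solver_tol > 0, p$s_min >= 1)
  if (!is.null(p$gradient)) {
    stopifnot(length(p$gradient) == 2, all(p$gradient >= 1))
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", names(flat), " = ",
             vapply(flat, function(v) paste(format(v), collapse = ":"),
                    character(1)), collapse = "\n"), "\n")
  invisible(x)
}

# Internal constructor; `cells` are loops of 1-based node indices (CCW),
# `theta0` the per-cell rest turning angles, `walls` the unique edge table.
.new_tissue <- function(nodes, cells, theta0, walls, boundary, bbox,
                        springs = NULL) {
  if (is.null(springs)) {
    springs <- tibble::tibble(cell = integer(), a = integer(), b = integer(),
                              ref = double())
  }
  structure(list(nodes = nodes, cells = cells, theta0 = theta0, walls = walls,
                 boundary = boundary, bbox = bbox, springs = springs),
            class = "tissue")
}

.wall_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))

# Unique undirected edges over all cell loops, with ownership counts.
.collect_edges <- function(cells) {
  a <- unlist(lapply(cells, function(l) l), use.names = FALSE)
  b <- unlist(lapply(cells, function(l) l[c(2:length(l), 1)]), use.names = FALSE)
  key <- .wall_key(a, b)
  first <- !duplicated(key)
  list(a = pmin(a, b)[first], b = pmax(a, b)[first], key = key[first],
       count = as.integer(table(key)[key[first]]))
}

.edge_lengths <- function(nodes, a, b) {
  sqrt((nodes[a, 1] - nodes[b, 1])^2 + (nodes[a, 2] - nodes[b, 2])^2)
}

#' Number of cells / nodes in a tissue
#' @param t A `tissue` object.
#' @return Integer count.
#' @export
n_cells <- function(t) length(t$cells)

#' @rdname n_cells
#' @export
n_nodes <- function(t) nrow(t$nodes)

#' Cell outlines of a tissue as a long tibble
#'
#' @param t A `tissue` object.
#' @return A tibble with columns `cell_id`, `x`, `y`: the node positions of
#'   each cell loop in order (closing edge implicit), ready for
#'   [contour_metrics()] or ggplot2 polygons.
#' @export
tissue_contours <- function(t) {
  stopifnot(inherits(t, "tissue"))
  n <- lengths(t$cells)
  idx <- unlist(t$cells, use.names = FALSE)
  tibble::tibble(cell_id = rep(seq_along(t$cells), n),
                 x = t$nodes[idx, 1], y = t$nodes[idx, 2])
}

#' Which cells are interior (no clamped outline node)?
#'
#' Boundary cells are pinned to the imposed tissue growth along the outline
#' and are artefactual; metrics are usually restricted to interior cells.
#'
#' @param t A `tissue` object.
#' @return Logical vector, one entry per cell.
#' @export
interior_cells <- function(t) {
  vapply(t$cells, function(l) !any(t$boundary[l]), logical(1))
}

#' @export
print.tissue <- function(x, ...) {
  cat("<tissue> ", length(x$cells), " cells, ", nrow(x$nodes), " nodes, ",
      nrow(x$springs), " transversal springs\n", sep = "")
  cat("  bbox: [", paste(signif(x$bbox, 4), collapse = ", "), "]\n")
  invisible(x)
}

#' Validate tissue invariants
#'
#' Diagnostic check of the structural invariants a simulatable tissue must
#' satisfy: closed simple CCW cell loops without repeated nodes, interior
#' walls owned by at most two cells, positive wall rest lengths, finite node
#' positions, spring endpoints on their own cell.
#'
#' @param t A `tissue` object.
#' @return A tibble with columns `check` and `detail`, one row per violation;
#'   zero rows for a valid tissue.
#' @export
validate_tissue <- function(t) {
  stopifnot(inherits(t, "tissue"))
  bad <- list()
  add <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }
  if (anyNA(t$nodes) || any(!is.finite(t$nodes))) {
    add("finite_nodes", "non-finite node position")
  }
  for (ci in seq_along(t$cells)) {
    l <- t$cells[[ci]]
    if (length(l) < 3) add("loop_length", paste("cell", ci, "has <3 nodes"))
    if (anyDuplicated(l)) add("loop_simple", paste("cell", ci, "repeats a node"))
    if (any(l < 1 | l > nrow(t$nodes))) {
      add("loop_index", paste("cell", ci, "indexes a missing node"))
      next
    }
    if (length(l) >= 3 && !anyDuplicated(l)) {
      a <- .signed_area(t$nodes[l, , drop = FALSE])
      if (is.finite(a) && a <= 0) {
        add("loop_ccw", paste("cell", ci, "is clockwise or degenerate"))
      }
    }
    if (length(t$theta0[[ci]]) != length(l)) {
      add("theta0_length", paste("cell", ci, "rest-angle vector mismatched"))
    }
  }
  ed <- .collect_edges(t$cells)
  if (any(ed$count > 2)) {
    add("wall_manifold", paste(sum(ed$count > 2), "walls owned by >2 cells"))
  }
  if (any(t$walls$rest <= 0)) add("wall_rest", "non-positive wall rest length")
  if (!setequal(.wall_key(t$walls$a, t$walls$b), ed$key)) {
    add("wall_table", "wall table out of sync with cell loops")
  }
  if (nrow(t$springs) > 0) {
    ok <- vapply(seq_len(nrow(t$springs)), function(i) {
      l <- t$cells[[t$springs$cell[i]]]
      t$springs$a[i] %in% l && t$springs$b[i] %in% l &&
        t$springs$a[i] != t$springs$b[i]
    }, logical(1))
    if (!all(ok)) add("spring_endpoints", "spring endpoint off its cell loop")
    if (any(t$springs$ref <= 0)) add("spring_ref", "non-positive spring ref length")
  }
  if (length(bad) == 0) {
    return(tibble::tibble(check = character(), detail = character()))
  }
  dplyr::bind_rows(bad)
}

# Subdivide every wall longer than max_segment into equal pieces, updating
# loops, rest angles (new hinges are straight: rest turning angle 0), rest
# lengths (split proportionally) and boundary flags (a node interpolated on an
# outline wall is itself on the outline).
.subdivide_walls <- function(t, max_segment) {
  ed <- .collect_edges(t$cells)
  len <- .edge_lengths(t$nodes, ed$a, ed$b)
  k <- pmax(1L, ceiling(len / max_segment))
  if (all(k == 1L)) return(t)
  rest_of <- stats::setNames(t$walls$rest, .wall_key(t$walls$a, t$walls$b))
  nodes <- t$nodes
  bnd <- t$boundary
  chains <- vector("list", length(ed$a))
  names(chains) <- ed$key
  piece_rest <- stats::setNames(rest_of[ed$key] / k, ed$key)
  for (i in seq_along(ed$a)) {
    if (k[i] == 1L) {
      chains[[i]] <- c(ed$a[i], ed$b[i])
      next
    }
    tseq <- seq_len(k[i] - 1L) / k[i]
    new <- cbind(nodes[ed$a[i], 1] + tseq * (nodes[ed$b[i], 1] - nodes[ed$a[i], 1]),
                 nodes[ed$a[i], 2] + tseq * (nodes[ed$b[i], 2] - nodes[ed$a[i], 2]))
    ids <- nrow(nodes) + seq_len(k[i] - 1L)
    nodes <- rbind(nodes, new)
    on_outline <- ed$count[i] == 1L && bnd[ed$a[i]] && bnd[ed$b[i]]
    bnd <- c(bnd, rep(on_outline, k[i] - 1L))
    chains[[i]] <- c(ed$a[i], ids, ed$b[i])
  }
  cells2 <- vector("list", length(t$cells))
  theta2 <- vector("list", length(t$cells))
  for (ci in seq_along(t$cells)) {
    l <- t$cells[[ci]]
    th <- t$theta0[[ci]]
    pieces <- vector("list", length(l))
    tpieces <- vector("list", length(l))
    for (j in seq_along(l)) {
      u <- l[j]; v <- l[if (j == length(l)) 1L else j + 1L]
      ch <- chains[[.wall_key(u, v)]]
      if (ch[1] != u) ch <- rev(ch)
      pieces[[j]] <- ch[-length(ch)]
      tpieces[[j]] <- c(th[j], rep(0, length(ch) - 2L))
    }
    cells2[[ci]] <- unlist(pieces, use.names = FALSE)
    theta2[[ci]] <- unlist(tpieces, use.names = FALSE)
  }
  wa <- integer(0); wb <- integer(0); wr <- double(0)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    wa <- c(wa, ch[-length(ch)])
    wb <- c(wb, ch[-1])
    wr <- c(wr, rep(piece_rest[[i]], length(ch) - 1L))
  }
  walls <- tibble::tibble(a = pmin(wa, wb), b = pmax(wa, wb), rest = wr)
  .new_tissue(nodes, cells2, theta2, walls, bnd, t$bbox, t$springs)
}

# ---- JSON serialization ----------------------------------------------------

#' Write / read a tissue as JSON
#'
#' Serializes the full simulator state (nodes, cell loops, rest angles, walls
#' with rest lengths, boundary flags, transversal springs) to a versioned
#' JSON document. Node indices are 0-based in the file for language
#' neutrality and converted on read.
#'
#' @param t A `tissue` object.
#' @param path File path.
#' @return `write_tissue_json()` returns `t` invisibly; `read_tissue_json()`
#'   returns a `tissue`.
#' @export
write_tissue_json <- function(t, path) {
  stopifnot(inherits(t, "tissue"))
  doc <- list(
    schema = "puzzlecell-tissue/1",
    nodes = unname(t$nodes),
    cells = lapply(t$cells, function(l) l - 1L),
    theta0 = t$theta0,
    walls = list(a = t$walls$a - 1L, b = t$walls$b - 1L, rest = t$walls$rest),
    boundary = which(t$boundary) - 1L,
    bbox = t$bbox,
    springs = list(cell = t$springs$cell - 1L, a = t$springs$a - 1L,
                   b = t$springs$b - 1L, ref = t$springs$ref)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(t)
}

#' @rdname write_tissue_json
#' @export
read_tissue_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "puzzlecell-tissue/1")) {
    stop("not a puzzlecell tissue JSON document", call. = FALSE)
  }
  nodes <- matrix(as.double(doc$nodes), ncol = 2)
  cells <- lapply(doc$cells, function(l) as.integer(l) + 1L)
  theta0 <- lapply(doc$theta0, as.double)
  walls <- tibble::tibble(a = as.integer(doc$walls$a) + 1L,
                          b = as.integer(doc$walls$b) + 1L,
                          rest = as.double(doc$walls$rest))
  boundary <- rep(FALSE, nrow(nodes))
  boundary[as.integer(doc$boundary) + 1L] <- TRUE
  springs <- tibble::tibble(cell = as.integer(doc$springs$cell) + 1L,
                            a = as.integer(doc$springs$a) + 1L,
                            b = as.integer(doc$springs$b) + 1L,
                            ref = as.double(doc$springs$ref))
  .new_tissue(nodes, cells, theta0, walls, boundary, as.double(doc$bbox),
              springs)
}
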