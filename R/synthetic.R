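# Synthetic inputs: meristematic-like tissue templates (convex, roughly
# isodiametric polygonal cells tiling a rectangle with shared walls) and
# parametric single-cell contours used as fixtures.

# Clip a convex polygon by the half-plane n . x <= c (Sutherland-Hodgman).
.clip_halfplane <- function(poly, nx, ny, cc) {
  n <- nrow(poly)
  d <- poly[, 1] * nx + poly[, 2] * ny - cc
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 1e-12; djn <- d[j] <= 1e-12
    if (din) out <- rbind(out, poly[i, ])
    if (din != djn) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seed i clipped to the rectangle, via successive bisector
# half-planes against all other seeds. Exact for convex domains and needs no
# triangulation library.
.voronoi_cells <- function(seeds, width, height) {
  n <- nrow(seeds)
  rect <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  lapply(seq_len(n), function(i) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) < 3) next
      mid <- (seeds[i, ] + seeds[j, ]) / 2
      dir <- seeds[j, ] - seeds[i, ]
      poly <- .clip_halfplane(poly, dir[1], dir[2], sum(dir * mid))
    }
    poly
  })
}

.poly_centroid <- function(m) {
  n <- nrow(m)
  x <- m[, 1]; y <- m[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Generate a meristematic-like tissue template
#'
#' Builds the initial condition of the growth model: a rectangle tiled by
#' convex, roughly isodiametric polygonal cells with shared walls, emulating
#' the epidermis of a meristem before cells stop dividing. Seeds are placed on
#' a jittered lattice, tessellated (Voronoi, clipped to the rectangle),
#' optionally Lloyd-relaxed towards centroidal cells, and walls are
#' subdivided to the requested spacing. Wall rest lengths and hinge rest
#' angles are set to the as-built geometry, so the template starts in
#' mechanical equilibrium.
#'
#' @param n_cells Approximate number of cells (`>= 4`); rounded to a full
#'   lattice.
#' @param width,height Template extent in micrometres.
#' @param jitter Seed displacement as a fraction of the lattice pitch
#'   (0 = regular lattice).
#' @param lloyd_iters Lloyd relaxation iterations (default 2: near-isodiametric
#'   without collapsing to perfect hexagons).
#' @param spacing Maximum wall segment length after subdivision
#'   (micrometres).
#' @param seed Random seed; the only source of randomness in a simulation.
#' @return A `tissue` object.
#' @examples
#' t0 <- generate_tissue(n_cells = 9, width = 30, height = 30, seed = 1)
#' validate_tissue(t0)
#' @export
generate_tissue <- function(n_cells = 36, width = 60, height = 60,
                            jitter = 0.35, lloyd_iters = 2L, spacing = 2.5,
                            seed = 1L) {
  stopifnot(n_cells >= 4, width > 0, height > 0, jitter >= 0, spacing > 0)
  nx <- max(2L, round(sqrt(n_cells * width / height)))
  ny <- max(2L, round(n_cells / nx))
  px <- width / nx; py <- height / ny
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  gx <- rep((seq_len(nx) - 0.5) * px, times = ny)
  gy <- rep((seq_len(ny) - 0.5) * py, each = nx)
  seeds <- cbind(gx + (stats::runif(nx * ny) - 0.5) * jitter * px,
                 gy + (stats::runif(nx * ny) - 0.5) * jitter * py)
  polys <- .voronoi_cells(seeds, width, height)
  for (it in seq_len(lloyd_iters)) {
    seeds <- t(vapply(polys, .poly_centroid, numeric(2)))
    polys <- .voronoi_cells(seeds, width, height)
  }
  if (any(vapply(polys, nrow, integer(1)) < 3)) {
    stop("degenerate template cell; adjust n_cells/jitter", call. = FALSE)
  }
  .tissue_from_polys(polys, width, height, spacing)
}

# Assemble a shared-node tissue from per-cell polygons whose shared vertices
# agree to floating-point tolerance; vertices are snapped on a fine grid.
.tissue_from_polys <- function(polys, width, height, spacing) {
  snap <- max(width, height) * 1e-7
  keyof <- function(m) paste0(round(m[, 1] / snap), "_", round(m[, 2] / snap))
  all_pts <- do.call(rbind, polys)
  keys <- keyof(all_pts)
  first <- !duplicated(keys)
  nodes <- all_pts[first, , drop = FALSE]
  id_of <- stats::setNames(seq_len(nrow(nodes)), keys[first])
  cells <- vector("list", length(polys))
  off <- 0L
  for (ci in seq_along(polys)) {
    m <- polys[[ci]]
    # drop near-duplicate consecutive vertices introduced by clipping
    l <- unname(id_of[keyof(m)])
    l <- l[l != c(l[-1], l[1])]
    if (length(l) < 3) stop("degenerate template cell", call. = FALSE)
    if (.signed_area(nodes[l, , drop = FALSE]) < 0) l <- rev(l)
    cells[[ci]] <- l
    off <- off + nrow(m)
  }
  tol <- snap * 10
  boundary <- nodes[, 1] < tol | nodes[, 1] > width - tol |
    nodes[, 2] < tol | nodes[, 2] > height - tol
  theta0 <- lapply(cells, function(l) turning_angles(nodes[l, , drop = FALSE]))
  ed <- .collect_edges(cells)
  walls <- tibble::tibble(a = ed$a, b = ed$b,
                          rest = .edge_lengths(nodes, ed$a, ed$b))
  t <- .new_tissue(nodes, cells, theta0, walls, boundary,
                   c(0, width, 0, height))
  .subdivide_walls(t, spacing)
}

#' Generate a lobed disc contour
#'
#' A disc of given radius with `n_lobes` radial protrusions of given length
#' and angular width, sampled at `n_points`. With `n_lobes = 0` this is a
#' plain circle. Useful for studying how lobes change (or fail to change) the
#' central open area: lengthening lobes leaves the LEC of the central disc
#' untouched while lobeyness grows.
#'
#' @param radius Disc radius (micrometres).
#' @param n_lobes Number of lobes (`>= 0`).
#' @param lobe_length Radial protrusion length beyond the disc.
#' @param lobe_width Angular width of each lobe as a fraction of its angular
#'   period, in `(0, 1)`.
#' @param n_points Number of contour samples.
#' @return A tibble with columns `x`, `y` (CCW contour).
#' @export
generate_lobed_disc <- function(radius = 10, n_lobes = 8, lobe_length = 5,
                                lobe_width = 0.35, n_points = 400) {
  stopifnot(radius > 0, n_lobes >= 0, lobe_length >= 0,
            lobe_width > 0, lobe_width < 1, n_points >= 12)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- rep(radius, n_points)
  if (n_lobes > 0 && lobe_length > 0) {
    # smooth bump profile per lobe period: raised cosine over the lobe arc
    phase <- (th * n_lobes / (2 * pi)) %% 1
    inl <- abs(phase - 0.5) < lobe_width / 2
    u <- (phase[inl] - 0.5) / lobe_width            # in (-1/2, 1/2)
    r[inl] <- radius + lobe_length * cos(pi * u)^2
  }
  normalize_contour(cbind(r * cos(th), r * sin(th)), check_simple = FALSE)
}

#' Named fixture contours
#'
#' Small closed shapes with hand-computable metrics, used throughout the test
#' suite and handy for exploring the metric definitions: a unit `square`, a
#' 5x1 `rectangle`, the `plus` cross (perimeter 12, hull perimeter
#' `4 + 4 * sqrt(2)`), a thin bent `boomerang` and a meandering `worm` (the
#' last two have hull solidity far above 1 at lobeyness near 1, the failure
#' mode of area-based convexity measures).
#'
#' @return A named list of tibbles with columns `x`, `y`.
#' @export
fixture_shapes <- function() {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  rectangle <- cbind(c(0, 5, 5, 0), c(0, 0, 1, 1))
  plus <- cbind(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
                c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
  # boomerang: circular arc band of small thickness spanning half a turn
  tha <- seq(-pi * 0.5, pi * 0.5, length.out = 60)
  boomerang <- rbind(cbind(10 * cos(tha), 10 * sin(tha)),
                     cbind(8.5 * cos(rev(tha)), 8.5 * sin(rev(tha))))
  # worm: sinusoidal midline with constant half-thickness
  s <- seq(0, 4 * pi, length.out = 80)
  mid <- cbind(s, 1.5 * sin(s))
  dmid <- cbind(1, 1.5 * cos(s))
  nrm <- cbind(-dmid[, 2], dmid[, 1]) / sqrt(rowSums(dmid^2))
  worm <- rbind(mid + 0.4 * nrm, (mid - 0.4 * nrm)[80:1, ])
  lapply(list(square = square, rectangle = rectangle, plus = plus,
              boomerang = boomerang, worm = worm),
         normalize_contour)
}
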