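# Independent oracles and shape generators used across the suite. These are
# deliberately written from first principles (not via package internals) so
# they can falsify the implementation.

# Regular n-gon with given circumradius, CCW, starting at angle phase.
regular_polygon <- function(n, r = 1, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  data.frame(x = r * cos(th), y = r * sin(th))
}

# Random star-shaped simple polygon: radius is a positive harmonic series in
# the polar angle. Always simple by construction.
random_star_polygon <- function(n_points = 80, n_harm = 4, amp = 0.45,
                                rng = NULL) {
  if (!is.null(rng)) set.seed(rng)
  th <- 2 * pi * (0:(n_points - 1)) / n_points
  r <- rep(1, n_points)
  for (k in seq_len(n_harm)) {
    r <- r + amp / k * runif(1, -1, 1) * cos(k * th + runif(1, 0, 2 * pi))
  }
  r <- pmax(r, 0.15)
  data.frame(x = r * cos(th), y = r * sin(th))
}

# Brute-force largest-empty-circle radius: maximum over an interior lattice
# of the minimum distance to the contour polyline.
grid_lec_radius <- function(poly, n_grid = 120) {
  m <- as.matrix(poly[, c("x", "y")])
  xs <- seq(min(m[, 1]), max(m[, 1]), length.out = n_grid)
  ys <- seq(min(m[, 2]), max(m[, 2]), length.out = n_grid)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  # even-odd test, written independently of the package
  n <- nrow(m)
  j <- c(n, 1:(n - 1))
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(n)) {
    xi <- m[i, 1]; yi <- m[i, 2]; xj <- m[j[i], 1]; yj <- m[j[i], 2]
    cr <- ((yi > g[, 2]) != (yj > g[, 2])) &
      (g[, 1] < (xj - xi) * (g[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr & !is.na(cr))
  }
  g <- g[inside, , drop = FALSE]
  if (nrow(g) == 0) return(0)
  best <- rep(Inf, nrow(g))
  nx <- m[c(2:n, 1), ]
  for (i in seq_len(n)) {
    ex <- nx[i, 1] - m[i, 1]; ey <- nx[i, 2] - m[i, 2]
    el2 <- max(ex^2 + ey^2, 1e-300)
    t <- pmin(1, pmax(0, ((g[, 1] - m[i, 1]) * ex + (g[, 2] - m[i, 2]) * ey) / el2))
    best <- pmin(best, (g[, 1] - m[i, 1] - t * ex)^2 + (g[, 2] - m[i, 2] - t * ey)^2)
  }
  sqrt(max(best))
}

# Shared fixture: the plus-shaped cross of the 3x3 unit grid minus corners.
plus_cross <- function() {
  data.frame(x = c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
             y = c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
}

# Small tissue used by mechanics/connections tests: cheap but non-trivial.
small_tissue <- function(n_cells = 9, seed = 3, spacing = 3) {
  generate_tissue(n_cells = n_cells, width = 30, height = 30,
                  spacing = spacing, seed = seed)
}

rigid_motion <- function(df, angle = 0.7, dx = 3, dy = -2, scale = 1) {
  m <- as.matrix(df[, c("x", "y")]) * scale
  data.frame(x = cos(angle) * m[, 1] - sin(angle) * m[, 2] + dx,
             y = sin(angle) * m[, 1] + cos(angle) * m[, 2] + dy)
}
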