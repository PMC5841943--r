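# Low-level 2D polygon geometry shared by the shape metrics and the tissue
# simulator. Contours are closed polylines stored as one point per row; the
# closing edge (last -> first) is implicit, orientation is counter-clockwise
# after normalize_contour(), coordinates are in micrometres.

# Coerce a contour given as matrix / data.frame (columns x, y or the first two
# numeric columns) to a plain numeric matrix; drops an explicit closing point
# and consecutive duplicates.
.ctr <- function(points, min_pts = 3L) {
  m <- .xy(points)
  if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) {
    m <- m[-nrow(m), , drop = FALSE]
  }
  if (nrow(m) > 1) {
    d <- rowSums(abs(m - m[c(2:nrow(m), 1), , drop = FALSE]))
    if (any(d < 1e-12)) m <- m[d >= 1e-12, , drop = FALSE]
  }
  if (nrow(m) < min_pts) {
    stop("contour needs at least ", min_pts, " distinct points", call. = FALSE)
  }
  m
}

.xy <- function(points) {
  if (is.matrix(points)) {
    m <- points[, 1:2, drop = FALSE]
  } else if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      m <- cbind(points$x, points$y)
    } else {
      num <- vapply(points, is.numeric, logical(1))
      m <- as.matrix(points[, which(num)[1:2], drop = FALSE])
    }
  } else {
    stop("contour must be a matrix or data frame of point coordinates",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop("contour coordinates must be finite", call. = FALSE)
  }
  unname(m)
}

.signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- x[c(2:nrow(m), 1)]; yn <- y[c(2:nrow(m), 1)]
  sum(x * yn - xn * y) / 2
}

.perim <- function(m) {
  d <- m[c(2:nrow(m), 1), , drop = FALSE] - m
  sum(sqrt(rowSums(d^2)))
}

# Even-odd (ray casting) point-in-polygon test, vectorized over query points.
# Points within `tol` of a polygon edge are classified as not inside, which is
# what the LEC circumcenter filter needs (boundary-touching candidates are
# discarded).
.pip <- function(pts, poly, tol = 0) {
  pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nx <- poly[c(2:n, 1), 1]; ny <- poly[c(2:n, 1), 2]
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(nrow(pts))
  for (i in seq_len(n)) {
    crosses <- ((y1[i] > py) != (ny[i] > py))
    if (any(crosses)) {
      xint <- x1[i] + (py[crosses] - y1[i]) * (nx[i] - x1[i]) / (ny[i] - y1[i])
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  if (tol > 0) {
    inside[.dist_to_boundary(pts, poly) < tol] <- FALSE
  }
  inside
}

# Minimum distance from each query point to the polygon outline.
.dist_to_boundary <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[c(2:n, 1), 1]; by <- poly[c(2:n, 1), 2]
  ex <- bx - ax; ey <- by - ay
  el2 <- pmax(ex^2 + ey^2, 1e-300)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    t <- pmin(1, pmax(0, ((pts[, 1] - ax[i]) * ex[i] +
                            (pts[, 2] - ay[i]) * ey[i]) / el2[i]))
    dx <- pts[, 1] - (ax[i] + t * ex[i])
    dy <- pts[, 2] - (ay[i] + t * ey[i])
    best <- pmin(best, dx^2 + dy^2)
  }
  sqrt(best)
}

# Proper segment-segment crossing test on all non-adjacent edge pairs.
.is_simple <- function(m) {
  n <- nrow(m)
  if (n < 3) return(FALSE)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  d1 <- o(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- o(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- o(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- o(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  !any(d1 != d2 & d3 != d4 & d1 != 0 & d2 != 0 & d3 != 0 & d4 != 0)
}

#' Normalize a cell contour
#'
#' Validates a closed contour and brings it into the package's canonical form:
#' consecutive duplicate points removed, an explicit closing point dropped, and
#' counter-clockwise orientation (positive signed area). All shape metrics
#' expect normalized contours; they call this themselves, so explicit use is
#' only needed when inspecting contours directly.
#'
#' @param points Contour points: a data frame with columns `x`, `y` (or a
#'   two-column matrix), one point per row, closing edge implicit.
#' @param check_simple Reject self-intersecting contours (default `TRUE`).
#' @return A tibble with columns `x`, `y`, oriented counter-clockwise.
#' @examples
#' sq <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0)) # clockwise
#' normalize_contour(sq)
#' @export
normalize_contour <- function(points, check_simple = TRUE) {
  m <- .ctr(points)
  a <- .signed_area(m)
  if (abs(a) < 1e-300) stop("degenerate contour: zero area", call. = FALSE)
  if (a < 0) m <- m[nrow(m):1, , drop = FALSE]
  if (check_simple && !.is_simple(m)) {
    stop("contour is self-intersecting", call. = FALSE)
  }
  tibble::tibble(x = m[, 1], y = m[, 2])
}

#' Polygon area (shoelace formula)
#'
#' @inheritParams normalize_contour
#' @return Area in square micrometres (positive).
#' @examples
#' polygon_area(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' @export
polygon_area <- function(points) {
  abs(.signed_area(.ctr(points)))
}

#' Polygon perimeter
#'
#' Sum of segment lengths including the implicit closing edge.
#'
#' @inheritParams normalize_contour
#' @return Perimeter in micrometres.
#' @export
polygon_perimeter <- function(points) {
  .perim(.ctr(points))
}

#' Convex hull of a contour
#'
#' The smallest convex polygon containing all contour points, returned
#' counter-clockwise. Collinear points along hull edges are dropped.
#'
#' @inheritParams normalize_contour
#' @return A tibble with columns `x`, `y` (hull vertices, CCW).
#' @export
convex_hull <- function(points) {
  m <- .ctr(points)
  h <- grDevices::chull(m[, 1], m[, 2]) # clockwise order
  if (length(h) < 3) stop("hull is degenerate (collinear points)", call. = FALSE)
  hm <- m[rev(h), , drop = FALSE]
  tibble::tibble(x = hm[, 1], y = hm[, 2])
}

#' Outward node normals of a contour
#'
#' The outward unit normal at each node, defined as the normalized bisector of
#' the outward normals of the two incident wall segments. For a CCW contour
#' the outward side is to the right of the direction of travel.
#'
#' @inheritParams normalize_contour
#' @return An `n x 2` matrix of unit vectors, one row per contour point.
#' @export
node_normals <- function(points) {
  m <- .ctr(points)
  if (.signed_area(m) < 0) m <- m[nrow(m):1, , drop = FALSE]
  n <- nrow(m)
  e <- m[c(2:n, 1), , drop = FALSE] - m           # edge i: node i -> i+1
  len <- sqrt(rowSums(e^2))
  if (any(len < 1e-300)) stop("zero-length contour segment", call. = FALSE)
  en <- cbind(e[, 2], -e[, 1]) / len              # outward edge normals (CCW)
  nn <- en + en[c(n, 1:(n - 1)), , drop = FALSE]  # edge i-1 and edge i at node i
  nl <- sqrt(rowSums(nn^2))
  # antiparallel edge normals (needle): fall back to the forward edge normal
  deg <- nl < 1e-9
  if (any(deg)) {
    nn[deg, ] <- en[deg, , drop = FALSE]
    nl[deg] <- 1
  }
  nn / nl
}

#' Outward normal at one contour node
#'
#' @inheritParams normalize_contour
#' @param i Node index (1-based).
#' @return A unit 2-vector.
#' @export
node_normal <- function(points, i) {
  nn <- node_normals(points)
  stopifnot(i >= 1, i <= nrow(nn))
  nn[i, ]
}

#' Signed turning (exterior) angles of a contour
#'
#' The signed exterior angle at each node of a CCW contour: positive where the
#' wall is locally convex, negative in indentations. Angles of a simple CCW
#' polygon sum to `2 * pi`.
#'
#' @inheritParams normalize_contour
#' @return Numeric vector of angles in radians, one per node.
#' @export
turning_angles <- function(points) {
  m <- .ctr(points)
  if (.signed_area(m) < 0) m <- m[nrow(m):1, , drop = FALSE]
  n <- nrow(m)
  u <- m - m[c(n, 1:(n - 1)), , drop = FALSE] # incoming edge at node i
  v <- m[c(2:n, 1), , drop = FALSE] - m       # outgoing edge at node i
  atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1], u[, 1] * v[, 1] + u[, 2] * v[, 2])
}

#' @rdname turning_angles
#' @param i Node index (1-based).
#' @export
turning_angle <- function(points, i) {
  ta <- turning_angles(points)
  stopifnot(i >= 1, i <= length(ta))
  ta[i]
}

# Total turning over a +/- window of nodes around each node: the curvature of
# the local wall arc, robust to how finely the wall is discretized (a lobe
# tip's turning stays concentrated no matter how many nodes describe it).
.window_turning <- function(m, window = 2L) {
  ta <- turning_angles(m)
  if (window <= 0) return(ta)
  n <- length(ta)
  k <- 2L * window + 1L
  idx <- outer(seq_len(n), -window:window, function(i, o) ((i + o - 1L) %% n) + 1L)
  rowSums(matrix(ta[idx], n, k))
}

#' Resample a contour to a maximum segment length
#'
#' Subdivides every segment longer than `spacing` into equal parts. Original
#' vertices are preserved, so the shape (and perimeter) is unchanged.
#'
#' @inheritParams normalize_contour
#' @param spacing Maximum segment length (micrometres), `> 0`.
#' @return A tibble with columns `x`, `y`.
#' @export
resample_contour <- function(points, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("`spacing` must be a single positive length", call. = FALSE)
  }
  m <- .ctr(points)
  n <- nrow(m)
  nxt <- m[c(2:n, 1), , drop = FALSE]
  len <- sqrt(rowSums((nxt - m)^2))
  k <- pmax(1L, ceiling(len / spacing))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- (seq_len(k[i]) - 1L) / k[i]
    out[[i]] <- cbind(m[i, 1] + t * (nxt[i, 1] - m[i, 1]),
                      m[i, 2] + t * (nxt[i, 2] - m[i, 2]))
  }
  r <- do.call(rbind, out)
  tibble::tibble(x = r[, 1], y = r[, 2])
}

# ---- Delaunay triangulation (Bowyer-Watson) --------------------------------
# No Delaunay library ships with this stack for R, and the triangulation is
# central to the LEC measure, so it is implemented here. Deterministic: a
# fixed-sequence symmetric-breaking jitter (1e-9 of the bounding-box scale)
# removes the exact collinearities of regularly sampled polygons.

.lcg_unif <- function(n, seed = 987654321) {
  s <- as.double(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (1103515245 * s + 12345) %% 2147483648
    out[i] <- s / 2147483648
  }
  out
}

.circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  bad <- abs(d) < 1e-300
  ux[bad] <- Inf; uy[bad] <- Inf
  r2 <- (ax - ux)^2 + (ay - uy)^2
  r2[bad] <- Inf
  list(x = ux, y = uy, r2 = r2)
}

# Returns list(tri = m x 3 vertex indices into `pts`, cx, cy, r2).
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points for a triangulation", call. = FALSE)
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-12)
  jit <- (matrix(.lcg_unif(2L * n), n, 2) - 0.5) * (1e-9 * scale)
  p <- pts + jit
  cx0 <- mean(range(p[, 1])); cy0 <- mean(range(p[, 2]))
  R <- 20 * scale + 1
  P <- rbind(c(cx0 - 3 * R, cy0 - R), c(cx0 + 3 * R, cy0 - R),
             c(cx0, cy0 + 3 * R), p)
  cap <- 8L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- ccy <- r2 <- numeric(cap)
  alive <- logical(cap)
  m <- 1L
  tri[1L, ] <- 1:3
  cc <- .circumcircle(P[1, 1], P[1, 2], P[2, 1], P[2, 2], P[3, 1], P[3, 2])
  ccx[1L] <- cc$x; ccy[1L] <- cc$y; r2[1L] <- cc$r2
  alive[1L] <- TRUE
  for (v in 4:(n + 3L)) {
    px <- P[v, 1]; py <- P[v, 2]
    act <- which(alive[seq_len(m)])
    bad <- act[(px - ccx[act])^2 + (py - ccy[act])^2 <= r2[act] * (1 + 1e-12)]
    if (length(bad) == 0L) { # numerically outside everything; force nearest
      d2 <- (px - ccx[act])^2 + (py - ccy[act])^2 - r2[act]
      bad <- act[which.min(d2)]
    }
    ea <- c(tri[bad, 1], tri[bad, 2], tri[bad, 3])
    eb <- c(tri[bad, 2], tri[bad, 3], tri[bad, 1])
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- lo * (n + 4) + hi
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    ka <- lo[once]; kb <- hi[once]
    nnew <- length(ka)
    if (m + nnew > cap) {
      cap2 <- max(2L * cap, m + nnew)
      tri <- rbind(tri, matrix(NA_integer_, cap2 - cap, 3))
      length(ccx) <- cap2; length(ccy) <- cap2; length(r2) <- cap2
      length(alive) <- cap2
      alive[is.na(alive)] <- FALSE
      cap <- cap2
    }
    if (nnew > 0L) {
      rows <- m + seq_len(nnew)
      tri[rows, 1] <- ka; tri[rows, 2] <- kb; tri[rows, 3] <- v
      cc <- .circumcircle(P[ka, 1], P[ka, 2], P[kb, 1], P[kb, 2], px, py)
      ccx[rows] <- cc$x; ccy[rows] <- cc$y; r2[rows] <- cc$r2
      alive[rows] <- TRUE
      m <- m + nnew
    }
  }
  keep <- which(alive[seq_len(m)] & tri[seq_len(m), 1] > 3L &
                  tri[seq_len(m), 2] > 3L & tri[seq_len(m), 3] > 3L &
                  is.finite(r2[seq_len(m)]))
  list(tri = tri[keep, , drop = FALSE] - 3L,
       cx = ccx[keep], cy = ccy[keep], r2 = r2[keep])
}

#' Largest empty circle inside a cell contour
#'
#' The radius and center of the biggest circle that fits inside the contour --
#' the package's geometric proxy for turgor-induced wall stress. The contour
#' is resampled to a maximum spacing, its points are Delaunay-triangulated,
#' and the largest circumscribed circle whose circumcenter lies inside the
#' polygon is returned. Candidates whose center falls on or outside the
#' boundary are ignored; with dense sampling the boundary case carries no
#' information.
#'
#' @inheritParams normalize_contour
#' @param spacing Maximum contour sampling interval before triangulation.
#'   Default: 1/100 of the bounding-box diagonal.
#' @return A one-row tibble with columns `radius`, `x`, `y` (center).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' largest_empty_circle(data.frame(x = cos(th), y = sin(th)))
#' @export
largest_empty_circle <- function(points, spacing = NULL) {
  ctr <- normalize_contour(points, check_simple = FALSE)
  m <- cbind(ctr$x, ctr$y)
  if (is.null(spacing)) {
    diag <- sqrt(diff(range(m[, 1]))^2 + diff(range(m[, 2]))^2)
    spacing <- diag / 100
  }
  rs <- resample_contour(m, spacing)
  pm <- cbind(rs$x, rs$y)
  dt <- .delaunay(pm)
  if (nrow(dt$tri) == 0) stop("degenerate contour: no interior triangles", call. = FALSE)
  inside <- .pip(cbind(dt$cx, dt$cy), pm)
  if (!any(inside)) stop("no circumcenter lies inside the contour", call. = FALSE)
  i <- which(inside)[which.max(dt$r2[inside])]
  tibble::tibble(radius = sqrt(dt$r2[i]), x = dt$cx[i], y = dt$cy[i])
}

#' Project a 3D contour onto its principal plane
#'
#' Cell contours extracted from curved surfaces are 3D polylines. This projects
#' the points onto the plane orthogonal to the direction of minimal variance
#' (the third principal component), passing through the contour centroid, and
#' expresses them in the orthonormal in-plane basis given by the first two
#' principal directions. For exactly planar contours the projection is an
#' isometry.
#'
#' @param points A data frame with columns `x`, `y`, `z` (or a three-column
#'   matrix) of 3D contour points.
#' @return A tibble with columns `x`, `y`: the projected 2D contour, oriented
#'   counter-clockwise.
#' @export
pca_project <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points))) {
      stop("3D contour needs columns x, y, z", call. = FALSE)
    }
    m <- cbind(points$x, points$y, points$z)
  } else {
    m <- as.matrix(points)[, 1:3, drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least 3 points", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-12) stop("collinear points: projection plane undefined", call. = FALSE)
  xy <- pc$x[, 1:2, drop = FALSE]
  normalize_contour(xy, check_simple = FALSE)
}
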