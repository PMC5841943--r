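# Placement and retirement of transversal springs -- the stress-response rule
# that generates lobes. Each eligible wall node connects to the closest node
# across its cell whose chord (i) separates the endpoints by at least s_min
# contour nodes, (ii) lies within theta_micro of the outward normals at both
# ends, (iii) stays inside the cell, and (iv) avoids locally convex wall
# regions (unless spk1_mode). The reference length is max(distance,
# min_micro), so a connection only pulls once the span exceeds the target.

#' Force of a tension-only transversal spring
#'
#' Linear in extension beyond the reference length and exactly zero under
#' compression, matching the high tensile but negligible compressive strength
#' of cellulose fibrils.
#'
#' @param current_length Current chord length.
#' @param ref_length Reference (rest) length fixed at placement.
#' @param k_m Spring stiffness.
#' @return Contracting force magnitude (0 when slack). Vectorized.
#' @examples
#' spring_force(12, ref_length = 10, k_m = 1) # 2
#' spring_force(5, ref_length = 10, k_m = 1)  # 0: inactive when compressed
#' @export
spring_force <- function(current_length, ref_length, k_m = 1) {
  stopifnot(all(current_length >= 0), all(ref_length > 0), k_m >= 0)
  k_m * pmax(0, current_length - ref_length)
}

# Does the chord between loop nodes i and j stay inside the cell polygon?
# Tests three interior sample points plus proper crossings against all
# non-incident edges.
.chord_inside <- function(m, i, j) {
  n <- nrow(m)
  a <- m[i, ]; b <- m[j, ]
  for (f in c(0.25, 0.5, 0.75)) {
    if (!.pip(rbind(a + f * (b - a)), m)) return(FALSE)
  }
  nxt <- function(k) if (k == n) 1L else k + 1L
  prv <- function(k) if (k == 1L) n else k - 1L
  skip <- c(i, prv(i), j, prv(j))
  e1 <- m
  e2 <- m[c(2:n, 1), , drop = FALSE]
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  keep <- setdiff(seq_len(n), skip)
  if (length(keep) == 0) return(TRUE)
  d1 <- o(a[1], a[2], b[1], b[2], e1[keep, 1], e1[keep, 2])
  d2 <- o(a[1], a[2], b[1], b[2], e2[keep, 1], e2[keep, 2])
  d3 <- o(e1[keep, 1], e1[keep, 2], e2[keep, 1], e2[keep, 2], a[1], a[2])
  d4 <- o(e1[keep, 1], e1[keep, 2], e2[keep, 1], e2[keep, 2], b[1], b[2])
  !any(d1 != d2 & d3 != d4 & d1 != 0 & d2 != 0 & d3 != 0 & d4 != 0)
}

#' Place transversal springs across all cells
#'
#' Discards every existing spring and reassigns connections from the current
#' cell shapes (the microtubule array is highly dynamic; reassignment reflects
#' the new geometry). Deterministic given tissue state and parameters; ties
#' between equidistant partners break to the lowest node index. Nodes with no
#' admissible partner simply receive no spring.
#'
#' As cells deform, this rule makes indentations attract connections (an
#' exposed concave tip is the closest node for many nodes across the cell)
#' while convex lobe tips lose them -- the emergent polarity that deepens
#' lobes under isotropic growth.
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object.
#' @return The tissue with a fresh `springs` table.
#' @export
place_connections <- function(t, p) {
  stopifnot(inherits(t, "tissue"))
  cos_min <- cos(p$theta_micro)
  out <- vector("list", length(t$cells))
  for (ci in seq_along(t$cells)) {
    l <- t$cells[[ci]]
    n <- length(l)
    if (n < 2L * p$s_min) next
    m <- t$nodes[l, , drop = FALSE]
    nrm <- node_normals(m)
    eligible <- if (p$spk1_mode) rep(TRUE, n) else
      .window_turning(m, p$convex_window) <= p$kappa_convex
    if (!any(eligible)) next
    dxm <- outer(m[, 1], m[, 1], function(xa, xb) xb - xa) # [a,b] = b - a
    dym <- outer(m[, 2], m[, 2], function(ya, yb) yb - ya)
    lm <- sqrt(dxm^2 + dym^2)
    lm[lm < 1e-300] <- 1e-300
    # a chord across the cell leaves each wall node along its inward normal
    ca <- -(dxm * nrm[, 1] + dym * nrm[, 2]) / lm           # cone at a
    cb <- (dxm * t(matrix(nrm[, 1], n, n)) +
             dym * t(matrix(nrm[, 2], n, n))) / lm          # cone at b
    idx <- seq_len(n)
    sep <- abs(outer(idx, idx, "-"))
    sep <- pmin(sep, n - sep)
    cand <- sep >= p$s_min & ca >= cos_min & cb >= cos_min &
      outer(eligible, eligible, "&")
    if (!any(cand)) next
    pa <- integer(0); pb <- integer(0); pr <- double(0)
    for (a in which(rowSums(cand) > 0)) {
      bs <- which(cand[a, ])
      bs <- bs[order(lm[a, bs], bs)]
      for (b in bs) {
        if (.chord_inside(m, a, b)) {
          pa <- c(pa, l[a]); pb <- c(pb, l[b])
          pr <- c(pr, max(lm[a, b], p$min_micro))
          break
        }
      }
    }
    if (length(pa) > 0) {
      key <- .wall_key(pa, pb)
      first <- !duplicated(key)
      out[[ci]] <- tibble::tibble(cell = ci, a = pa[first], b = pb[first],
                                  ref = pr[first])
    }
  }
  t$springs <- dplyr::bind_rows(out)
  if (nrow(t$springs) == 0) {
    t$springs <- tibble::tibble(cell = integer(), a = integer(),
                                b = integer(), ref = double())
  }
  t
}

#' Current state of the transversal springs
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object (for `k_m`).
#' @return A tibble with one row per spring: `cell`, `a`, `b`, `ref`,
#'   `length` (current chord length), `force` and `active`.
#' @export
spring_state <- function(t, p) {
  stopifnot(inherits(t, "tissue"))
  s <- t$springs
  if (nrow(s) == 0) {
    return(tibble::tibble(cell = integer(), a = integer(), b = integer(),
                          ref = double(), length = double(), force = double(),
                          active = logical()))
  }
  len <- .edge_lengths(t$nodes, s$a, s$b)
  tibble::tibble(cell = s$cell, a = s$a, b = s$b, ref = s$ref, length = len,
                 force = spring_force(len, s$ref, p$k_m),
                 active = len > s$ref)
}
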