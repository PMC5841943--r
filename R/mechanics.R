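# Mechanical equilibrium of the spring-hinge network.
#
# Energy terms (see sim_params() for stiffness semantics):
#   walls    0.5 * k_s * (l - l0)^2 / l0        per segment (strain-based, so
#                                               subdividing a wall leaves its
#                                               mechanics unchanged)
#   hinges   0.5 * k_b * (phi - phi0)^2         per node per owning cell,
#                                               phi = signed turning angle
#   springs  0.5 * k_m * max(0, l - ref)^2      tension-only transversal
#
# Forces are analytic gradients of this energy (verified against central
# finite differences in the test suite). Tissue-outline nodes are pinned at
# their post-growth positions: tissue-scale growth is imposed, so the outline
# follows it and the interior relaxes against it.
#
# Layout: node coordinates are handled as split vectors (all x, then all y);
# per-element gradient contributions are scattered to nodes through a sparse
# incidence matrix built once per equilibration, which keeps the inner
# minimizer loop allocation-light.

# Flatten mechanics into index arrays once per equilibration, plus the sparse
# map from per-element contribution slots to node coordinates.
.mech_arrays <- function(t) {
  n <- nrow(t$nodes)
  hin_a <- integer(0); hin_b <- integer(0); hin_c <- integer(0)
  phi0 <- double(0)
  for (ci in seq_along(t$cells)) {
    l <- t$cells[[ci]]
    k <- length(l)
    hin_a <- c(hin_a, l[c(k, 1:(k - 1))])
    hin_b <- c(hin_b, l)
    hin_c <- c(hin_c, l[c(2:k, 1)])
    phi0 <- c(phi0, t$theta0[[ci]])
  }
  mech <- list(n = n, ea = t$walls$a, eb = t$walls$b, l0 = t$walls$rest,
               ha = hin_a, hb = hin_b, hc = hin_c, phi0 = phi0,
               sa = t$springs$a, sb = t$springs$b, sref = t$springs$ref)
  ne <- length(mech$ea); nh <- length(hin_a); ns <- length(mech$sa)
  # contribution slots, in the order .grad_vals() emits them:
  #   edges:  vx (ne), vy (ne)           coeff -1 at a, +1 at b
  #   hinges: dux, duy, dvx, dvy (nh)    u = b - a, v = c - b
  #   springs: vx (ns), vy (ns)          coeff -1 at a, +1 at b
  off <- 0L
  ii <- integer(0); jj <- integer(0); xx <- double(0)
  put <- function(rows, cols, vals) {
    ii <<- c(ii, rows); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }
  if (ne > 0) {
    se <- seq_len(ne)
    put(mech$ea, off + se, rep(-1, ne));  put(mech$eb, off + se, rep(1, ne))
    put(n + mech$ea, off + ne + se, rep(-1, ne))
    put(n + mech$eb, off + ne + se, rep(1, ne))
    off <- off + 2L * ne
  }
  if (nh > 0) {
    sh <- seq_len(nh); one <- rep(1, nh)
    put(hin_a, off + sh, -one); put(hin_b, off + sh, one)          # dux
    put(n + hin_a, off + nh + sh, -one); put(n + hin_b, off + nh + sh, one)
    put(hin_b, off + 2L * nh + sh, -one); put(hin_c, off + 2L * nh + sh, one) # dvx
    put(n + hin_b, off + 3L * nh + sh, -one)
    put(n + hin_c, off + 3L * nh + sh, one)
    off <- off + 4L * nh
  }
  if (ns > 0) {
    ss <- seq_len(ns)
    put(mech$sa, off + ss, rep(-1, ns)); put(mech$sb, off + ss, rep(1, ns))
    put(n + mech$sa, off + ns + ss, rep(-1, ns))
    put(n + mech$sb, off + ns + ss, rep(1, ns))
    off <- off + 2L * ns
  }
  mech$scatter <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                       dims = c(2L * n, off))
  mech
}

.energy_terms <- function(x, y, mech, p) {
  dx <- x[mech$eb] - x[mech$ea]
  dy <- y[mech$eb] - y[mech$ea]
  l <- sqrt(dx^2 + dy^2)
  e_wall <- 0.5 * p$k_s * sum((l - mech$l0)^2 / mech$l0)
  ux <- x[mech$hb] - x[mech$ha]; uy <- y[mech$hb] - y[mech$ha]
  vx <- x[mech$hc] - x[mech$hb]; vy <- y[mech$hc] - y[mech$hb]
  phi <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  # deviation wrapped to (-pi, pi]: the hinge penalty is continuous even
  # when a fold passes through a straight-back configuration
  dphi <- (phi - mech$phi0 + pi) %% (2 * pi) - pi
  e_bend <- 0.5 * p$k_b * sum(dphi^2)
  e_spring <- 0
  if (length(mech$sa) > 0) {
    sdx <- x[mech$sb] - x[mech$sa]; sdy <- y[mech$sb] - y[mech$sa]
    e_spring <- 0.5 * p$k_m * sum(pmax(0, sqrt(sdx^2 + sdy^2) - mech$sref)^2)
  }
  c(wall = e_wall, bend = e_bend, spring = e_spring)
}

# Per-element gradient contribution values, in the slot order the scatter
# matrix expects; the full gradient is scatter %*% vals.
.grad_vals <- function(x, y, mech, p) {
  dx <- x[mech$eb] - x[mech$ea]
  dy <- y[mech$eb] - y[mech$ea]
  l <- pmax(sqrt(dx^2 + dy^2), 1e-300)
  f <- p$k_s * (l - mech$l0) / mech$l0
  ev <- c(f * dx / l, f * dy / l)
  ux <- x[mech$hb] - x[mech$ha]; uy <- y[mech$hb] - y[mech$ha]
  vx <- x[mech$hc] - x[mech$hb]; vy <- y[mech$hc] - y[mech$hb]
  cr <- ux * vy - uy * vx
  dt <- ux * vx + uy * vy
  s2 <- pmax(ux^2 + uy^2, 1e-300) * pmax(vx^2 + vy^2, 1e-300)
  dphi <- (atan2(cr, dt) - mech$phi0 + pi) %% (2 * pi) - pi
  w <- p$k_b * dphi / s2
  hv <- c(w * (dt * vy - cr * vx), w * (-dt * vx - cr * vy),
          w * (-dt * uy - cr * ux), w * (dt * ux - cr * uy))
  sv <- double(0)
  if (length(mech$sa) > 0) {
    sdx <- x[mech$sb] - x[mech$sa]; sdy <- y[mech$sb] - y[mech$sa]
    sl <- pmax(sqrt(sdx^2 + sdy^2), 1e-300)
    fs <- p$k_m * pmax(0, sl - mech$sref)
    sv <- c(fs * sdx / sl, fs * sdy / sl)
  }
  c(ev, hv, sv)
}

# Gradient of total energy w.r.t. c(x, y); length 2n.
.energy_gradient <- function(x, y, mech, p) {
  as.numeric(mech$scatter %*% .grad_vals(x, y, mech, p))
}

#' Total elastic energy of a tissue
#'
#' Sum of wall stretching, hinge bending and (tension-only) transversal
#' spring energies at the current node positions. Zero for a tissue at its
#' rest configuration with slack springs; invariant under rigid motions.
#'
#' @param t A `tissue` object.
#' @param p A [sim_params()] object.
#' @param by_term Return the three components instead of their sum.
#' @return Energy (arbitrary units), or a named length-3 vector if
#'   `by_term = TRUE`.
#' @export
total_energy <- function(t, p, by_term = FALSE) {
  stopifnot(inherits(t, "tissue"))
  if (anyNA(t$nodes) || any(!is.finite(t$nodes))) {
    stop("non-finite node positions", call. = FALSE)
  }
  mech <- .mech_arrays(t)
  e <- .energy_terms(t$nodes[, 1], t$nodes[, 2], mech, p)
  if (by_term) e else sum(e)
}

# Net force (negative gradient) per node; n x 2 matrix.
.node_forces <- function(t, p) {
  mech <- .mech_arrays(t)
  g <- .energy_gradient(t$nodes[, 1], t$nodes[, 2], mech, p)
  n <- nrow(t$nodes)
  -cbind(g[seq_len(n)], g[n + seq_len(n)])
}

#' Relax a tissue to mechanical equilibrium
#'
#' Minimizes the total elastic energy over the interior (non-outline) node
#' positions with the tissue outline pinned, using a quasi-Newton minimizer
#' with analytic gradients, restarted until the largest net force on any free
#' node drops below `p$solver_tol` or `p$max_iter` iterations are spent.
#' Energy never increases (the incoming configuration is kept if the
#' minimizer cannot improve it); topology, wall rest lengths and springs are
#' untouched.
#'
#' @param t A `tissue` object (outline nodes are those flagged in
#'   `t$boundary`).
#' @param p A [sim_params()] object.
#' @return The relaxed `tissue`, with attributes `residual` (final max force
#'   norm), `iterations` and `converged`. Non-convergence within `max_iter`
#'   raises a warning, never a silent acceptance.
#' @export
equilibrate <- function(t, p) {
  stopifnot(inherits(t, "tissue"))
  mech <- .mech_arrays(t)
  n <- nrow(t$nodes)
  free <- which(!t$boundary)
  x <- t$nodes[, 1]; y <- t$nodes[, 2]
  resid <- function(x, y) {
    if (length(free) == 0) return(0)
    g <- .energy_gradient(x, y, mech, p)
    max(sqrt(g[free]^2 + g[n + free]^2))
  }
  e0 <- sum(.energy_terms(x, y, mech, p))
  r <- resid(x, y)
  iters <- 0L
  if (length(free) > 0 && r > p$solver_tol) {
    nf <- length(free)
    fn <- function(par) {
      x[free] <- par[seq_len(nf)]; y[free] <- par[nf + seq_len(nf)]
      v <- sum(.energy_terms(x, y, mech, p))
      if (is.finite(v)) v else 1e30 # line search backs off runaway trial steps
    }
    gr <- function(par) {
      x[free] <- par[seq_len(nf)]; y[free] <- par[nf + seq_len(nf)]
      g <- .energy_gradient(x, y, mech, p)
      g[!is.finite(g)] <- 0
      c(g[free], g[n + free])
    }
    par <- c(x[free], y[free])
    budget <- p$max_iter
    ecur <- e0
    while (r > p$solver_tol && budget > 0L) {
      res <- tryCatch(
        stats::optim(par, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = budget, factr = 1e1)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value) || anyNA(res$par)) break
      iters <- iters + res$counts[[1]]
      budget <- budget - max(1L, res$counts[[1]])
      if (res$value <= ecur + 1e-12 * max(1, abs(ecur))) {
        par <- res$par
        ecur <- res$value
        x[free] <- par[seq_len(nf)]; y[free] <- par[nf + seq_len(nf)]
        rn <- resid(x, y)
        if (rn >= r * (1 - 1e-9) && rn > p$solver_tol) { r <- rn; break }
        r <- rn
      } else break
    }
  }
  if (r > p$solver_tol) {
    warning(sprintf("equilibrate: residual %.3g > tol %.3g after %d iterations",
                    r, p$solver_tol, iters), call. = FALSE)
  }
  t$nodes <- cbind(x, y, deparse.level = 0)
  attr(t, "residual") <- r
  attr(t, "iterations") <- iters
  attr(t, "converged") <- r <= p$solver_tol
  t
}
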