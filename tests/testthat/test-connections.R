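# Single-cell tissue built directly from a contour: placement rules can then
# be probed on controlled geometries.
single_cell_tissue <- function(contour, spacing = 2) {
  rs <- resample_contour(contour, spacing)
  nodes <- cbind(rs$x, rs$y)
  cells <- list(seq_len(nrow(nodes)))
  theta0 <- list(turning_angles(nodes))
  ed <- puzzlecell:::.collect_edges(cells)
  walls <- tibble::tibble(a = ed$a, b = ed$b,
                          rest = puzzlecell:::.edge_lengths(nodes, ed$a, ed$b))
  puzzlecell:::.new_tissue(nodes, cells, theta0, walls,
                           rep(FALSE, nrow(nodes)),
                           c(range(nodes[, 1]), range(nodes[, 2])))
}

test_that("spring force is one-sided and linear in extension", {
  expect_equal(spring_force(10, ref_length = 10, k_m = 3), 0)
  expect_equal(spring_force(5, ref_length = 10, k_m = 3), 0) # compressed: inactive
  expect_equal(spring_force(12, ref_length = 10, k_m = 1), 2)
  expect_equal(spring_force(1.2 * 10, 10, 1), 0.2 * 10, tolerance = 1e-12)
})

test_that("parallel walls pair up straight across the cell", {
  rect <- data.frame(x = c(0, 30, 30, 0), y = c(0, 0, 8, 8))
  t0 <- single_cell_tissue(rect, spacing = 2)
  p <- sim_params(min_micro = 5, s_min = 3)
  t1 <- place_connections(t0, p)
  s <- spring_state(t1, p)
  expect_gte(nrow(s), 8)
  # chords are vertical spans of length 8 (long-wall nodes to their opposites)
  vert <- abs(t1$nodes[s$a, 1] - t1$nodes[s$b, 1]) < 1e-6
  expect_true(all(vert))
  expect_equal(unique(round(s$length, 9)), 8)
  # d > min_micro so ref = d: active only on further stretch
  expect_equal(s$ref, rep(8, nrow(s)))
  expect_false(any(s$active))
})

test_that("convex lobe tips are excluded from connections", {
  lobed <- generate_lobed_disc(radius = 10, n_lobes = 3, lobe_length = 7,
                               lobe_width = 0.3, n_points = 120)
  t0 <- single_cell_tissue(lobed, spacing = 1.5)
  p <- sim_params(min_micro = 5, s_min = 3)
  t1 <- place_connections(t0, p)
  m <- t0$nodes[t0$cells[[1]], ]
  wt <- puzzlecell:::.window_turning(m, p$convex_window)
  tips <- t0$cells[[1]][wt > p$kappa_convex]
  expect_gt(length(tips), 0)
  expect_gt(nrow(t1$springs), 0)
  expect_false(any(t1$springs$a %in% tips | t1$springs$b %in% tips))
  # spk1 mode removes the inhibition: tips may now carry springs
  t2 <- place_connections(t0, sim_params(min_micro = 5, s_min = 3,
                                         spk1_mode = TRUE))
  expect_gt(nrow(t2$springs), nrow(t1$springs))
})

test_that("small cells get slack springs with ref = min_micro", {
  small <- generate_lobed_disc(radius = 5, n_lobes = 0, n_points = 48)
  t0 <- single_cell_tissue(small, spacing = 1)
  # inhibition off: a small disc is convex everywhere, and this test probes
  # the reference-length rule, not eligibility
  p <- sim_params(min_micro = 15, s_min = 5, kappa_convex = 10)
  t1 <- place_connections(t0, p)
  s <- spring_state(t1, p)
  expect_gt(nrow(s), 0)
  expect_true(all(s$ref == 15))
  expect_true(all(s$length < s$ref))
  expect_false(any(s$active))
  expect_equal(sum(s$force), 0)
})

test_that("no spring leaves its cell or crosses the boundary", {
  # a deep C-shape: naive closest-opposite chords would cut across the mouth
  th <- seq(0.4, 2 * pi - 0.4, length.out = 60)
  cshape <- rbind(cbind(12 * cos(th), 12 * sin(th)),
                  cbind(6 * cos(rev(th)), 6 * sin(rev(th))))
  t0 <- single_cell_tissue(as.data.frame(`colnames<-`(cshape, c("x", "y"))),
                           spacing = 1.5)
  p <- sim_params(min_micro = 3, s_min = 3, kappa_convex = 10)
  t1 <- place_connections(t0, p)
  s <- t1$springs
  expect_gt(nrow(s), 0)
  m <- t0$nodes[t0$cells[[1]], ]
  for (i in seq_len(nrow(s))) {
    mid <- (t0$nodes[s$a[i], ] + t0$nodes[s$b[i], ]) / 2
    expect_true(puzzlecell:::.pip(rbind(mid), m))
  }
})

test_that("placement is deterministic and refreshes old springs", {
  t0 <- small_tissue()
  # enlarge the template so spans exceed the target and walls flatten
  t0$nodes <- t0$nodes * 2.2
  t0$walls$rest <- t0$walls$rest * 2.2
  t0$bbox <- t0$bbox * 2.2
  p <- sim_params(min_micro = 10, kappa_convex = 10)
  t1 <- place_connections(t0, p)
  t2 <- place_connections(t0, p)
  expect_identical(t1$springs, t2$springs)
  expect_gt(nrow(t1$springs), 0)
  # re-placement discards, never accumulates
  t3 <- place_connections(t1, p)
  expect_identical(t3$springs, t1$springs)
  # all springs connect nodes of the same cell
  for (i in seq_len(nrow(t1$springs))) {
    l <- t1$cells[[t1$springs$cell[i]]]
    expect_true(all(c(t1$springs$a[i], t1$springs$b[i]) %in% l))
  }
})
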