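test_that("normalize_contour orients CCW, deduplicates and rejects bad input", {
  cw_sq <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0))
  out <- normalize_contour(cw_sq)
  expect_equal(nrow(out), 4)
  expect_gt(puzzlecell:::.signed_area(cbind(out$x, out$y)), 0)

  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  expect_equal(as.data.frame(normalize_contour(tri)), tri)

  dup <- data.frame(x = c(0, 1, 1, 1, 0), y = c(0, 0, 0, 1, 1))
  expect_equal(nrow(normalize_contour(dup)), 4)

  expect_error(normalize_contour(data.frame(x = c(0, 1), y = c(0, 0))), "3 distinct")
  crossed <- data.frame(x = c(0, 4, 1, 3), y = c(0, 0, 2, 2))
  expect_error(normalize_contour(crossed), "self-intersecting")
})

test_that("area and perimeter match closed forms", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  tri345 <- data.frame(x = c(0, 3, 0), y = c(0, 0, 4))
  expect_equal(polygon_area(tri345), 6)
  rect <- data.frame(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_perimeter(rect), 12)
  ngon <- regular_polygon(200)
  expect_equal(polygon_area(ngon), pi, tolerance = 1e-3)
  expect_equal(polygon_perimeter(ngon), 2 * pi, tolerance = 1e-3)
})

test_that("convex hull is convex, idempotent and contains its input", {
  hexa <- regular_polygon(6)
  h <- convex_hull(hexa)
  expect_equal(nrow(h), 6) # convex input: vertex set preserved
  expect_equal(sort(h$x), sort(hexa$x))

  h1 <- convex_hull(plus_cross())
  expect_equal(nrow(h1), 8)
  expect_equal(polygon_perimeter(h1), 4 + 4 * sqrt(2))
  expect_equal(polygon_area(h1), 7)
  h2 <- convex_hull(h1)
  expect_equal(polygon_perimeter(h2), polygon_perimeter(h1))

  for (s in 1:5) {
    p <- random_star_polygon(60, rng = s)
    expect_lte(polygon_perimeter(convex_hull(p)), polygon_perimeter(p) + 1e-9)
    expect_true(all(puzzlecell:::.window_turning(
      puzzlecell:::.ctr(convex_hull(p)), 0) > -1e-9))
  }
})

test_that("node normals point outward and match analytic directions", {
  sq <- resample_contour(data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)), 1)
  # midpoint of the bottom edge
  i <- which(sq$x == 1 & sq$y == 0)
  expect_equal(node_normal(sq, i), c(0, -1))
  j <- which(sq$x == 0 & sq$y == 0)
  expect_equal(node_normal(sq, j), c(-sqrt(2) / 2, -sqrt(2) / 2))

  circ <- regular_polygon(300)
  nn <- node_normals(circ)
  radial <- cbind(circ$x, circ$y)
  ang <- acos(pmin(1, rowSums(nn * radial)))
  expect_lt(max(ang), 1 * pi / 180)
})

test_that("turning angles carry the convexity sign and sum to 2*pi", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(turning_angle(sq, 2), pi / 2)
  fine <- resample_contour(sq, 0.25)
  ta <- turning_angles(fine)
  expect_equal(sum(abs(ta) < 1e-12), nrow(fine) - 4) # straight-wall nodes
  expect_equal(sum(ta), 2 * pi)
  # deep indentation: negative turning at the notch tip
  notch <- data.frame(x = c(0, 4, 4, 2.05, 2, 1.95, 0),
                      y = c(0, 0, 3, 3, 0.5, 3, 3))
  ta2 <- turning_angles(notch)
  expect_lt(ta2[5], 0)
  for (s in 1:5) {
    expect_equal(sum(turning_angles(random_star_polygon(70, rng = s))), 2 * pi)
  }
})

test_that("resample_contour preserves vertices and perimeter", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  r <- resample_contour(sq, 0.25)
  expect_equal(nrow(r), 16)
  expect_equal(polygon_perimeter(r), 4, tolerance = 1e-12)
  expect_equal(nrow(resample_contour(r, 0.3)), 16) # already fine: unchanged
  expect_error(resample_contour(sq, 0), "positive")
  star <- random_star_polygon(40, rng = 7)
  expect_equal(polygon_perimeter(resample_contour(star, 0.03)),
               polygon_perimeter(star), tolerance = 1e-9)
})

test_that("largest empty circle matches closed forms", {
  circ <- regular_polygon(200)
  lec <- largest_empty_circle(circ)
  expect_equal(lec$radius, 1, tolerance = 5e-3)
  expect_equal(abs(lec$x) + abs(lec$y), 0, tolerance = 1e-2)

  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(largest_empty_circle(sq, spacing = 0.02)$radius, 0.5,
               tolerance = 5e-3)
  rect <- data.frame(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1))
  expect_equal(largest_empty_circle(rect)$radius, 0.5, tolerance = 5e-3)
})

test_that("largest empty circle agrees with the grid oracle and is empty", {
  for (s in 1:12) {
    p <- random_star_polygon(70, rng = s)
    lec <- largest_empty_circle(p, spacing = 0.05)
    oracle <- grid_lec_radius(p, n_grid = 110)
    expect_equal(lec$radius, oracle, tolerance = 0.02)
    # center inside, open disc empty of the contour samples the LEC saw
    rs <- resample_contour(p, 0.05)
    expect_true(puzzlecell:::.pip(cbind(lec$x, lec$y), cbind(rs$x, rs$y)))
    d <- sqrt((rs$x - lec$x)^2 + (rs$y - lec$y)^2)
    expect_gte(min(d), lec$radius * (1 - 1e-6))
  }
})

test_that("pca projection is an isometry for planar contours", {
  star <- random_star_polygon(50, rng = 2)
  flat <- data.frame(x = star$x, y = star$y, z = 3)
  pr <- pca_project(flat)
  expect_equal(polygon_perimeter(pr), polygon_perimeter(star), tolerance = 1e-9)
  d0 <- dist(cbind(star$x, star$y))
  expect_equal(as.numeric(dist(cbind(pr$x, pr$y))), as.numeric(d0),
               tolerance = 1e-9)

  # rotate 30 degrees about the x axis: still planar, perimeter preserved
  a <- pi / 6
  rot <- data.frame(x = star$x, y = star$y * cos(a), z = star$y * sin(a))
  expect_equal(polygon_perimeter(pca_project(rot)), polygon_perimeter(star),
               tolerance = 1e-9)

  # small out-of-plane noise: projected perimeter below 3D polyline length
  set.seed(9)
  noisy <- data.frame(x = star$x, y = star$y, z = rnorm(nrow(star), 0, 0.02))
  m3 <- as.matrix(noisy)
  len3 <- sum(sqrt(rowSums((m3[c(2:nrow(m3), 1), ] - m3)^2)))
  expect_lte(polygon_perimeter(pca_project(noisy)), len3)

  expect_error(pca_project(data.frame(x = 1:5, y = 1:5, z = 1:5)), "collinear")
})
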