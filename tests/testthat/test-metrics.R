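test_that("lobeyness is 1 for convex shapes and grows with lobing", {
  expect_equal(lobeyness(regular_polygon(6)), 1, tolerance = 1e-12)
  expect_equal(lobeyness(resample_contour(regular_polygon(7), 0.01)), 1,
               tolerance = 1e-9)
  expect_equal(lobeyness(plus_cross()), 12 / (4 + 4 * sqrt(2)))
  # monotone in lobe amplitude
  lob <- vapply(c(1, 2, 4), function(len) {
    lobeyness(generate_lobed_disc(radius = 10, n_lobes = 8, lobe_length = len))
  }, numeric(1))
  expect_true(all(diff(lob) > 0))
  expect_gt(lob[1], 1)
})

test_that("circularity matches closed forms and inflates with elongation", {
  expect_equal(circularity(regular_polygon(400)), 2 * sqrt(pi), tolerance = 1e-4)
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(circularity(sq), 4)
  rect <- data.frame(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1))
  expect_equal(circularity(rect), 12 / sqrt(5))
  # elongation inflates circularity even though the shape has no lobes
  expect_gt(circularity(rect), circularity(sq))
  expect_equal(lobeyness(rect), 1)
})

test_that("hull solidity flags bent shapes that lobeyness ignores", {
  expect_equal(hull_solidity(regular_polygon(5)), 1, tolerance = 1e-9)
  expect_equal(hull_solidity(plus_cross()), 7 / 5)
  boom <- fixture_shapes()$boomerang
  expect_gt(hull_solidity(boom), 2)
  expect_lt(lobeyness(boom), 1.3)
})

test_that("shape metrics are invariant under rigid motion and scaling", {
  for (s in 1:4) {
    p <- random_star_polygon(60, rng = s)
    q <- rigid_motion(p, angle = 1.1, dx = -4, dy = 7, scale = 3.7)
    expect_equal(lobeyness(q), lobeyness(p), tolerance = 1e-9)
    expect_equal(circularity(q), circularity(p), tolerance = 1e-9)
    expect_equal(hull_solidity(q), hull_solidity(p), tolerance = 1e-9)
    expect_equal(aspect_ratio(q), aspect_ratio(p), tolerance = 1e-6)
  }
})

test_that("growth anisotropy recovers imposed deformations", {
  p <- random_star_polygon(50, rng = 3)
  expect_equal(growth_anisotropy(p, p), 1)
  iso <- data.frame(x = 1.3 * p$x, y = 1.3 * p$y)
  expect_equal(growth_anisotropy(p, iso), 1, tolerance = 1e-9)
  st <- data.frame(x = 1.2 * p$x, y = p$y)
  expect_equal(growth_anisotropy(p, st), 1.2, tolerance = 1e-9)
  # invariant under pre/post rotation
  expect_equal(growth_anisotropy(rigid_motion(p, 0.5), rigid_motion(st, -0.9)),
               1.2, tolerance = 1e-6)
  expect_error(growth_anisotropy(p, p[1:10, ]), "same number")
  flatl <- data.frame(x = 1:5, y = rep(0, 5))
  expect_error(growth_anisotropy(flatl, flatl), "rank-deficient")
})

test_that("stress proxy is the thin-wall hoop closed form", {
  expect_equal(stress_proxy(10, pressure = 0.5, thickness = 1), 5)
  expect_equal(stress_proxy(20, 0.5, 1), 2 * stress_proxy(10, 0.5, 1))
  expect_equal(stress_proxy(0, 0.5, 1), 0)
})

test_that("contour_metrics tidies many cells and keeps LEC below cell area", {
  shapes <- dplyr::bind_rows(
    dplyr::mutate(generate_lobed_disc(10, 8, 5), cell_id = 1),
    dplyr::mutate(regular_polygon(40, r = 8), cell_id = 2)
  )
  m <- contour_metrics(shapes)
  expect_equal(nrow(m), 2)
  expect_true(all(m$lobeyness >= 1))
  expect_true(all(m$lec_area <= m$area))
  expect_equal(m$lec_area, pi * m$lec_radius^2)
  expect_equal(m$stress_proxy, 0.5 * m$lec_radius)
  expect_gt(m$lobeyness[1], m$lobeyness[2])
})

test_that("lec_vs_area_summary filters to the largest cells per group", {
  rec <- tibble::tibble(step = rep(c(0L, 1L), each = 5),
                        area = c(1:5, 2 * (1:5)),
                        lec_area = 0.5 * c(1:5, 2 * (1:5)))
  s <- lec_vs_area_summary(rec, top_fraction = 0.2)
  expect_equal(s$mean_cell_area, c(5, 10))
  expect_equal(s$mean_lec_area, c(2.5, 5))
  expect_equal(s$circular_reference, s$mean_cell_area)
  s1 <- lec_vs_area_summary(tibble::tibble(area = c(1, 3), lec_area = c(1, 3)),
                            top_fraction = 1)
  expect_equal(s1$mean_cell_area, 2)
  expect_equal(s1$mean_lec_area, s1$circular_reference) # circles: on the line
  # lobed cells fall below the circular reference
  discs <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(generate_lobed_disc(10, 8, 5 + i), cell_id = i)
  }))
  met <- contour_metrics(discs)
  s2 <- lec_vs_area_summary(met, top_fraction = 1)
  expect_lt(s2$mean_lec_area, s2$mean_cell_area)
})
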