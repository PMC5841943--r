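test_that("growth is the imposed affine map with relaxed walls", {
  t0 <- small_tissue()
  p <- sim_params(g_x = 1.05, g_y = 1.05)
  t1 <- grow_tissue(t0, p)
  # positions scale exactly (node count may grow by subdivision afterwards)
  n0 <- nrow(t0$nodes)
  expect_equal(t1$nodes[seq_len(n0), ], t0$nodes * 1.05)
  # wall springs relaxed: zero stretch energy right after growth
  expect_equal(unname(total_energy(t1, p, by_term = TRUE)["wall"]), 0,
               tolerance = 1e-18)
  pan <- sim_params(g_x = 1.05, g_y = 1)
  t2 <- grow_tissue(t0, pan)
  expect_equal(t2$nodes[seq_len(n0), 1], t0$nodes[, 1] * 1.05)
  expect_equal(t2$nodes[seq_len(n0), 2], t0$nodes[, 2])
  expect_error(grow_tissue(t0, sim_params(g_x = 1, g_y = 1)), NA)
})

test_that("transversal references do not grow; wall rests never shrink", {
  t0 <- small_tissue()
  p <- sim_params(min_micro = 6, kappa_convex = 10)
  t0 <- place_connections(t0, p)
  ref0 <- t0$springs$ref
  t1 <- grow_tissue(t0, p)
  expect_identical(t1$springs$ref, ref0)
  # grown springs are now longer relative to their fixed reference
  s0 <- spring_state(t0, p)
  s1 <- spring_state(t1, p)
  expect_true(all(s1$length >= s0$length))
  expect_true(all(t1$walls$rest > 0))
})

test_that("without growth restriction cells stay affine images", {
  t0 <- generate_tissue(n_cells = 9, width = 30, height = 30, seed = 2)
  p <- sim_params(k_m = 0, n_steps = 5)
  lob0 <- contour_metrics(tissue_contours(t0), lec = FALSE)$lobeyness
  t <- t0
  for (s in 1:5) t <- sim_step(t, p, s)
  lob <- contour_metrics(tissue_contours(t), lec = FALSE)$lobeyness
  expect_true(all(abs(lob - 1) < 0.01))
  expect_equal(lob, lob0, tolerance = 1e-6)
  # the tissue is exactly the scaled template (original nodes first)
  n0 <- nrow(t0$nodes)
  expect_equal(t$nodes[seq_len(n0), ], t0$nodes * 1.03^5, tolerance = 1e-9)
  expect_equal(polygon_area(t$nodes[t$cells[[1]], ]),
               polygon_area(t0$nodes[t0$cells[[1]], ]) * (1.03^2)^5,
               tolerance = 1e-9)
})

test_that("runs are deterministic given seed and config", {
  p <- sim_params(n_steps = 4, seed = 7)
  tmpl <- generate_tissue(n_cells = 9, width = 30, height = 30, seed = 7)
  s1 <- suppressWarnings(run_scenario("isotropic", p, template = tmpl))
  s2 <- suppressWarnings(run_scenario("isotropic", p, template = tmpl))
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$tissue$nodes, s2$tissue$nodes)
})

test_that("scenario presets configure the intended regimes", {
  p <- sim_params()
  expect_equal(puzzlecell:::.apply_scenario(p, "anisotropic")$g_y, 1)
  expect_equal(puzzlecell:::.apply_scenario(p, "gradient")$gradient,
               c(1, p$g_x))
  spk <- puzzlecell:::.apply_scenario(p, "spk1")
  expect_true(spk$spk1_mode)
  expect_gt(spk$k_m, p$k_m)
  expect_gt(spk$k_s, p$k_s)
  expect_gt(spk$reset_period, p$reset_period)
  expect_equal(puzzlecell:::.apply_scenario(p, "no_restriction")$k_m, 0)
  expect_error(run_scenario("wobbly", p), "arg")
})

test_that("gradient growth interpolates the y factor across the tissue", {
  nodes <- cbind(c(0, 45, 90), c(10, 10, 10))
  p <- sim_params(gradient = c(1, 1.06))
  g <- puzzlecell:::.growth_factors(nodes, c(0, 90, 0, 20), p)
  expect_equal(g[, 2], c(1, 1.03, 1.06))
  expect_equal(g[, 1], rep(p$g_x, 3))
})

test_that("run artifacts are complete, tidy and serializable", {
  p <- sim_params(n_steps = 3, seed = 5)
  tmpl <- generate_tissue(n_cells = 9, width = 30, height = 30, seed = 5)
  sim <- suppressWarnings(run_scenario("isotropic", p, template = tmpl,
                                       snapshot_every = 2))
  expect_s3_class(sim, "puzzle_sim")
  expect_named(sim$snapshots, c("step0", "step2", "step3"))
  expect_equal(sort(unique(sim$metrics$step)), 0:3)
  td <- tidy(sim)
  expect_true(all(td$interior))
  gl <- glance(sim)
  expect_equal(gl$n_steps, 3L)
  expect_equal(gl$growth_x, 1.03^3)
  # metrics CSV round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(sim$metrics, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$metrics))
  # svg frame
  fsvg <- withr::local_tempfile(fileext = ".svg")
  write_tissue_svg(sim$tissue, fsvg)
  expect_true(any(grepl("<polygon", readLines(fsvg))))
  # autoplot objects build without error
  expect_s3_class(autoplot(sim$tissue), "ggplot")
  expect_s3_class(autoplot(sim), "ggplot")
})

test_that("sweep returns one summary row per value and honours k_m = 0", {
  tmpl <- generate_tissue(n_cells = 9, width = 30, height = 30, seed = 4)
  base <- sim_params(n_steps = 3, seed = 4)
  sw <- suppressWarnings(sweep_parameter("k_m", c(0, 1), base = base,
                                         template = tmpl))
  expect_equal(nrow(sw), 2)
  expect_equal(sw$value, c(0, 1))
  expect_lt(abs(sw$mean_lobeyness[1] - 1), 0.01)
  expect_error(sweep_parameter("nope", 1, base), "arg")
})
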