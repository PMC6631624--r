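test_that("scratch initial condition carves a centered cell-free stripe", {
  g <- grid_1d(0, 2000, 401, t_end = 1)
  # wound covering half the domain
  init <- make_scratch_initial_condition(fk_parameters(D = 1, tau = 1, b = 1000), g)
  expect_equal(sum(init$values[1, ] == 0), 401 / 2, tolerance = 1 / 200)
  expect_true(all(init$values[1, ] %in% c(0, 1)))
  # one-grid-cell wound leaves a single interior zero
  init1 <- make_scratch_initial_condition(fk_parameters(D = 1, tau = 1, b = g$dx), g)
  expect_equal(sum(init1$values[1, ] == 0), 1)
  # 500 um wound on a 2000 um domain with 401 nodes: 100 +/- 1 zero nodes
  init5 <- make_scratch_initial_condition(fk_parameters(D = 1, tau = 1, b = 500), g)
  n0 <- sum(init5$values[1, ] == 0)
  expect_true(abs(n0 - 100) <= 1)
  # zero-density extent equals b to within one grid cell
  expect_equal(n0 * g$dx, 500, tolerance = 2 * g$dx / 500)
  # wound wider than the domain is refused
  expect_error(
    make_scratch_initial_condition(fk_parameters(D = 1, tau = 1, b = 2500), g),
    "wound width")
})

test_that("FK solver is static without dynamics and refuses unstable steps", {
  g <- grid_1d(0, 100, 11, t_end = 2, save_every = 1, dt = 0.01)
  p0 <- fk_parameters(D = 0, k = 0, b = 10)
  u0 <- matrix(c(1, 0.2, 0.8, 0.1, 0.5, 0, 0.9, 0.3, 0.6, 0.4, 1), 1)
  out <- simulate_fk_1d(density_field(0, u0, g), p0, g)
  expect_identical(out$values[2, ], out$values[1, ])
  expect_identical(out$values[3, ], out$values[1, ])
  # dt above dx^2/(2D) raises a stability error, not silent garbage
  gbad <- grid_1d(0, 100, 11, t_end = 2, save_every = 1, dt = 0.5)
  pD <- fk_parameters(D = 200, k = 0, b = 10)
  expect_error(simulate_fk_1d(density_field(0, u0, gbad), pD, gbad),
               class = "wk_stability_error")
  expect_lt(fk_stability_limit(200, 10), 0.5)
})

test_that("pure diffusion follows the heat kernel within 1% L2", {
  D <- 300; sigma0 <- 40; L <- 4000
  g <- grid_1d(0, L, 801, t_end = 6, save_every = 1)
  p <- fk_parameters(D = D, k = 0, b = 100)
  u0 <- exp(-(g$x - L / 2)^2 / (2 * sigma0^2))
  field <- simulate_fk_1d(density_field(0, matrix(u0, 1), g), p, g)
  for (i in c(4, 7)) {
    s2 <- sigma0^2 + 2 * D * field$times[i]
    exact <- sigma0 / sqrt(s2) * exp(-(g$x - L / 2)^2 / (2 * s2))
    l2 <- sqrt(sum((field$values[i, ] - exact)^2) / sum(exact^2))
    expect_lt(l2, 0.01)
  }
})

test_that("no-flux boundaries conserve mass when growth is off", {
  sim <- tiny_scratch_field(D = 400, tau = 1e9, b = 500, t_end = 6,
                            save_every = 1)
  m <- total_cell_mass(sim$field)
  expect_equal(max(abs(m / m[1] - 1)), 0, tolerance = 1e-6)
})

test_that("density respects the comparison principle and stays monotone", {
  for (pars in list(c(D = 200, tau = 10), c(D = 800, tau = 25))) {
    g <- grid_1d(0, 2000, 401, t_end = 12, save_every = 3)
    p <- fk_parameters(D = pars[["D"]], tau = pars[["tau"]], b = 600)
    field <- simulate_fk_1d(make_scratch_initial_condition(p, g), p, g)
    expect_lte(max(field$values), p$u_hat * (1 + 1e-9))
    expect_gte(min(field$values), 0)
    # the left half of the profile starts monotone decreasing and stays so
    half <- seq_len(round(g$n_nodes / 2))
    for (i in seq_along(field$times))
      expect_true(all(diff(field$values[i, half]) <= 1e-9))
  }
})

test_that("simulated fronts travel at the Fisher-KPP minimum speed", {
  D <- 400; tau <- 12
  v_th <- forward_speed(D, tau)
  t_end <- 12 * tau
  L <- ceiling(1.6 * v_th * t_end + 1500)
  g <- grid_1d(0, L, round(L / 5) + 1, t_end = t_end, save_every = t_end / 150)
  p <- fk_parameters(D = D, tau = tau, b = 100)
  u0 <- ifelse(g$x < 0.2 * L, 1, 0)
  field <- simulate_fk_1d(density_field(0, matrix(u0, 1), g), p, g)
  v_hat <- estimate_front_speed(field, 1)
  expect_equal(v_hat, v_th, tolerance = 0.05)
})

test_that("renderer handles degenerate fields and is seed-deterministic", {
  cfg <- render_config(pixel_size = 4, seed = 42)
  # all-zero field: pure background + noise, full-frame ground-truth mask
  st0 <- render_timelapse(flat_field(0), cfg)
  expect_true(all(st0$gt_masks[[1]]))
  expect_equal(mean(st0$frames[[1]]), 0.35, tolerance = 0.01)
  expect_lt(sd(st0$frames[[1]]), 2 * 0.02)
  # confluent field: empty ground-truth mask, strong texture
  st1 <- render_timelapse(flat_field(1), cfg)
  expect_false(any(st1$gt_masks[[1]]))
  expect_gt(sd(st1$frames[[1]]), 0.1)
  # half-occupied field: wound fraction 0.5 within one pixel column
  g <- grid_1d(0, 1600, 161, t_end = 1, save_every = 1)
  u_half <- ifelse(g$x < 800, 1, 0)
  sth <- render_timelapse(density_field(0, matrix(u_half, 1), g), cfg)
  frac <- mean(sth$gt_masks[[1]])
  expect_lte(abs(frac - 0.5), 1 / ncol(sth$gt_masks[[1]]) + 1e-12)
  # identical seed + config give a bit-identical stack
  sim <- tiny_scratch_field()
  a <- render_timelapse(sim$field, cfg)
  b <- render_timelapse(sim$field, cfg)
  expect_identical(a$frames, b$frames)
  c <- render_timelapse(sim$field, render_config(pixel_size = 4, seed = 43))
  expect_false(identical(a$frames, c$frames))
})

test_that("renderer ground-truth masks match the sub-threshold area", {
  sim <- tiny_scratch_field(t_end = 8, save_every = 2)
  cfg <- render_config(pixel_size = 4, seed = 7, occupancy_threshold = 0.2)
  st <- render_timelapse(sim$field, cfg)
  for (i in seq_along(st$times)) {
    sub_extent <- sum(sim$field$values[i, ] < 0.2) * sim$grid$dx
    mask_extent <- mean(rowSums(st$gt_masks[[i]])) * cfg$pixel_size
    expect_equal(mask_extent, sub_extent, tolerance = 2 * cfg$pixel_size / max(sub_extent, 1))
  }
})

test_that("renderer refuses a frame too small for the domain", {
  sim <- tiny_scratch_field()
  cfg <- render_config(pixel_size = 4, frame_shape = c(64, 100))
  expect_error(render_timelapse(sim$field, cfg), "frame too small")
})

test_that("image stacks round-trip through TIFF + sidecar", {
  sim <- tiny_scratch_field()
  st <- render_timelapse(sim$field, render_config(pixel_size = 4, seed = 9))
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_image_stack(st, path, metadata = list(seed = 9))
  back <- read_image_stack(path)
  expect_equal(back$times, st$times)
  expect_equal(back$pixel_size, st$pixel_size)
  expect_equal(length(back$frames), length(st$frames))
  # 16-bit quantization error only
  expect_lt(max(abs(back$frames[[1]] - st$frames[[1]])), 1 / 65535)
})

test_that("growth-curve generator matches the doubling law exactly when noiseless", {
  expect_equal(simulate_growth_curve(100, 24, c(0, 24), 0)$count[2], 200)
  expect_equal(simulate_growth_curve(100, 24, c(0, 24, 48), 0)$count[3], 400)
  expect_equal(simulate_growth_curve(9e3, 20, c(0, 10), 0)$count[2],
               9e3 * sqrt(2), tolerance = 1e-12)
  # noisy curves are positive, seed-reproducible, mean-one noise
  a <- simulate_growth_curve(100, 24, 0:10, noise_cv = 0.1, seed = 5)
  b <- simulate_growth_curve(100, 24, 0:10, noise_cv = 0.1, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$count > 0))
})
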