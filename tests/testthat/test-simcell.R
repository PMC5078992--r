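test_that("constructors enforce their invariants", {
  expect_error(cell_geometry(radius = -1), "radius")
  expect_error(cell_geometry(tirf_depth = 1.5, radius = 0.5), "tirf_depth")
  expect_error(diffusion_model(d_fast = 0.01, d_slow = 0.05), "d_fast >= d_slow")
  expect_error(diffusion_model(sigma_loc = -0.1), "sigma_loc")
  expect_error(simulation_config(track_min_points = 1), "track_min_points")
  expect_error(simulation_config(bleach_survival_per_frame = 0),
               "bleach_survival")
  # stationarity consistency: alpha derived from rates, conflicts rejected
  m <- diffusion_model(rate_fast_to_slow = 6, rate_slow_to_fast = 2)
  expect_equal(m$alpha, 0.25)
  expect_error(diffusion_model(alpha = 0.9, rate_fast_to_slow = 6,
                               rate_slow_to_fast = 2), "conflicts")
})

test_that("step_surface: zero diffusion leaves the position unchanged and
           static rates never switch the state", {
  geom <- cell_geometry()
  m0 <- diffusion_model(d_fast = 0, d_slow = 0, alpha = 0.5,
                        rate_fast_to_slow = 0, rate_slow_to_fast = 0)
  st <- surface_state(axial = 0.3, angle = 0.2, motion_state = "fast")
  withr::with_seed(1, {
    for (i in 1:20) st <- step_surface(st, m0, geom, dt = 0.003)
  })
  expect_equal(st$axial, 0.3)
  expect_equal(st$angle, 0.2)
  expect_identical(st$motion_state, "fast")
})

test_that("step_surface displacement variance matches 2*D*dt", {
  # Monte Carlo vs closed form: 1e5 axial steps at D = 0.1, dt = 3 ms
  geom <- cell_geometry(radius = 0.5, length = 1e6, tirf_depth = 1)
  m <- diffusion_model(d_fast = 0.1, d_slow = 0.1, alpha = 1,
                       rate_fast_to_slow = 0, rate_slow_to_fast = 0)
  n <- 1e5
  out <- withr::with_seed(7,
    sptdiff:::step_surface_vec(numeric(n), numeric(n), rep(TRUE, n), m, geom,
                               dt = 0.003, kinetic = FALSE))
  v_target <- 2 * 0.1 * 0.003
  se <- v_target * sqrt(2 / (n - 1))      # SE of a normal sample variance
  expect_lt(abs(var(out$axial) - v_target), 3 * se)
  expect_lt(abs(var(out$angle * geom$radius) - v_target), 3 * se)
})

test_that("projection geometry and TIRF visibility", {
  geom <- cell_geometry(radius = 0.5, length = 3, tirf_depth = 0.125)
  bottom <- project_and_observe(surface_state(0, 0, "fast"), geom)
  expect_true(bottom$visible)
  expect_equal(bottom$image_xy, c(0, 0))
  expect_equal(bottom$z, 0)
  side <- project_and_observe(surface_state(0, pi / 2, "fast"), geom)
  expect_false(side$visible)
  expect_equal(side$z, 0.5)
  # visibility half-angle solves radius*(1 - cos(theta)) = depth
  expect_equal(visibility_half_angle(geom), acos(0.75), tolerance = 1e-12)
  at_edge <- project_and_observe(
    surface_state(0, acos(0.75) - 1e-9, "fast"), geom)
  expect_true(at_edge$visible)
  beyond <- project_and_observe(
    surface_state(0, acos(0.75) + 1e-6, "fast"), geom)
  expect_false(beyond$visible)
  # full-visibility geometry sees everything
  expect_equal(visibility_half_angle(cell_geometry(0.5, 3, 1)), pi)
})

test_that("simulate_tracks: frozen molecules give constant tracks", {
  cfg <- simulation_config(
    geometry = cell_geometry(0.5, 3, 1),
    model = diffusion_model(0, 0, alpha = 0.5, sigma_loc = 0,
                            rate_fast_to_slow = 0, rate_slow_to_fast = 0),
    n_molecules = 50, mixture_mode = "static", seed = 3)
  sim <- simulate_tracks(cfg)
  expect_gt(n_tracks(sim$tracks), 0)
  for (tr in split(sim$tracks$data, sim$tracks$data$track_id)) {
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("static mixture draws the fast state with probability alpha", {
  alpha <- 0.3
  cfg <- planar_sim_config(0.05, n_molecules = 4000, seed = 5,
                           alpha = alpha, d_slow = 0)
  sim <- simulate_tracks(cfg)
  first <- sim$truth[sim$truth$frame == 0, ]
  p_hat <- mean(first$motion_state == "fast")
  se <- sqrt(alpha * (1 - alpha) / nrow(first))
  expect_lt(abs(p_hat - alpha), 3 * se)
  # static: state constant within every track
  expect_equal(length(unique(paste(sim$truth$track_id,
                                   sim$truth$motion_state))),
               length(unique(sim$truth$track_id)))
})

test_that("kinetic mode is stationary at alpha over molecule-frames", {
  cfg <- simulation_config(
    geometry = cell_geometry(0.5, 3, 1),
    model = diffusion_model(0.05, 0, sigma_loc = 0,
                            rate_fast_to_slow = 6, rate_slow_to_fast = 2),
    n_molecules = 12000, n_frames_max = 12, track_min_points = 2,
    bleach_survival_per_frame = 1, mixture_mode = "kinetic",
    observe = "surface", seed = 11)
  sim <- simulate_tracks(cfg)
  expect_gt(nrow(sim$truth), 1e5)
  # molecules (not frames) are the independent units for the SE
  frac <- tapply(sim$truth$motion_state == "fast", sim$truth$track_id, mean)
  expect_lt(abs(mean(frac) - 0.25), 3 * sd(frac) / sqrt(length(frac)))
})

test_that("identical config gives byte-identical track tables", {
  cfg <- simulation_config(n_molecules = 200, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tracks(simulate_tracks(cfg)$tracks, f1)
  write_tracks(simulate_tracks(cfg)$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1)
})

test_that("a config retaining zero tracks warns and returns an empty set", {
  cfg <- simulation_config(n_molecules = 5, track_min_points = 12,
                           bleach_survival_per_frame = 0.01, seed = 1)
  expect_warning(sim <- simulate_tracks(cfg), "zero tracks")
  expect_equal(n_tracks(sim$tracks), 0)
})

test_that("track lengths respect the min/max window and bleaching regime", {
  cfg <- planar_sim_config(0.05, n_molecules = 2000, seed = 8)
  lens <- track_lengths(filter_by_length(simulate_tracks(cfg)$tracks, 4, 12))
  expect_true(all(lens >= 4 & lens <= 12))
})
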