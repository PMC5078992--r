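test_that("MSD matches hand computation and zero for stationary tracks", {
  one <- make_track_set(list(cbind(c(0, 1, 2), 0)))
  msd <- compute_msd(one, 2)
  expect_equal(msd$msd, c(1, 4))
  expect_equal(msd$n_pairs_per_lag, c(2L, 1L))
  expect_equal(msd$lags, c(0.03, 0.06))
  frozen <- make_track_set(list(cbind(rep(0.5, 5), 1), cbind(rep(1, 4), 2)))
  expect_true(all(compute_msd(frozen, 3)$msd == 0))
})

test_that("compute_msd equals the brute-force double-loop oracle", {
  for (seed in 1:4) {
    ts <- random_brownian_set(8, d = 0.08, sigma = 0.02, seed = seed)
    msd <- compute_msd(ts, 6)
    oracle <- brute_msd(ts, 6)
    keep <- oracle$n > 0
    expect_equal(msd$msd, oracle$msd[keep], tolerance = 1e-12)
    expect_equal(msd$n_tracks_per_lag, unname(oracle$n[keep]))
  }
  # also with frame gaps: lag counts follow frame differences, not row order
  gappy <- make_track_set(list(cbind(c(0, 1, 2, 5), 0)),
                          frames = list(c(0L, 1L, 2L, 5L)))
  expect_equal(compute_msd(gappy, 5)$msd, brute_msd(gappy, 5)$msd)
})

test_that("estimate_diffusion recovers exact lines and flat MSDs", {
  line <- make_track_set(list(cbind(c(0, 1, 2), 0)))  # placeholder container
  msd <- compute_msd(line, 2)
  # exact line: msd = 4*D*t with D = 0.1 at lags 0.03..0.12
  msd$lags <- (1:4) * 0.03; msd$lag_frames <- 1:4
  msd$msd <- 4 * 0.1 * msd$lags
  est <- estimate_diffusion(msd, 4)
  expect_equal(est$d_app, 0.1, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  # flat MSD = 4*sigma^2: zero slope, intercept houses the offset
  msd$msd <- rep(4 * 0.03^2, 4)
  est2 <- estimate_diffusion(msd, 4)
  expect_equal(est2$d_app, 0)
  expect_equal(est2$intercept, 4 * 0.03^2)
  expect_error(estimate_diffusion(compute_msd(line, 2), 4), "lags")
})

test_that("d_app is invariant to rigid motions of all tracks", {
  ts <- random_brownian_set(60, d = 0.05, sigma = 0.02, seed = 2)
  d0 <- estimate_diffusion(compute_msd(ts, 4))$d_app
  th <- 0.7
  rot <- ts
  x <- ts$data$x_um; y <- ts$data$y_um
  rot$data$x_um <- cos(th) * x - sin(th) * y + 3.2
  rot$data$y_um <- sin(th) * x + cos(th) * y - 1.1
  expect_equal(estimate_diffusion(compute_msd(rot, 4))$d_app, d0,
               tolerance = 1e-10)
})

test_that("bootstrap_diffusion: degenerate, deterministic, and 1/sqrt(n)", {
  # identical copies of one track: no resampling variance
  p <- cbind(cumsum(c(0, rnorm(7, 0, 0.05))), cumsum(c(0, rnorm(7, 0, 0.05))))
  same <- make_track_set(rep(list(p), 5))
  b <- bootstrap_diffusion(same, n_boot = 50, seed = 1)
  expect_equal(b$boot_sd, 0)
  ts <- random_brownian_set(100, d = 0.05, seed = 3)
  b1 <- bootstrap_diffusion(ts, n_boot = 200, seed = 9)
  b2 <- bootstrap_diffusion(ts, n_boot = 200, seed = 9)
  expect_identical(b1$boot_sd, b2$boot_sd)
  expect_equal(b1$d_app, estimate_diffusion(compute_msd(ts, 4))$d_app)
  # resampling scaling: x4 tracks gives ~x2 smaller boot_sd
  big <- random_brownian_set(400, d = 0.05, seed = 3)
  b4 <- bootstrap_diffusion(big, n_boot = 200, seed = 9)
  expect_gt(b1$boot_sd / b4$boot_sd, 1.4)
  expect_lt(b1$boot_sd / b4$boot_sd, 2.8)
})

test_that("pooling two same-model sets moves d_app by < 2 boot_sd", {
  a <- simulate_tracks(planar_sim_config(0.05, 0.03, 1500, seed = 21))$tracks
  b <- simulate_tracks(planar_sim_config(0.05, 0.03, 1500, seed = 22))$tracks
  b$data$track_id <- paste0("b_", b$data$track_id)
  est_a <- bootstrap_diffusion(a, n_boot = 200, seed = 1)
  pooled <- track_set(rbind(a$data, b$data), a$frame_interval)
  est_p <- estimate_diffusion(compute_msd(pooled, 4))
  expect_lt(abs(est_p$d_app - est_a$d_app), 2 * est_a$boot_sd)
})

test_that("permutation test: exact-null p, symmetry, +1 convention", {
  ts <- random_brownian_set(40, d = 0.05, seed = 5)
  ts_b <- ts
  ts_b$data$track_id <- paste0("b_", ts_b$data$track_id)
  # identical groups: observed statistic exactly 0 so p = 1 under +1 rule
  r <- permutation_test(ts, ts_b, n_perm = 99, seed = 1)
  expect_equal(r$stat_observed, 0)
  expect_equal(r$p_value, 1)
  # symmetry: swapping conditions negates the statistic, p unchanged
  a <- simulate_tracks(planar_sim_config(0.05, 0.03, 300, seed = 31))$tracks
  b <- simulate_tracks(planar_sim_config(0.09, 0.03, 300, seed = 32))$tracks
  r_ab <- permutation_test(a, b, n_perm = 200, seed = 7)
  r_ba <- permutation_test(b, a, n_perm = 200, seed = 7)
  expect_equal(r_ab$stat_observed, -r_ba$stat_observed)
  expect_equal(r_ab$p_value, r_ba$p_value)
  expect_gte(r_ab$p_value, 1 / 201)
  # bootstrap-within-permutation variant runs and is seeded
  r_bw <- permutation_test(a, b, n_perm = 50, seed = 7, boot_within = TRUE)
  expect_identical(
    r_bw$p_value,
    permutation_test(a, b, n_perm = 50, seed = 7, boot_within = TRUE)$p_value)
})

test_that("growth rate recovers exponential, constant and linear growth", {
  t <- seq(0, 3000, by = 30)
  g <- 5e-4
  gr <- growth_rate_from_length(t, 2 * exp(g * t), window = 10)
  mid <- !is.na(gr$growth_rate)
  expect_lt(max(abs(gr$growth_rate[mid] - g) / g), 0.01)
  flat <- growth_rate_from_length(t, rep(2.5, length(t)))
  expect_true(all(abs(flat$growth_rate[!is.na(flat$growth_rate)]) < 1e-12))
  a <- 1e-3; L0 <- 2
  lin <- growth_rate_from_length(t, L0 + a * t, window = 10)
  ok <- which(!is.na(lin$growth_rate))
  expect_equal(lin$growth_rate[ok], a / (L0 + a * t[ok]), tolerance = 0.02)
  expect_error(growth_rate_from_length(t, rep(-1, length(t))), "lengths")
  expect_error(growth_rate_from_length(t[1:5], rep(1, 5)), "window")
})
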