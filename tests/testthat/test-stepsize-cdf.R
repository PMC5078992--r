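test_that("step collection counts overlapping pairs per lag", {
  one <- make_track_set(list(cbind(c(0, 1, 2), 0)))
  st <- collect_step_sizes(one, 1:2)
  expect_equal(st$n_per_lag, c(2L, 1L))
  expect_equal(sort(st$r2[[1]]), c(1, 1))
  expect_equal(st$r2[[2]], 4)
  frozen <- make_track_set(list(cbind(rep(1, 6), 2)))
  expect_true(all(unlist(collect_step_sizes(frozen, 1:4)$r2) == 0))
  expect_error(collect_step_sizes(one, 5:6), "long enough")
})

test_that("step collection matches the brute-force recount oracle", {
  for (seed in 1:3) {
    ts <- random_brownian_set(6, d = 0.05, sigma = 0.01, seed = seed)
    st <- collect_step_sizes(ts, 1:4)
    for (li in 1:4)
      expect_equal(sort(st$r2[[li]]), sort(brute_steps(ts, li)),
                   tolerance = 1e-12)
  }
})

test_that("model CDFs: anchors, degenerate mixtures, monotonicity", {
  expect_equal(model_cdf_one(0, 0.03, 0.05, 0.03), 0)
  sc <- 4 * 0.05 * 0.03 + 4 * 0.03^2
  expect_equal(model_cdf_one(sc, 0.03, 0.05, 0.03), 1 - exp(-1))
  # alpha = 1 / alpha = 0 collapse to the one-species model
  r2 <- seq(0, 0.1, length.out = 50)
  expect_equal(model_cdf_two(r2, 0.03, 0.05, 0.001, 1, 0.03),
               model_cdf_one(r2, 0.03, 0.05, 0.03))
  expect_equal(model_cdf_two(r2, 0.03, 0.05, 0.001, 0, 0.03),
               model_cdf_one(r2, 0.03, 0.001, 0.03))
  # property: valid CDF on a dense grid for random valid parameters
  withr::with_seed(42, {
    for (i in 1:25) {
      D1 <- runif(1, 0, 0.5); D2 <- runif(1, 0, D1)
      a <- runif(1); s <- runif(1, 0, 0.05); t <- runif(1, 0.01, 0.2)
      grid <- seq(0, 1.5, length.out = 400)
      v <- model_cdf_two(grid, t, D1, D2, a, s)
      expect_true(all(v >= 0 & v <= 1))
      expect_true(all(diff(v) >= -1e-12))
      expect_gt(model_cdf_two(50, t, D1, D2, a, s), 0.999)
    }
  })
})

test_that("sampling round-trip: empirical CDF matches the model", {
  n <- 1e4
  r2 <- withr::with_seed(5, sample_r2_mixture(n, 0.03, 0.05, sigma = 0.03))
  ks <- max(abs(stats::ecdf(r2)(sort(r2)) -
                model_cdf_one(sort(r2), 0.03, 0.05, 0.03)))
  expect_lt(ks, 1.63 / sqrt(n))       # KS 1% critical value
})

test_that("fit_cdf recovers one-species parameters from exact samples", {
  data <- withr::with_seed(10, make_step_data(lapply(1:4, function(k)
    sample_r2_mixture(5e4, k * 0.03, 0.05, sigma = 0.03))))
  fit <- fit_cdf(data, "one_species")
  expect_lt(abs(fit$D - 0.05) / 0.05, 0.05)
  expect_lt(abs(fit$sigma - 0.03) / 0.03, 0.10)
  # two-species fit can only improve rss (nesting), up to solver tolerance
  fit2 <- fit_cdf(data, "two_species")
  expect_lte(fit2$rss, fit$rss * (1 + 1e-8))
  # evaluating the two-species model at alpha = 1 reproduces the
  # one-species objective exactly (nested models)
  pts <- sptdiff:::cdf_fit_points(data)
  obj1 <- sptdiff:::cdf_objective(pts, FALSE)
  obj2 <- sptdiff:::cdf_objective(pts, TRUE)
  expect_equal(obj2(c(fit$D, 0.001, 1, fit$sigma)),
               obj1(c(fit$D, fit$sigma)), tolerance = 1e-12)
})

test_that("fit_cdf recovers a two-species mixture from exact samples", {
  data <- withr::with_seed(11, make_step_data(lapply(1:4, function(k)
    sample_r2_mixture(3e4, k * 0.03, 0.05, D2 = 0, alpha = 0.4,
                      sigma = 0.03))))
  fit <- fit_cdf(data, "two_species")
  expect_gte(fit$D1, fit$D2)    # relabeling convention
  expect_lt(abs(fit$alpha - 0.4), 0.05)
  expect_lt(abs(fit$D1 - 0.05) / 0.05, 0.15)
  expect_lt(fit$D2, 0.005)
  expect_lt(abs(fit$sigma - 0.03) / 0.03, 0.20)
})

test_that("quantile-grid evaluation approximates the full-support fit", {
  data <- withr::with_seed(12, make_step_data(lapply(1:4, function(k)
    sample_r2_mixture(2e4, k * 0.03, 0.05, D2 = 0, alpha = 0.5,
                      sigma = 0.03))))
  full <- fit_cdf(data, "two_species")
  grid <- fit_cdf(data, "two_species", grid_n = 200)
  expect_lt(abs(full$alpha - grid$alpha), 0.02)
  expect_lt(abs(full$D1 - grid$D1) / full$D1, 0.05)
})

test_that("compare_models scores by BIC with the exact parameter penalty", {
  fake <- function(model, rss, n) {
    k <- if (model == "two_species") 4L else 2L
    structure(list(model = model, rss = rss, n_points = n,
                   bic = n * log(rss / n) + k * log(n), n_params = k),
              class = "cdf_fit")
  }
  n <- 1000
  same <- compare_models(fake("one_species", 2.5, n), fake("two_species", 2.5, n))
  expect_equal(same$delta_bic, 2 * log(n))   # pure parameter-count penalty
  expect_equal(same$chosen, "one_species")
  expect_error(compare_models(fake("one_species", 1, 500),
                              fake("two_species", 1, 600)), "n_points")
})

test_that("fitted alpha and ensemble d_app co-vary across a generator sweep,
           with sigma and D1 stable", {
  alphas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  fit_a <- d_app <- sig <- d1 <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    sim <- simulate_tracks(planar_sim_config(
      0.05, sigma = 0.03, n_molecules = 2200, seed = 100 + i,
      alpha = alphas[i], d_slow = 0))
    ts <- filter_by_length(sim$tracks, 4, 12)
    d_app[i] <- estimate_diffusion(compute_msd(ts, 4))$d_app
    f <- fit_cdf(collect_step_sizes(ts, 1:4), "two_species", grid_n = 300)
    fit_a[i] <- f$alpha; sig[i] <- f$sigma; d1[i] <- f$D1
  }
  expect_true(all(diff(fit_a) > 0))
  expect_true(all(diff(d_app) > 0))
  expect_gt(cor(fit_a, d_app), 0.98)
  # the generator only varies alpha; the fit must say the same
  expect_lt(max(abs(sig - 0.03) / 0.03), 0.2)
  expect_lt(max(abs(d1 - 0.05) / 0.05), 0.15)
})
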