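# Fixtures are built in code; no binary data anywhere.

# A track_set from a list of per-track position matrices (n x 2), with
# optional explicit frame vectors.
make_track_set <- function(positions, frames = NULL, frame_interval = 0.03,
                           condition = "test") {
  rows <- lapply(seq_along(positions), function(i) {
    p <- positions[[i]]
    f <- if (is.null(frames)) seq_len(nrow(p)) - 1L else frames[[i]]
    data.frame(track_id = sprintf("t%03d", i), condition = condition,
               frame = f, x_um = p[, 1], y_um = p[, 2],
               stringsAsFactors = FALSE)
  })
  track_set(do.call(rbind, rows), frame_interval = frame_interval)
}

# Random planar Brownian track_set (direct, independent of the simulator).
random_brownian_set <- function(n_tracks, d, sigma = 0, dt = 0.03,
                                len_range = c(4L, 12L), seed = 1) {
  withr::with_seed(seed, {
    positions <- lapply(seq_len(n_tracks), function(i) {
      n <- sample(seq(len_range[1], len_range[2]), 1)
      steps <- matrix(stats::rnorm(2 * (n - 1), 0, sqrt(2 * d * dt)),
                      ncol = 2)
      pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
      pos + matrix(stats::rnorm(2 * n, 0, sigma), ncol = 2)
    })
    make_track_set(positions, frame_interval = dt)
  })
}

# Brute-force MSD oracle: explicit double loop over all frame pairs,
# per-track mean then ensemble mean. Kept deliberately naive.
brute_msd <- function(ts, max_lag) {
  trs <- split(ts$data, ts$data$track_id)
  out <- sapply(seq_len(max_lag), function(k) {
    per_track <- c()
    for (tr in trs) {
      vals <- c()
      for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
        if (tr$frame[j] - tr$frame[i] == k)
          vals <- c(vals, (tr$x_um[j] - tr$x_um[i])^2 +
                          (tr$y_um[j] - tr$y_um[i])^2)
      }
      if (length(vals)) per_track <- c(per_track, mean(vals))
    }
    c(msd = mean(per_track), n = length(per_track))
  })
  list(msd = out["msd", ], n_tracks = out["n", ])
}

# Brute-force step-size oracle: all squared displacements at exactly lag k.
brute_steps <- function(ts, k) {
  trs <- split(ts$data, ts$data$track_id)
  vals <- c()
  for (tr in trs) {
    for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
      if (tr$frame[j] - tr$frame[i] == k)
        vals <- c(vals, (tr$x_um[j] - tr$x_um[i])^2 +
                        (tr$y_um[j] - tr$y_um[i])^2)
    }
  }
  vals
}

# Exact inverse-CDF sampler for the one/two-species squared-step models:
# r2 is exponential with scale 4Dt + 4 sigma^2 (mixture over species).
sample_r2_mixture <- function(n, t, D1, D2 = NULL, alpha = 1, sigma = 0) {
  fast <- stats::runif(n) < alpha
  sc_fast <- 4 * D1 * t + 4 * sigma^2
  sc_slow <- if (is.null(D2)) sc_fast else 4 * D2 * t + 4 * sigma^2
  stats::rexp(n) * ifelse(fast, sc_fast, sc_slow)
}

# step_size_data built directly from sampled squared steps (bypasses tracks)
make_step_data <- function(r2_list, dt = 0.03) {
  structure(list(lags_frames = seq_along(r2_list),
                 lag_times = seq_along(r2_list) * dt,
                 r2 = r2_list,
                 track_index = vector("list", length(r2_list)),
                 n_per_lag = vapply(r2_list, length, integer(1)),
                 n_tracks = 1L, frame_interval = dt),
            class = "step_size_data")
}

# Simulator config for the planar validation world (surface coordinates,
# long cell so caps never bite, no TIRF truncation).
planar_sim_config <- function(d, sigma = 0, n_molecules = 2000, seed = 1,
                              alpha = 1, d_slow = d) {
  simulation_config(
    geometry = cell_geometry(radius = 0.5, length = 50, tirf_depth = 1),
    model = diffusion_model(d_fast = d, d_slow = d_slow, alpha = alpha,
                            sigma_loc = sigma,
                            rate_fast_to_slow = 0, rate_slow_to_fast = 0),
    n_molecules = n_molecules, n_frames_max = 14L,
    mixture_mode = "static", observe = "surface", seed = seed)
}
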