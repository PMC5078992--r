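# Ensemble MSD and diffusion inference.
#
# The MSD is per-track-mean-then-ensemble-mean: msd(k) is the mean over
# tracks of each track's mean squared displacement over all overlapping
# frame pairs at lag k, so the s.e.m. over tracks (molecules as independent
# units) is well defined. The apparent diffusion constant is slope/4 of an
# unweighted OLS line through the first few MSD points (free intercept,
# which absorbs the 4*sigma^2 localization-error offset).

# Per-track mean squared displacement at lags 1..max_lag (frames).
# Returns list(means = n_tracks x max_lag matrix with NA where a track has
# no pair at that lag, counts = matching pair counts). Handles frame gaps:
# a pair contributes to lag k iff its frame difference is exactly k.
track_lag_matrix <- function(ts, max_lag) {
  stopifnot(inherits(ts, "track_set"), max_lag >= 1)
  trs <- split_tracks(ts)
  nt <- length(trs)
  means <- matrix(NA_real_, nt, max_lag)
  counts <- matrix(0L, nt, max_lag)
  for (i in seq_len(nt)) {
    tr <- trs[[i]]
    f <- tr$frame
    x <- tr$x_um; y <- tr$y_um
    top <- min(max_lag, f[length(f)] - f[1])
    for (k in seq_len(top)) {
      j <- match(f + k, f)               # partner index at exactly k frames
      ok <- !is.na(j)
      if (!any(ok)) next
      jj <- j[ok]; ii <- which(ok)
      r2 <- (x[jj] - x[ii])^2 + (y[jj] - y[ii])^2
      means[i, k] <- mean(r2)
      counts[i, k] <- length(r2)
    }
  }
  list(means = means, counts = counts, track_ids = names(trs))
}

#' Ensemble mean-squared displacement
#'
#' For each lag `k = 1..max_lag_frames`, computes the mean over tracks of
#' the per-track mean squared displacement across all overlapping frame
#' pairs separated by exactly `k` frames; tracks with no pair at a lag are
#' excluded from that lag. The reported `sem` is the SD of the per-track
#' means divided by `sqrt(n_tracks_per_lag)`.
#'
#' @param ts A [track_set()] whose tracks all have >= 2 points.
#' @param max_lag_frames Largest lag, in frames.
#' @return An object of class `msd_result`: data.frame-like list with
#'   `lag_frames`, `lags` (seconds), `msd`, `sem`, `n_tracks_per_lag`,
#'   `n_pairs_per_lag`. Lags with no data are dropped with a warning.
#' @export
compute_msd <- function(ts, max_lag_frames = 10L) {
  stopifnot(inherits(ts, "track_set"))
  if (!nrow(ts$data)) stop("empty track_set: no tracks to compute MSD from")
  if (max_lag_frames < 1) stop("max_lag_frames must be >= 1")
  lm <- track_lag_matrix(ts, max_lag_frames)
  n_tr <- colSums(!is.na(lm$means))
  keep <- n_tr > 0
  if (!all(keep))
    warning("dropping lag(s) with no displacement pairs: ",
            paste(which(!keep), collapse = ", "))
  msd <- colMeans(lm$means, na.rm = TRUE)[keep]
  sdv <- apply(lm$means, 2, stats::sd, na.rm = TRUE)[keep]
  structure(list(lag_frames = which(keep),
                 lags = which(keep) * ts$frame_interval,
                 msd = unname(msd),
                 sem = unname(sdv / sqrt(n_tr[keep])),
                 n_tracks_per_lag = unname(n_tr[keep]),
                 n_pairs_per_lag = unname(colSums(lm$counts)[keep]),
                 frame_interval = ts$frame_interval),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d lags (%.3g-%.3g s)\n",
              length(x$lags), min(x$lags), max(x$lags)))
  print(data.frame(lag_s = x$lags, msd_um2 = x$msd, sem = x$sem,
                   n_tracks = x$n_tracks_per_lag))
  invisible(x)
}

# OLS slope/intercept of y on x; closed form, no lm() overhead.
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

#' Apparent diffusion constant from the first MSD points
#'
#' Ordinary least squares of MSD versus lag time over the first
#' `n_fit_points` lags (lag 0 excluded, free intercept). The apparent
#' diffusion constant is slope/4 (2D diffusion); the intercept estimates the
#' `4*sigma^2` localization-error offset.
#'
#' @param msd An `msd_result` from [compute_msd()] with at least
#'   `n_fit_points` lags.
#' @param n_fit_points Number of leading MSD points to fit, default 4.
#' @return An object of class `diffusion_estimate` with `d_app` (um^2/s),
#'   `intercept` (um^2), `n_fit_points`, and the number of tracks at lag 1.
#' @export
estimate_diffusion <- function(msd, n_fit_points = 4L) {
  stopifnot(inherits(msd, "msd_result"))
  if (length(msd$lags) < n_fit_points)
    stop(sprintf("MSD has %d lags but n_fit_points = %d",
                 length(msd$lags), n_fit_points))
  sel <- seq_len(n_fit_points)
  fit <- ols_line(msd$lags[sel], msd$msd[sel])
  structure(list(d_app = unname(fit["slope"]) / 4,
                 intercept = unname(fit["intercept"]),
                 n_fit_points = as.integer(n_fit_points),
                 n_tracks = msd$n_tracks_per_lag[1],
                 boot_sd = NA_real_, n_boot = 0L),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> d_app = %.4g um^2/s (intercept %.4g um^2",
              x$d_app, x$intercept))
  if (x$n_boot > 0) cat(sprintf(", bootstrap SD %.3g over %d resamples",
                                x$boot_sd, x$n_boot))
  cat(sprintf("), %d tracks\n", x$n_tracks))
  invisible(x)
}

# d_app and intercept from a precomputed lag matrix restricted to rows
# `rows` (with repetition allowed, for bootstrap). Returns c(d_app, intercept).
d_app_from_lag_matrix <- function(means, lag_times, rows) {
  m <- means[rows, , drop = FALSE]
  mu <- colMeans(m, na.rm = TRUE)
  fit <- ols_line(lag_times, mu)
  c(unname(fit["slope"]) / 4, unname(fit["intercept"]))
}

#' Bootstrap uncertainty for the apparent diffusion constant
#'
#' Resamples whole tracks with replacement `n_boot` times (tracks, not
#' displacements, are the independent units), recomputes the ensemble MSD
#' and its linear fit per replicate, and reports the SD of the replicate
#' `d_app` values. The point estimate comes from the unresampled data.
#'
#' @param ts A [track_set()] with at least 2 tracks.
#' @param n_fit_points MSD points used in the linear fit, default 4.
#' @param n_boot Number of bootstrap resamples, default 1000.
#' @param seed Integer seed; same seed gives identical results.
#' @return A `diffusion_estimate` with `boot_sd` and `n_boot` filled in.
#' @export
bootstrap_diffusion <- function(ts, n_fit_points = 4L, n_boot = 1000L,
                                seed = 1L) {
  stopifnot(inherits(ts, "track_set"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (n_tracks(ts) < 2) stop("need >= 2 tracks to bootstrap")
  lm <- track_lag_matrix(ts, n_fit_points)
  if (any(colSums(!is.na(lm$means)) == 0))
    stop("no displacement pairs at some fitted lag; reduce n_fit_points")
  lag_times <- seq_len(n_fit_points) * ts$frame_interval
  nt <- nrow(lm$means)
  point <- d_app_from_lag_matrix(lm$means, lag_times, seq_len(nt))
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      d_app_from_lag_matrix(lm$means, lag_times,
                            sample.int(nt, nt, replace = TRUE))[1]
    }, numeric(1))
  })
  structure(list(d_app = point[1], intercept = point[2],
                 n_fit_points = as.integer(n_fit_points),
                 n_tracks = nt,
                 boot_sd = stats::sd(boots), n_boot = as.integer(n_boot)),
            class = "diffusion_estimate")
}

#' Permutation test for a difference in apparent diffusion constants
#'
#' The observed statistic is `d_app(a) - d_app(b)`. The null distribution is
#' built by randomly permuting track-to-condition labels (preserving group
#' sizes) and recomputing the statistic; the two-sided p-value uses the
#' add-one convention `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#' Optionally (`boot_within = TRUE`) each permutation replicate additionally
#' resamples tracks with replacement within each permuted group, the
#' "permutation test with bootstrap sampling" variant.
#'
#' @param ts_a,ts_b Non-empty [track_set()]s for the two conditions; frame
#'   intervals must match.
#' @param n_fit_points MSD points in the linear fit, default 4.
#' @param n_perm Number of permutations, default 10000.
#' @param seed Integer seed.
#' @param boot_within Bootstrap within permutation replicates (off by
#'   default).
#' @param keep_null Store the null statistics in the result.
#' @return An object of class `permutation_result` with `stat_observed`,
#'   `p_value`, `n_perm`, and optionally `null_stats`.
#' @export
permutation_test <- function(ts_a, ts_b, n_fit_points = 4L, n_perm = 10000L,
                             seed = 1L, boot_within = FALSE,
                             keep_null = FALSE) {
  stopifnot(inherits(ts_a, "track_set"), inherits(ts_b, "track_set"))
  if (!nrow(ts_a$data) || !nrow(ts_b$data))
    stop("both track sets must be non-empty")
  if (abs(ts_a$frame_interval - ts_b$frame_interval) > 1e-12)
    stop("frame intervals differ between conditions")
  if (n_perm < 1) stop("n_perm must be >= 1")
  la <- track_lag_matrix(ts_a, n_fit_points)
  lb <- track_lag_matrix(ts_b, n_fit_points)
  means <- rbind(la$means, lb$means)
  na <- nrow(la$means); nb <- nrow(lb$means); n <- na + nb
  lag_times <- seq_len(n_fit_points) * ts_a$frame_interval
  stat <- function(rows_a, rows_b) {
    d_app_from_lag_matrix(means, lag_times, rows_a)[1] -
      d_app_from_lag_matrix(means, lag_times, rows_b)[1]
  }
  obs <- stat(seq_len(na), na + seq_len(nb))
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(n)
      ra <- perm[seq_len(na)]; rb <- perm[na + seq_len(nb)]
      if (boot_within) {
        ra <- ra[sample.int(na, na, replace = TRUE)]
        rb <- rb[sample.int(nb, nb, replace = TRUE)]
      }
      stat(ra, rb)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_perm + 1)
  structure(list(stat_observed = obs, p_value = p,
                 n_perm = as.integer(n_perm),
                 null_stats = if (keep_null) null_stats else NULL),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> delta d_app = %.4g um^2/s, p = %.4g (%d permutations)\n",
              x$stat_observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Instantaneous relative growth rate from a cell-length time series
#'
#' Smooths `L(t)` with a centered moving average of `window` points, then
#' computes `dL/dt` by central differences on the smoothed series and the
#' relative (instantaneous) growth rate `(1/L) dL/dt`. Ends where the
#' smoothing window or the central difference is undefined are `NA`.
#'
#' @param times Sample times, seconds, strictly increasing.
#' @param lengths Cell lengths, um, all > 0.
#' @param window Moving-average window in points, default 10.
#' @return An object of class `growth_series` with `times`, `lengths`,
#'   `smoothed_lengths` and `growth_rate` (1/s).
#' @export
growth_rate_from_length <- function(times, lengths, window = 10L) {
  stopifnot(is.numeric(times), is.numeric(lengths),
            length(times) == length(lengths))
  if (any(lengths <= 0)) stop("lengths must be > 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  if (n < window + 2) stop("need at least window + 2 samples")
  sm <- stats::filter(lengths, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  dldt <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  dldt[idx] <- (sm[idx + 1] - sm[idx - 1]) / (times[idx + 1] - times[idx - 1])
  structure(list(times = times, lengths = lengths, smoothed_lengths = sm,
                 growth_rate = dldt / sm),
            class = "growth_series")
}

#' Local MSD slope ratio (saturation diagnostic)
#'
#' Compares the OLS slope of the MSD over a late lag window against the
#' local slope at the first lag, estimated by the forward difference
#' `(msd(2) - msd(1)) / (t2 - t1)` so that the constant `4*sigma^2`
#' localization-error offset cancels. Free diffusion gives a ratio near 1;
#' a ratio well below 1 indicates saturation of the MSD, as produced by
#' TIRF-field truncation of a fast/slow molecule population.
#'
#' @param msd An `msd_result` with at least 2 leading lags.
#' @param late_min Start of the late window in seconds, default 0.21.
#' @return List with `early_slope`, `late_slope` (um^2/s) and `ratio`.
#' @export
msd_slope_ratio <- function(msd, late_min = 0.21) {
  stopifnot(inherits(msd, "msd_result"))
  late <- which(msd$lags >= late_min)
  if (length(late) < 2) stop("need >= 2 MSD lags at or beyond late_min")
  if (length(msd$lags) < 2 || msd$lag_frames[1] != 1L)
    stop("early slope needs MSD lags 1 and 2")
  early_slope <- (msd$msd[2] - msd$msd[1]) / (msd$lags[2] - msd$lags[1])
  late_slope <- ols_line(msd$lags[late], msd$msd[late])["slope"]
  list(early_slope = unname(early_slope), late_slope = unname(late_slope),
       ratio = unname(late_slope / early_slope))
}
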