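# Step-size (jump-distance) CDF analysis.
#
# For a molecule diffusing freely in 2D with constant D and localized with
# per-coordinate error SD sigma, the squared displacement r^2 over a lag t
# is exponentially distributed with mean 4*D*t + 4*sigma^2 (each coordinate
# difference is N(0, 2Dt + 2sigma^2)). Hence
#   P(R^2 <= r^2) = 1 - exp(-r^2 / (4 D t + 4 sigma^2))
# and a two-species population mixes two such terms with weight alpha on
# the fast species. The empirical CDFs at several lags are fit JOINTLY by
# one parameter vector: pooling lags is what separates D (scales with t)
# from sigma (does not).

#' Pool squared step sizes per lag across tracks
#'
#' For each lag `k` (frames), collects every overlapping squared displacement
#' between localizations exactly `k` frames apart, pooled across all tracks
#' of the set. The originating track index is kept so fits can be
#' bootstrapped over tracks.
#'
#' @param ts A [track_set()].
#' @param lags Integer frame lags, default `1:4` (30, 60, 90, 120 ms at the
#'   default 30-ms frame interval).
#' @return An object of class `step_size_data`: list with `lags_frames`,
#'   `lag_times` (s), `r2` (list of numeric vectors, um^2), `track_index`
#'   (list of integer vectors), `n_per_lag`, `frame_interval`.
#' @export
collect_step_sizes <- function(ts, lags = 1:4) {
  stopifnot(inherits(ts, "track_set"), all(lags >= 1))
  lags <- sort(unique(as.integer(lags)))
  trs <- split_tracks(ts)
  r2 <- vector("list", length(lags))
  tix <- vector("list", length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    acc <- vector("list", length(trs))
    acc_ix <- vector("list", length(trs))
    for (i in seq_along(trs)) {
      tr <- trs[[i]]
      f <- tr$frame
      j <- match(f + k, f)
      ok <- !is.na(j)
      if (!any(ok)) next
      jj <- j[ok]; ii <- which(ok)
      v <- (tr$x_um[jj] - tr$x_um[ii])^2 + (tr$y_um[jj] - tr$y_um[ii])^2
      acc[[i]] <- v
      acc_ix[[i]] <- rep.int(i, length(v))
    }
    r2[[li]] <- unlist(acc, use.names = FALSE)
    tix[[li]] <- unlist(acc_ix, use.names = FALSE)
  }
  n_per_lag <- vapply(r2, length, integer(1))
  if (n_per_lag[1] == 0)
    stop("no track is long enough for the smallest requested lag")
  structure(list(lags_frames = lags,
                 lag_times = lags * ts$frame_interval,
                 r2 = r2, track_index = tix, n_per_lag = n_per_lag,
                 n_tracks = length(trs),
                 frame_interval = ts$frame_interval),
            class = "step_size_data")
}

#' @export
print.step_size_data <- function(x, ...) {
  cat("<step_size_data>\n")
  print(data.frame(lag_frames = x$lags_frames, lag_s = x$lag_times,
                   n_steps = x$n_per_lag))
  invisible(x)
}

#' One-species step-size CDF model
#'
#' `P(R^2 <= r2) = 1 - exp(-r2 / (4*D*t + 4*sigma^2))`. With a degenerate
#' scale (`D = sigma = 0`) the CDF is the unit step at `r2 = 0`.
#'
#' @param r2 Squared displacement(s), um^2, >= 0.
#' @param t Lag time, s, > 0.
#' @param D Diffusion constant, um^2/s, >= 0.
#' @param sigma Per-coordinate localization error SD, um, >= 0.
#' @return Probabilities in `[0, 1]`, same length as `r2`.
#' @export
model_cdf_one <- function(r2, t, D, sigma) {
  stopifnot(all(r2 >= 0), t > 0, D >= 0, sigma >= 0)
  s <- 4 * D * t + 4 * sigma^2
  if (s == 0) return(as.numeric(r2 >= 0))   # step function at 0
  1 - exp(-r2 / s)
}

#' Two-species step-size CDF model
#'
#' Mixture of two one-species terms with weight `alpha` on the fast species:
#' `1 - (alpha*exp(-r2/(4*D1*t + 4*sigma^2)) +
#' (1-alpha)*exp(-r2/(4*D2*t + 4*sigma^2)))`.
#'
#' @inheritParams model_cdf_one
#' @param D1 Fast diffusion constant, um^2/s.
#' @param D2 Slow diffusion constant, um^2/s (`D1 >= D2` by convention).
#' @param alpha Mobile (fast) fraction in `[0, 1]`.
#' @return Probabilities in `[0, 1]`.
#' @export
model_cdf_two <- function(r2, t, D1, D2, alpha, sigma) {
  stopifnot(all(r2 >= 0), t > 0, D1 >= 0, D2 >= 0,
            alpha >= 0, alpha <= 1, sigma >= 0)
  alpha * model_cdf_one(r2, t, D1, sigma) +
    (1 - alpha) * model_cdf_one(r2, t, D2, sigma)
}

# ---- joint nonlinear least squares machinery -------------------------------

# Precompute, per lag, sorted r2 and the empirical CDF heights i/n
# (MATLAB's ecdf convention evaluated at the observed points), optionally
# thinned to a fixed-quantile grid of size grid_n per lag.
cdf_fit_points <- function(data, grid_n = NULL) {
  lapply(seq_along(data$lags_frames), function(li) {
    r2 <- sort(data$r2[[li]])
    n <- length(r2)
    if (n == 0) return(NULL)
    fhat <- seq_len(n) / n
    if (!is.null(grid_n) && n > grid_n) {
      ix <- unique(round(seq(1, n, length.out = grid_n)))
      r2 <- r2[ix]; fhat <- fhat[ix]
    }
    list(r2 = r2, fhat = fhat, t = data$lag_times[li])
  })
}

# Objective (RSS) and analytic gradient for the two-species model with
# parameter vector th = c(D1, D2, alpha, sigma). The one-species model is
# the same code path with alpha fixed at 1 and D2 unused.
cdf_objective <- function(points, two_species) {
  function(th) {
    D1 <- th[1]; D2 <- if (two_species) th[2] else 0
    alpha <- if (two_species) th[3] else 1
    sigma <- th[length(th)]
    rss <- 0
    for (p in points) {
      if (is.null(p)) next
      s1 <- 4 * D1 * p$t + 4 * sigma^2
      A <- exp(-p$r2 / pmax(s1, 1e-300))
      if (two_species) {
        s2 <- 4 * D2 * p$t + 4 * sigma^2
        B <- exp(-p$r2 / pmax(s2, 1e-300))
        e <- p$fhat - (1 - alpha * A - (1 - alpha) * B)
      } else {
        e <- p$fhat - (1 - A)
      }
      rss <- rss + sum(e * e)
    }
    rss
  }
}

cdf_gradient <- function(points, two_species) {
  function(th) {
    D1 <- th[1]; D2 <- if (two_species) th[2] else 0
    alpha <- if (two_species) th[3] else 1
    sigma <- th[length(th)]
    g <- numeric(length(th))
    for (p in points) {
      if (is.null(p)) next
      s1 <- pmax(4 * D1 * p$t + 4 * sigma^2, 1e-300)
      A <- exp(-p$r2 / s1)
      dA_ds1 <- A * p$r2 / s1^2
      if (two_species) {
        s2 <- pmax(4 * D2 * p$t + 4 * sigma^2, 1e-300)
        B <- exp(-p$r2 / s2)
        dB_ds2 <- B * p$r2 / s2^2
        e <- p$fhat - (1 - alpha * A - (1 - alpha) * B)
        # model = 1 - alpha*A - (1-alpha)*B; residual e = fhat - model,
        # dRSS/dtheta = -2*sum(e * dmodel/dtheta)
        dm_dD1 <- -alpha * dA_ds1 * 4 * p$t
        dm_dD2 <- -(1 - alpha) * dB_ds2 * 4 * p$t
        dm_da <- -(A - B)
        dm_dsig <- -(alpha * dA_ds1 + (1 - alpha) * dB_ds2) * 8 * sigma
        g[1] <- g[1] - 2 * sum(e * dm_dD1)
        g[2] <- g[2] - 2 * sum(e * dm_dD2)
        g[3] <- g[3] - 2 * sum(e * dm_da)
        g[4] <- g[4] - 2 * sum(e * dm_dsig)
      } else {
        e <- p$fhat - (1 - A)
        dm_dD <- -dA_ds1 * 4 * p$t
        dm_dsig <- -dA_ds1 * 8 * sigma
        g[1] <- g[1] - 2 * sum(e * dm_dD)
        g[2] <- g[2] - 2 * sum(e * dm_dsig)
      }
    }
    g
  }
}

# Log-likelihood of the pooled squared steps under the exponential-mixture
# density implied by the CDF model (r^2 ~ alpha*Exp(s1) + (1-alpha)*Exp(s2)
# per lag, scale s = 4*D*t + 4*sigma^2). Used for the BIC: residuals of the
# stacked empirical CDFs are strongly autocorrelated, so a Gaussian-RSS
# pseudo-likelihood badly overstates the evidence for extra parameters.
step_loglik <- function(data, th, two_species) {
  ll <- 0
  for (li in seq_along(data$lags_frames)) {
    r2 <- data$r2[[li]]
    if (!length(r2)) next
    t <- data$lag_times[li]
    if (two_species) {
      s1 <- max(4 * th[1] * t + 4 * th[4]^2, 1e-300)
      s2 <- max(4 * th[2] * t + 4 * th[4]^2, 1e-300)
      dens <- th[3] / s1 * exp(-r2 / s1) + (1 - th[3]) / s2 * exp(-r2 / s2)
    } else {
      s <- max(4 * th[1] * t + 4 * th[2]^2, 1e-300)
      dens <- exp(-r2 / s) / s
    }
    ll <- ll + sum(log(pmax(dens, 1e-300)))
  }
  ll
}

# Deterministic multi-start grid; screened by initial objective value and
# only the best n_full starts optimized fully.
cdf_start_grid <- function(two_species) {
  Ds <- 10^seq(-3, 0, by = 1)
  sigs <- c(0.02, 0.04)
  if (!two_species) {
    as.matrix(expand.grid(D = Ds, sigma = sigs))
  } else {
    g <- expand.grid(D1 = Ds, D2 = c(0, Ds), alpha = c(0.25, 0.5, 0.75),
                     sigma = sigs)
    as.matrix(g[g$D1 > g$D2, , drop = FALSE])
  }
}

#' Fit step-size CDFs jointly across lags by nonlinear least squares
#'
#' A single parameter vector is fit to the empirical CDFs of all lags
#' simultaneously, minimizing the sum of squared residuals (empirical minus
#' model CDF) evaluated at every observed squared displacement (or on a
#' fixed-quantile grid per lag via `grid_n`). Parameters are bounded
#' (`D >= 0`, `alpha` in `[0, 1]`, `sigma >= 0`) with L-BFGS-B and analytic
#' gradients; optimization is restarted from a deterministic grid of initial
#' values and the best final RSS wins (`D1 >= D2` enforced by relabeling).
#'
#' @param data A `step_size_data` from [collect_step_sizes()] with >= 2
#'   populated lags.
#' @param model `"one_species"` or `"two_species"`.
#' @param grid_n Optional per-lag evaluation grid size (quantile-thinned);
#'   `NULL` (default) evaluates at every observed step.
#' @param n_full Number of screened starts optimized fully, default 5.
#' @param seed Accepted for interface stability; the default fit is fully
#'   deterministic and does not consume randomness.
#' @return An object of class `cdf_fit`: parameters (`D`, `sigma` or `D1`,
#'   `D2`, `alpha`, `sigma`), `rss` (on the evaluation points), `n_points`,
#'   `bic`, `model`, and `convergence` diagnostics. The BIC is computed from
#'   the exponential-mixture log-likelihood of the pooled squared steps at
#'   the fitted parameters (not from the CDF residuals, which are strongly
#'   autocorrelated and would overstate the evidence for extra parameters).
#' @export
fit_cdf <- function(data, model = c("two_species", "one_species"),
                    grid_n = NULL, n_full = 5L, seed = NULL) {
  stopifnot(inherits(data, "step_size_data"))
  model <- match.arg(model)
  two <- model == "two_species"
  if (sum(data$n_per_lag > 0) < 2)
    stop("need at least 2 populated lags for a joint CDF fit")
  points <- cdf_fit_points(data, grid_n = grid_n)
  n_points <- sum(vapply(points, function(p) length(p$r2), integer(1)))
  obj <- cdf_objective(points, two)
  grd <- cdf_gradient(points, two)
  starts <- cdf_start_grid(two)
  lower <- if (two) c(0, 0, 0, 1e-6) else c(0, 1e-6)
  upper <- if (two) c(Inf, Inf, 1, Inf) else c(Inf, Inf)

  init_vals <- apply(starts, 1, obj)
  order_ix <- order(init_vals)
  full_ix <- order_ix[seq_len(min(n_full, nrow(starts)))]
  best <- NULL
  n_converged <- 0L
  for (i in full_ix) {
    fit <- tryCatch(
      stats::optim(pmax(starts[i, ], lower), obj, grd, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_converged <- n_converged + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || n_converged == 0L)
    stop(errorCondition(
      paste0("CDF fit failed to converge from any of the ", length(full_ix),
             " screened starts (model ", model,
             "); check the input step sizes"),
      class = c("sptdiff_convergence_error", "error", "condition")))
  th <- best$par
  if (two && th[2] > th[1]) {            # relabel so D1 >= D2
    th <- c(th[2], th[1], 1 - th[3], th[4])
  }
  rss <- best$value
  k <- if (two) 4L else 2L
  n_steps <- sum(data$n_per_lag)
  bic <- -2 * step_loglik(data, th, two) + k * log(n_steps)
  params <- if (two) list(D1 = th[1], D2 = th[2], alpha = th[3],
                          sigma = th[4])
            else list(D = th[1], sigma = th[2])
  structure(c(params,
              list(model = model, rss = rss, n_points = n_points, bic = bic,
                   n_params = k,
                   convergence = list(n_starts_screened = nrow(starts),
                                      n_starts_optimized = length(full_ix),
                                      n_converged = n_converged,
                                      code = best$convergence))),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  if (x$model == "two_species") {
    cat(sprintf(
      "<cdf_fit two_species> D1 = %.4g, D2 = %.4g um^2/s, alpha = %.3f, sigma = %.4g um\n",
      x$D1, x$D2, x$alpha, x$sigma))
  } else {
    cat(sprintf("<cdf_fit one_species> D = %.4g um^2/s, sigma = %.4g um\n",
                x$D, x$sigma))
  }
  cat(sprintf("  rss = %.5g over %d points, BIC = %.2f\n",
              x$rss, x$n_points, x$bic))
  invisible(x)
}

#' Compare one- and two-species CDF fits
#'
#' Primary criterion: lower BIC. A nested F-test p-value is reported as a
#' secondary diagnostic (the one-species model is the two-species model with
#' `alpha = 1`).
#'
#' @param fit_one,fit_two `cdf_fit` objects for the one- and two-species
#'   models, fit on identical data.
#' @return List with `chosen` (`"one_species"`/`"two_species"`),
#'   `delta_bic` (BIC(two) - BIC(one); negative favours two), both RSS
#'   values, and `f_test_p`.
#' @export
compare_models <- function(fit_one, fit_two) {
  stopifnot(inherits(fit_one, "cdf_fit"), inherits(fit_two, "cdf_fit"),
            fit_one$model == "one_species", fit_two$model == "two_species")
  if (fit_one$n_points != fit_two$n_points)
    stop("fits were not computed on the same data (n_points differ)")
  n <- fit_one$n_points
  df1 <- fit_two$n_params - fit_one$n_params
  df2 <- n - fit_two$n_params
  fstat <- ((fit_one$rss - fit_two$rss) / df1) / (fit_two$rss / df2)
  f_p <- if (fstat > 0) stats::pf(fstat, df1, df2, lower.tail = FALSE) else 1
  delta <- fit_two$bic - fit_one$bic
  list(chosen = if (delta < 0) "two_species" else "one_species",
       delta_bic = delta, rss_one = fit_one$rss, rss_two = fit_two$rss,
       f_stat = fstat, f_test_p = f_p)
}

#' Track-level bootstrap for CDF fit parameters
#'
#' Resamples tracks with replacement, rebuilds the pooled step sizes per
#' replicate, and refits (warm-started from the point estimate on a
#' quantile grid for speed). Reports the SD of each parameter across
#' replicates.
#'
#' @param ts A [track_set()].
#' @param model `"one_species"` or `"two_species"`.
#' @param lags Frame lags, default `1:4`.
#' @param n_boot Number of resamples, default 100.
#' @param seed Integer seed.
#' @param grid_n Evaluation grid per lag for replicate fits, default 200.
#' @return List with the point-estimate `fit` and `boot_sd`, a named vector
#'   of parameter SDs.
#' @export
bootstrap_cdf <- function(ts, model = "two_species", lags = 1:4,
                          n_boot = 100L, seed = 1L, grid_n = 200L) {
  stopifnot(inherits(ts, "track_set"))
  data <- collect_step_sizes(ts, lags)
  point <- fit_cdf(data, model = model)
  two <- model == "two_species"
  th0 <- if (two) c(point$D1, point$D2, point$alpha, point$sigma)
         else c(point$D, point$sigma)
  lower <- if (two) c(0, 0, 0, 1e-6) else c(0, 1e-6)
  upper <- if (two) c(Inf, Inf, 1, Inf) else c(Inf, Inf)
  nt <- data$n_tracks
  # indices of each track's steps per lag, precomputed once
  by_track <- lapply(seq_along(data$lags_frames), function(li) {
    sel <- factor(data$track_index[[li]], levels = seq_len(nt))
    split(seq_along(data$track_index[[li]]), sel)
  })
  reps <- withr::with_seed(seed, {
    replicate(n_boot, {
      pick <- sample.int(nt, nt, replace = TRUE)
      bdat <- data
      for (li in seq_along(data$lags_frames)) {
        keep <- unlist(by_track[[li]][pick], use.names = FALSE)
        bdat$r2[[li]] <- data$r2[[li]][keep]
      }
      bdat$n_per_lag <- vapply(bdat$r2, length, integer(1))
      pts <- cdf_fit_points(bdat, grid_n = grid_n)
      fit <- tryCatch(
        stats::optim(pmax(th0, lower), cdf_objective(pts, two),
                     cdf_gradient(pts, two), method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 300, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(fit)) rep(NA_real_, length(th0)) else {
        th <- fit$par
        if (two && th[2] > th[1]) th <- c(th[2], th[1], 1 - th[3], th[4])
        th
      }
    })
  })
  boot_sd <- apply(reps, 1, stats::sd, na.rm = TRUE)
  names(boot_sd) <- if (two) c("D1", "D2", "alpha", "sigma")
                    else c("D", "sigma")
  list(fit = point, boot_sd = boot_sd, n_boot = n_boot)
}
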