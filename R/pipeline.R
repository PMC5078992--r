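# Reproducible end-to-end runs: simulate/read -> length filter -> MSD +
# bootstrap -> step-size CDF fits -> model choice, with every artifact
# written next to the echoed configuration and seed.

#' Read a run or simulation configuration from JSON or YAML
#'
#' Format is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml: ", path)
}

#' Build a [simulation_config()] from a plain config list
#'
#' Accepts the nested structure `list(geometry = ..., model = ...,
#' n_molecules = ..., seed = ...)` as parsed from JSON/YAML; unspecified
#' fields take the documented defaults. A seed is mandatory.
#'
#' @param cfg Named list.
#' @return A `simulation_config`.
#' @export
simulation_config_from_list <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("simulation config requires a seed")
  geom <- do.call(cell_geometry, as.list(cfg$geometry))
  model <- do.call(diffusion_model, as.list(cfg$model))
  extra <- cfg[setdiff(names(cfg), c("geometry", "model"))]
  do.call(simulation_config, c(list(geometry = geom, model = model), extra))
}

# canonical JSON used both for echoing configs and hashing them
write_config_json <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unname(tools::md5sum(path))
}

default_run_config <- function() {
  list(condition = "condition",
       filter = list(min_points = 4L, max_points = 12L),
       msd = list(max_lag_frames = 10L, n_fit_points = 4L),
       bootstrap = list(n_boot = 1000L),
       cdf = list(lags = 1:4, grid_n = NULL))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

# Resolve a run config's input into a track_set (simulating if needed).
resolve_tracks <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$tracks_csv)) {
    read_tracks(inp$tracks_csv, frame_interval = cfg$frame_interval)
  } else if (!is.null(inp$simulation)) {
    sim_cfg <- inp$simulation
    if (is.null(sim_cfg$seed)) sim_cfg$seed <- cfg$seed
    sim <- simulate_tracks(simulation_config_from_list(sim_cfg),
                           condition = cfg$condition %||% "simulated")
    sim$tracks
  } else stop("run config input must contain tracks_csv or simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain nested lists for JSON serialization
as_plain <- function(x) {
  if (is.list(x)) lapply(unclass(x), as_plain) else x
}

#' Run the full single-condition analysis
#'
#' Simulates (or reads) tracks, applies the track-length filter, computes
#' the ensemble MSD, the apparent diffusion constant with bootstrap SD, the
#' one- and two-species step-size CDF fits and their comparison. All
#' artifacts (MSD table, per-lag empirical-vs-model CDF tables, JSON report
#' carrying the echoed config and its MD5 hash) are written to `out_dir`
#' when given; a rerun with the same config is byte-identical.
#'
#' @param cfg Run configuration: a named list (see the vignette) or a path
#'   to a JSON/YAML file. Must carry a `seed`.
#' @param out_dir Optional output directory (created if missing).
#' @return The report, an object of class `spt_report` (named list).
#' @export
run_single_condition <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- merge_config(default_run_config(), cfg)
  if (is.null(cfg$seed)) stop("run config requires a seed")

  log_stage <- function(fmt, ...) message(sprintf(paste0("[sptdiff] ", fmt), ...))

  ts <- resolve_tracks(cfg)
  n_in <- n_tracks(ts)
  log_stage("input: %d tracks, %d localizations", n_in, nrow(ts$data))
  ts <- filter_by_length(ts, cfg$filter$min_points, cfg$filter$max_points)
  n_kept <- n_tracks(ts)
  log_stage("length filter [%d, %s]: %d -> %d tracks",
            cfg$filter$min_points, as.character(cfg$filter$max_points),
            n_in, n_kept)
  if (n_kept == 0)
    stop("no tracks remain after length filtering; nothing to analyse")

  msd <- compute_msd(ts, cfg$msd$max_lag_frames)
  est <- bootstrap_diffusion(ts, n_fit_points = cfg$msd$n_fit_points,
                             n_boot = cfg$bootstrap$n_boot, seed = cfg$seed)
  log_stage("d_app = %.4g +/- %.2g um^2/s (%d bootstrap samples)",
            est$d_app, est$boot_sd, est$n_boot)

  steps <- collect_step_sizes(ts, lags = cfg$cdf$lags)
  grid_n <- cfg$cdf$grid_n
  fit1 <- fit_cdf(steps, model = "one_species", grid_n = grid_n)
  fit2 <- fit_cdf(steps, model = "two_species", grid_n = grid_n)
  choice <- compare_models(fit1, fit2)
  log_stage("CDF model choice: %s (delta BIC %.1f)", choice$chosen,
            choice$delta_bic)

  report <- structure(list(
    condition = cfg$condition,
    seed = cfg$seed,
    n_tracks_input = n_in, n_tracks_analysed = n_kept,
    msd = list(lags = msd$lags, msd = msd$msd, sem = msd$sem,
               n_tracks_per_lag = msd$n_tracks_per_lag),
    diffusion = list(d_app = est$d_app, intercept = est$intercept,
                     boot_sd = est$boot_sd, n_boot = est$n_boot,
                     n_fit_points = est$n_fit_points),
    cdf_fit_one = unclass(fit1)[c("D", "sigma", "rss", "bic", "n_points")],
    cdf_fit_two = unclass(fit2)[c("D1", "D2", "alpha", "sigma", "rss",
                                  "bic", "n_points")],
    model_choice = choice,
    config = cfg), class = "spt_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- write_config_json(cfg, file.path(out_dir, "config.json"))
    report$config_md5 <- hash
    write_msd_csv(msd, file.path(out_dir, "msd.csv"))
    write_cdf_tables(steps, fit1, fit2, file.path(out_dir, "cdf_lag"))
    jsonlite::write_json(as_plain(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

write_msd_csv <- function(msd, path) {
  lines <- c("lag_frames,lag_s,msd_um2,sem_um2,n_tracks,n_pairs",
             sprintf("%d,%.6f,%.8f,%.8f,%d,%d", msd$lag_frames, msd$lags,
                     msd$msd, msd$sem, msd$n_tracks_per_lag,
                     msd$n_pairs_per_lag))
  writeLines(lines, path)
  invisible(path)
}

# per-lag empirical vs model CDF tables (plotting-ready)
write_cdf_tables <- function(steps, fit1, fit2, stem) {
  for (li in seq_along(steps$lags_frames)) {
    r2 <- sort(steps$r2[[li]])
    if (!length(r2)) next
    fhat <- seq_along(r2) / length(r2)
    t <- steps$lag_times[li]
    m1 <- model_cdf_one(r2, t, fit1$D, fit1$sigma)
    m2 <- model_cdf_two(r2, t, fit2$D1, fit2$D2, fit2$alpha, fit2$sigma)
    lines <- c("r2_um2,ecdf,model_one,model_two",
               sprintf("%.8f,%.8f,%.8f,%.8f", r2, fhat, m1, m2))
    writeLines(lines, sprintf("%s%d.csv", stem, steps$lags_frames[li]))
  }
  invisible(stem)
}

#' Run a two-condition comparison
#'
#' Runs [run_single_condition()] for each config, then a permutation test on
#' the apparent diffusion constants and the difference in fitted mobile
#' fractions between the two-species CDF fits.
#'
#' @param cfg_a,cfg_b Run configurations (lists or file paths).
#' @param out_dir Optional output directory; per-condition artifacts land in
#'   `a/` and `b/` subdirectories.
#' @param n_perm Permutations for the diffusion-difference test.
#' @param seed Seed for the permutation test (defaults to `cfg_a$seed`).
#' @return An object of class `spt_comparison`.
#' @export
run_comparison <- function(cfg_a, cfg_b, out_dir = NULL, n_perm = 10000L,
                           seed = NULL) {
  if (is.character(cfg_a)) cfg_a <- read_config(cfg_a)
  if (is.character(cfg_b)) cfg_b <- read_config(cfg_b)
  rep_a <- run_single_condition(cfg_a,
                                if (!is.null(out_dir)) file.path(out_dir, "a"))
  rep_b <- run_single_condition(cfg_b,
                                if (!is.null(out_dir)) file.path(out_dir, "b"))
  cfg_a <- rep_a$config; cfg_b <- rep_b$config
  ts_a <- filter_by_length(resolve_tracks(cfg_a), cfg_a$filter$min_points,
                           cfg_a$filter$max_points)
  ts_b <- filter_by_length(resolve_tracks(cfg_b), cfg_b$filter$min_points,
                           cfg_b$filter$max_points)
  perm <- permutation_test(ts_a, ts_b,
                           n_fit_points = cfg_a$msd$n_fit_points,
                           n_perm = n_perm, seed = seed %||% cfg_a$seed)
  out <- structure(list(
    condition_a = rep_a$condition, condition_b = rep_b$condition,
    report_a = rep_a, report_b = rep_b,
    delta_d_app = rep_a$diffusion$d_app - rep_b$diffusion$d_app,
    permutation = list(stat_observed = perm$stat_observed,
                       p_value = perm$p_value, n_perm = perm$n_perm),
    delta_alpha = rep_a$cdf_fit_two$alpha - rep_b$cdf_fit_two$alpha),
    class = "spt_comparison")
  if (!is.null(out_dir)) {
    jsonlite::write_json(as_plain(out), file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.spt_report <- function(x, ...) {
  cat(sprintf("<spt_report> condition '%s': %d tracks analysed\n",
              x$condition, x$n_tracks_analysed))
  cat(sprintf("  d_app = %.4g +/- %.2g um^2/s; CDF model: %s (alpha = %.3f)\n",
              x$diffusion$d_app, x$diffusion$boot_sd,
              x$model_choice$chosen, x$cdf_fit_two$alpha))
  invisible(x)
}

#' @export
print.spt_comparison <- function(x, ...) {
  cat(sprintf("<spt_comparison> '%s' vs '%s'\n", x$condition_a, x$condition_b))
  cat(sprintf("  delta d_app = %.4g um^2/s (p = %.4g, %d permutations); delta alpha = %.3f\n",
              x$delta_d_app, x$permutation$p_value, x$permutation$n_perm,
              x$delta_alpha))
  invisible(x)
}
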