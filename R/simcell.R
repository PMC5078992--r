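# Monte Carlo simulation of membrane-protein tracks on a cylindrical cell.
#
# Coordinates: axial z' along the cylinder axis (reflecting caps), angle
# theta around the axis with theta = 0 at the coverslip contact line. Arc
# length radius*theta and the axial coordinate form a locally flat 2D
# surface, so free diffusion is two independent 1D Brownian motions.

# Vectorized core shared by step_surface() and simulate_tracks().
# state_fast is logical; returns updated vectors. Angle is kept unwrapped.
step_surface_vec <- function(axial, angle, state_fast, model, geometry, dt,
                             kinetic = TRUE) {
  n <- length(axial)
  d <- ifelse(state_fast, model$d_fast, model$d_slow)
  sd_step <- sqrt(2 * d * dt)
  axial <- axial + stats::rnorm(n, 0, sd_step)
  angle <- angle + stats::rnorm(n, 0, sd_step) / geometry$radius

  # reflect at the caps (repeat in case of a wild step across the full cell)
  half <- geometry$length / 2
  repeat {
    over <- axial > half
    under <- axial < -half
    if (!any(over) && !any(under)) break
    axial[over] <- 2 * half - axial[over]
    axial[under] <- -2 * half - axial[under]
  }

  if (kinetic) {
    ktot <- model$rate_fast_to_slow + model$rate_slow_to_fast
    if (ktot > 0) {
      # exact two-state CTMC transition probabilities over dt
      decay <- 1 - exp(-ktot * dt)
      p_fs <- model$rate_fast_to_slow / ktot * decay
      p_sf <- model$rate_slow_to_fast / ktot * decay
      u <- stats::runif(n)
      flip <- ifelse(state_fast, u < p_fs, u < p_sf)
      state_fast <- xor(state_fast, flip)
    }
  }
  list(axial = axial, angle = angle, state_fast = state_fast)
}

#' Advance one molecule on the membrane by one time step
#'
#' Axial and arc-length displacements are independent zero-mean Gaussians
#' with variance `2 * D(state) * dt`, where D is the diffusion constant of
#' the current motion state; the state is then updated by an exact two-state
#' continuous-time Markov jump over `dt`. The axial coordinate reflects at
#' the cylinder caps; the angle accumulates without wrapping (wrap at
#' projection time).
#'
#' @param state A [surface_state()].
#' @param model A [diffusion_model()].
#' @param geometry A [cell_geometry()].
#' @param dt Time step in seconds, > 0.
#' @param kinetic If `FALSE`, suppress state switching (static mixture mode).
#' @return The updated `surface_state`.
#' @export
step_surface <- function(state, model, geometry, dt, kinetic = TRUE) {
  stopifnot(inherits(state, "surface_state"),
            inherits(model, "diffusion_model"),
            inherits(geometry, "cell_geometry"), dt > 0)
  out <- step_surface_vec(state$axial, state$angle,
                          state$motion_state == "fast",
                          model, geometry, dt, kinetic = kinetic)
  surface_state(out$axial, out$angle,
                if (out$state_fast) "fast" else "slow")
}

#' Project a surface position into the image plane and test TIRF visibility
#'
#' Image x is the axial coordinate; image y is `radius * sin(angle)`; the
#' height above the coverslip is `z = radius * (1 - cos(angle))`, and the
#' molecule is visible iff `z <= tirf_depth`.
#'
#' @param state A [surface_state()] (angle may be unwrapped).
#' @param geometry A [cell_geometry()].
#' @return A list with `visible` (logical), `image_xy` (numeric length 2, um)
#'   and `z` (height above the coverslip, um).
#' @export
project_and_observe <- function(state, geometry) {
  stopifnot(inherits(state, "surface_state"),
            inherits(geometry, "cell_geometry"))
  th <- state$angle %% (2 * pi)
  z <- geometry$radius * (1 - cos(th))
  list(visible = z <= geometry$tirf_depth,
       image_xy = c(state$axial, geometry$radius * sin(th)),
       z = z)
}

#' Simulate an ensemble of single-molecule tracks
#'
#' Each molecule starts at a uniformly random visible surface position with
#' its motion state drawn fast with probability `alpha` (fixed for life in
#' static mixture mode). Per camera frame, `substeps_per_frame` Brownian
#' substeps are taken and the molecule is then observed; its track is the
#' first maximal run of consecutive visible frames, truncated by geometric
#' per-frame photobleaching survival and by `track_max_points`, and discarded
#' if shorter than `track_min_points`. I.i.d. Gaussian localization noise of
#' SD `sigma_loc` is added per observed coordinate. In `observe = "surface"`
#' mode the recorded positions are the unwrapped in-membrane coordinates
#' (axial, radius*angle) and the whole surface is treated as visible.
#'
#' @param config A [simulation_config()]; its `seed` makes the output
#'   fully deterministic.
#' @param condition Condition label stored in the track table.
#' @return An object of class `spt_sim`: a list with `tracks` (a
#'   [track_set()] of noisy observed positions), `truth` (data.frame of
#'   per-frame ground truth: unwrapped surface coordinates, height `z_um`,
#'   and `motion_state`), and the `config`. If no track survives filtering,
#'   `tracks` is an empty track_set and a warning is raised.
#' @export
simulate_tracks <- function(config, condition = "simulated") {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  model <- config$model
  n <- config$n_molecules
  kinetic <- config$mixture_mode == "kinetic"
  surface_mode <- config$observe == "surface"
  dt_sub <- model$frame_interval / config$substeps_per_frame

  withr::with_seed(config$seed, {
    # initial positions uniform on the visible band (area element ~ dz dtheta)
    th_max <- if (surface_mode) pi else visibility_half_angle(geom)
    axial <- stats::runif(n, -geom$length / 2, geom$length / 2)
    angle <- stats::runif(n, -th_max, th_max)
    state_fast <- stats::runif(n) < model$alpha
    if (!kinetic || model$rate_fast_to_slow + model$rate_slow_to_fast == 0)
      kinetic <- FALSE

    # photobleaching: number of frames survived, geometric, capped
    surv <- config$bleach_survival_per_frame
    life <- if (surv >= 1) rep(config$n_frames_max, n)
            else pmin(1L + stats::rgeom(n, 1 - surv), config$n_frames_max)

    nf <- config$n_frames_max
    ax_rec <- matrix(NA_real_, n, nf)
    an_rec <- matrix(NA_real_, n, nf)
    st_rec <- matrix(NA, n, nf)
    ax_rec[, 1] <- axial; an_rec[, 1] <- angle; st_rec[, 1] <- state_fast
    for (f in 2:nf) {
      for (s in seq_len(config$substeps_per_frame)) {
        stp <- step_surface_vec(axial, angle, state_fast, model, geom,
                                dt_sub, kinetic = kinetic)
        axial <- stp$axial; angle <- stp$angle; state_fast <- stp$state_fast
      }
      ax_rec[, f] <- axial; an_rec[, f] <- angle; st_rec[, f] <- state_fast
    }

    # visibility at frame times; first maximal visible run per molecule
    if (surface_mode) {
      vis <- matrix(TRUE, n, nf)
    } else {
      z <- geom$radius * (1 - cos(an_rec %% (2 * pi)))
      vis <- z <= geom$tirf_depth
    }
    # molecules start visible by construction; run ends at first invisible
    # frame or at bleaching, whichever comes first
    run_len <- integer(n)
    for (i in seq_len(n)) {
      lim <- life[i]
      hidden <- which(!vis[i, seq_len(lim)])
      run_len[i] <- if (length(hidden)) hidden[1] - 1L else lim
    }
    run_len <- pmin(run_len, config$track_max_points)
    keep <- run_len >= config$track_min_points

    if (!any(keep)) {
      warning("simulation retained zero tracks after length filtering")
      empty <- track_set(data.frame(track_id = character(),
                                    condition = character(),
                                    frame = integer(),
                                    x_um = double(), y_um = double()),
                         frame_interval = model$frame_interval,
                         metadata = list(seed = config$seed,
                                         n_molecules = n, n_tracks = 0))
      return(structure(list(tracks = empty,
                            truth = data.frame(),
                            config = config),
                       class = "spt_sim"))
    }

    idx <- which(keep)
    lens <- run_len[idx]
    total <- sum(lens)
    mol <- rep(idx, lens)
    frame0 <- sequence(lens) - 1L                  # 0-based frame index
    flat <- (frame0) * n + mol                     # column-major [mol, frame]
    ax <- ax_rec[flat]; an <- an_rec[flat]; fast <- st_rec[flat]

    if (surface_mode) {
      x <- ax
      y <- geom$radius * an
      zh <- geom$radius * (1 - cos(an %% (2 * pi)))
    } else {
      thw <- an %% (2 * pi)
      x <- ax
      y <- geom$radius * sin(thw)
      zh <- geom$radius * (1 - cos(thw))
    }
    x_obs <- x + stats::rnorm(total, 0, model$sigma_loc)
    y_obs <- y + stats::rnorm(total, 0, model$sigma_loc)

    id <- sprintf("mol%06d", mol)
    tracks <- track_set(
      data.frame(track_id = id, condition = condition, frame = frame0,
                 x_um = x_obs, y_um = y_obs, stringsAsFactors = FALSE),
      frame_interval = model$frame_interval,
      metadata = list(seed = config$seed, n_molecules = n,
                      n_tracks = length(idx), observe = config$observe,
                      mixture_mode = config$mixture_mode))
    truth <- data.frame(track_id = id, frame = frame0,
                        axial_um = ax, angle_rad = an,
                        arc_um = geom$radius * an, z_um = zh,
                        motion_state = ifelse(fast, "fast", "slow"),
                        stringsAsFactors = FALSE)
    structure(list(tracks = tracks, truth = truth, config = config),
              class = "spt_sim")
  })
}

#' Ground-truth surface-coordinate track set from a simulation
#'
#' Rebuilds the simulated tracks using the unwrapped in-membrane coordinates
#' (axial, arc length) instead of the projected image positions, without
#' localization noise. Used to quantify how small the curvature/projection
#' correction is.
#'
#' @param sim An `spt_sim` from [simulate_tracks()].
#' @return A [track_set()].
#' @export
surface_tracks <- function(sim) {
  stopifnot(inherits(sim, "spt_sim"))
  tr <- sim$truth
  track_set(data.frame(track_id = tr$track_id,
                       condition = "surface_truth",
                       frame = tr$frame,
                       x_um = tr$axial_um, y_um = tr$arc_um,
                       stringsAsFactors = FALSE),
            frame_interval = sim$config$model$frame_interval,
            metadata = list(seed = sim$config$seed, ground_truth = TRUE))
}

#' @export
print.spt_sim <- function(x, ...) {
  cat(sprintf("<spt_sim> %d retained tracks (%d localizations) from %d molecules, seed %d\n",
              n_tracks(x$tracks), nrow(x$tracks$data),
              x$config$n_molecules, x$config$seed))
  invisible(x)
}
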