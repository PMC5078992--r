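#' Cylindrical cell geometry for the TIRF observation window
#'
#' The cell body is modelled as a cylinder of given `radius` lying on the
#' coverslip along the image x axis. Only membrane positions whose height
#' above the coverslip, `z = radius * (1 - cos(angle))`, is at most
#' `tirf_depth` are visible in the evanescent TIRF field.
#'
#' @param radius Cylinder radius in micrometres. Default 0.5 (typical
#'   *E. coli* half-width).
#' @param length Cylinder length in micrometres (reflecting caps). Default 3.
#' @param tirf_depth Depth of the TIRF visibility window above the coverslip,
#'   in micrometres. Default 0.125, the midpoint of the ~100-150 nm range
#'   within which single molecules remain observable. `tirf_depth = 2*radius`
#'   makes the whole surface visible (no truncation).
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry()
#' visibility_half_angle(geom)  # ~0.7227 rad for the defaults
#' @export
cell_geometry <- function(radius = 0.5, length = 3, tirf_depth = 0.125) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(length), base::length(length) == 1L, is.finite(length),
            is.numeric(tirf_depth), base::length(tirf_depth) == 1L,
            is.finite(tirf_depth))
  if (radius <= 0) stop("radius must be > 0")
  if (length <= 0) stop("length must be > 0")
  if (tirf_depth <= 0 || tirf_depth > 2 * radius)
    stop("tirf_depth must satisfy 0 < tirf_depth <= 2*radius")
  structure(list(radius = radius, length = length, tirf_depth = tirf_depth),
            class = "cell_geometry")
}

#' Half-angle of the visible band around the coverslip contact line
#'
#' Solves `radius * (1 - cos(theta)) = tirf_depth` for the largest angle at
#' which a membrane molecule is still inside the TIRF window. When the whole
#' circumference is visible the result is `pi`.
#'
#' @param geometry A [cell_geometry()].
#' @return Half-angle in radians, in `(0, pi]`.
#' @export
visibility_half_angle <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  c <- 1 - geometry$tirf_depth / geometry$radius
  if (c <= -1) pi else acos(c)
}

#' Two-state diffusion model for a membrane protein
#'
#' Molecules diffuse on the membrane with constant `d_fast` (state "fast")
#' or `d_slow` (state "slow"), switching between states as a two-state
#' continuous-time Markov chain with the given rates. `alpha` is the
#' stationary fraction in the fast state; when both rates are positive it is
#' derived from them (`alpha = rate_slow_to_fast / (rate_slow_to_fast +
#' rate_fast_to_slow)`) and a conflicting user value is an error. Localization
#' noise of per-coordinate standard deviation `sigma_loc` is added to every
#' observed position, contributing a constant `4*sigma_loc^2` offset to the
#' MSD and to the squared-step scale.
#'
#' @param d_fast Fast-state diffusion constant, um^2/s. Default 0.05.
#' @param d_slow Slow-state diffusion constant, um^2/s. Default 0 (static).
#' @param alpha Stationary fast fraction in `[0, 1]`. Ignored (derived) when
#'   both switching rates are positive.
#' @param sigma_loc Per-coordinate localization error SD, um. Default 0.03.
#' @param rate_fast_to_slow,rate_slow_to_fast Switching rates, 1/s.
#'   Defaults 5 and 5 (dwell times of ~6-7 frames at 30 ms).
#' @param frame_interval Camera frame interval in seconds. Default 0.03.
#' @return An object of class `diffusion_model`.
#' @export
diffusion_model <- function(d_fast = 0.05, d_slow = 0, alpha = 0.5,
                            sigma_loc = 0.03,
                            rate_fast_to_slow = 5, rate_slow_to_fast = 5,
                            frame_interval = 0.03) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num1(d_fast), num1(d_slow), num1(alpha), num1(sigma_loc),
            num1(rate_fast_to_slow), num1(rate_slow_to_fast),
            num1(frame_interval))
  if (d_slow < 0 || d_fast < d_slow)
    stop("require d_fast >= d_slow >= 0")
  if (sigma_loc < 0) stop("sigma_loc must be >= 0")
  if (rate_fast_to_slow < 0 || rate_slow_to_fast < 0)
    stop("switching rates must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (rate_fast_to_slow > 0 && rate_slow_to_fast > 0) {
    alpha_stat <- rate_slow_to_fast / (rate_slow_to_fast + rate_fast_to_slow)
    if (!missing(alpha) && abs(alpha - alpha_stat) > 1e-8)
      stop(sprintf(
        "alpha = %g conflicts with stationary fraction %g implied by the rates",
        alpha, alpha_stat))
    alpha <- alpha_stat
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(d_fast = d_fast, d_slow = d_slow, alpha = alpha,
                 sigma_loc = sigma_loc,
                 rate_fast_to_slow = rate_fast_to_slow,
                 rate_slow_to_fast = rate_slow_to_fast,
                 frame_interval = frame_interval),
            class = "diffusion_model")
}

#' Full simulation configuration
#'
#' Bundles geometry, diffusion model and acquisition parameters. A track is
#' the first maximal run of consecutive visible frames of a molecule,
#' truncated by per-frame photobleaching survival, then length-filtered to
#' `[track_min_points, track_max_points]` (the 4-12 point window used for
#' analysis; longer runs are truncated to `track_max_points`).
#'
#' @param geometry A [cell_geometry()].
#' @param model A [diffusion_model()].
#' @param n_molecules Number of molecules to simulate.
#' @param n_frames_max Maximum number of camera frames per molecule.
#' @param substeps_per_frame Brownian substeps per frame (default 10), so a
#'   molecule cannot tunnel across the visibility boundary unnoticed;
#'   visibility itself is evaluated only at frame times.
#' @param track_min_points,track_max_points Retained track length window,
#'   default 4 and 12.
#' @param bleach_survival_per_frame Per-frame photobleaching survival
#'   probability, default 0.85 (raw track lengths concentrate in 4-12).
#' @param mixture_mode `"kinetic"` (two-state switching at the model rates)
#'   or `"static"` (each molecule keeps one state for life, fast with
#'   probability `alpha`).
#' @param observe `"image"` (project to the camera plane: x = axial,
#'   y = radius*sin(angle)) or `"surface"` (unwrapped in-membrane
#'   coordinates: x = axial, y = radius*angle, full visibility assumed) —
#'   the latter is the planar reference mode used for estimator validation.
#' @param seed Integer RNG seed; mandatory for reproducible pipeline runs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = cell_geometry(),
                              model = diffusion_model(),
                              n_molecules = 1000L,
                              n_frames_max = 50L,
                              substeps_per_frame = 10L,
                              track_min_points = 4L,
                              track_max_points = 12L,
                              bleach_survival_per_frame = 0.85,
                              mixture_mode = c("kinetic", "static"),
                              observe = c("image", "surface"),
                              seed = 1L) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(model, "diffusion_model"))
  mixture_mode <- match.arg(mixture_mode)
  observe <- match.arg(observe)
  n_molecules <- as.integer(n_molecules)
  n_frames_max <- as.integer(n_frames_max)
  substeps_per_frame <- as.integer(substeps_per_frame)
  track_min_points <- as.integer(track_min_points)
  track_max_points <- as.integer(track_max_points)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (n_frames_max < 2L) stop("n_frames_max must be >= 2")
  if (substeps_per_frame < 1L) stop("substeps_per_frame must be >= 1")
  if (track_min_points < 2L || track_min_points > track_max_points)
    stop("require 2 <= track_min_points <= track_max_points")
  if (bleach_survival_per_frame <= 0 || bleach_survival_per_frame > 1)
    stop("bleach_survival_per_frame must be in (0, 1]")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed is mandatory and must be an integer")
  structure(list(geometry = geometry, model = model,
                 n_molecules = n_molecules, n_frames_max = n_frames_max,
                 substeps_per_frame = substeps_per_frame,
                 track_min_points = track_min_points,
                 track_max_points = track_max_points,
                 bleach_survival_per_frame = bleach_survival_per_frame,
                 mixture_mode = mixture_mode, observe = observe,
                 seed = seed),
            class = "simulation_config")
}

#' Internal per-molecule surface state
#'
#' @param axial Axial coordinate, um, in `[-length/2, length/2]`.
#' @param angle Angle around the cylinder axis, radians; 0 is the coverslip
#'   contact line. Stored unwrapped (cumulative); wrap only for projection.
#' @param motion_state `"fast"` or `"slow"`.
#' @return An object of class `surface_state`.
#' @export
surface_state <- function(axial = 0, angle = 0,
                          motion_state = c("fast", "slow")) {
  motion_state <- match.arg(motion_state)
  stopifnot(is.numeric(axial), is.numeric(angle))
  structure(list(axial = axial, angle = angle, motion_state = motion_state),
            class = "surface_state")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> radius %.3g um, length %.3g um, TIRF depth %.3g um (half-angle %.4g rad)\n",
    x$radius, x$length, x$tirf_depth, visibility_half_angle(x)))
  invisible(x)
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf(
    "<diffusion_model> D_fast %.3g, D_slow %.3g um^2/s; alpha %.3g; sigma %.3g um; rates %.3g/%.3g 1/s; dt %.3g s\n",
    x$d_fast, x$d_slow, x$alpha, x$sigma_loc,
    x$rate_fast_to_slow, x$rate_slow_to_fast, x$frame_interval))
  invisible(x)
}
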