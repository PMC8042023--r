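#' Simulation configuration for a growing spherocylindrical cell
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The cell is modelled as a cylinder of diameter `diameter_D` capped by two
#' inert polar zones of axial size `cap_size_c` (the inert-zone size, i.e. the
#' changepoint `P_yc` that the kinematics module recovers). The cylindrical
#' active zone of length `L` elongates by homogeneous axial insertion at
#' per-length rate `H(t) = H0 * (1 + beta * t)`, so `dL/dt = H(t) * L`.
#'
#' @param cap_size_c Inert-zone axial size, in micrometres (ground-truth
#'   changepoint). Presets: 0.27 (LB), 0.22 (TB), 0.37 (SOC).
#' @param diameter_D Cell diameter, micrometres.
#' @param initial_active_length_L0 Active-zone length at time 0, micrometres.
#' @param growth_rate_H0 Per-length axial growth rate at time 0, 1/min.
#' @param growth_acceleration_beta Linear growth-rate acceleration, 1/min^2;
#'   `beta = 0` gives pure exponential elongation.
#' @param frame_interval_dt Frame interval, minutes.
#' @param n_frames Number of frames simulated during elongation.
#' @param division_trigger_length Total cell length (active zone plus both
#'   caps) that triggers division, micrometres; used when
#'   `division_trigger = "length"`.
#' @param division_trigger Either `"length"` or `"timer"`.
#' @param division_time Age at division, minutes (timer trigger).
#' @param division_duration Duration of septal growth, minutes.
#' @param n_motors Number of wall-anchored motor landmarks placed on the
#'   founding cell.
#' @param motor_placement List describing the placement law of motors along
#'   the axis: `list(type = "uniform")` places motors uniformly over the whole
#'   cell (active zone and caps); `list(type = "truncgauss", sigma = 0.4)`
#'   places motors in the active zone with a truncated Gaussian law on the
#'   normalized coordinate `[-0.5, 0.5]`.
#' @param localization_sigma Gaussian localization noise added to observed
#'   positions, micrometres.
#' @param detection_miss_rate Probability that a motor is missed in a frame.
#' @param elongation_during_division If `TRUE` (default) the two half-rods
#'   keep elongating while the septum grows (elongation and septal growth are
#'   independent processes); if `FALSE` elongation pauses.
#' @param rng_seed Root seed; all stochastic elements derive named substreams
#'   from it.
#' @param render List of rendering options: `enabled`, `pixel_size`
#'   (micrometres per pixel, default 0.052), `psf_sigma` (micrometres),
#'   `photon_count` (expected photons at a spot peak), `background`
#'   (photons per pixel), `margin` (micrometres of padding around the cell),
#'   `shot_noise` (logical).
#'
#' @return An object of class `wm_sim_config` (a validated list).
#' @seealso [sim_preset()] for the LB/TB/SOC growth-medium presets.
#' @export
sim_config <- function(cap_size_c = 0.27,
                       diameter_D = 1.06,
                       initial_active_length_L0 = 2.0,
                       growth_rate_H0 = 0.01,
                       growth_acceleration_beta = 0.005,
                       frame_interval_dt = 10,
                       n_frames = 7,
                       division_trigger_length = 5.0,
                       division_trigger = c("length", "timer"),
                       division_time = 60,
                       division_duration = 20,
                       n_motors = 9,
                       motor_placement = list(type = "uniform"),
                       localization_sigma = 0.03,
                       detection_miss_rate = 0,
                       elongation_during_division = TRUE,
                       rng_seed = 1L,
                       render = list()) {
  division_trigger <- match.arg(division_trigger)
  render_defaults <- list(enabled = FALSE, pixel_size = 0.052,
                          psf_sigma = 0.10, photon_count = 2000,
                          background = 100, margin = 0.6, shot_noise = TRUE)
  render <- utils::modifyList(render_defaults, render)

  cfg <- list(
    cap_size_c = cap_size_c,
    diameter_D = diameter_D,
    initial_active_length_L0 = initial_active_length_L0,
    growth_rate_H0 = growth_rate_H0,
    growth_acceleration_beta = growth_acceleration_beta,
    frame_interval_dt = frame_interval_dt,
    n_frames = as.integer(n_frames),
    division_trigger_length = division_trigger_length,
    division_trigger = division_trigger,
    division_time = division_time,
    division_duration = division_duration,
    n_motors = as.integer(n_motors),
    motor_placement = motor_placement,
    localization_sigma = localization_sigma,
    detection_miss_rate = detection_miss_rate,
    elongation_during_division = isTRUE(elongation_during_division),
    rng_seed = as.integer(rng_seed),
    render = render
  )
  class(cfg) <- "wm_sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every field of a [sim_config()] list and fails with a message that
#' names all offending keys at once.
#'
#' @param cfg A `wm_sim_config` or plain named list.
#' @return The validated `wm_sim_config`, invisibly usable.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)

  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$cap_size_c) && cfg$cap_size_c > 0, "cap_size_c")
  chk(num1(cfg$diameter_D) && cfg$diameter_D > 0, "diameter_D")
  chk(num1(cfg$initial_active_length_L0) && cfg$initial_active_length_L0 > 0,
      "initial_active_length_L0")
  chk(num1(cfg$growth_rate_H0) && cfg$growth_rate_H0 >= 0, "growth_rate_H0")
  chk(num1(cfg$growth_acceleration_beta), "growth_acceleration_beta")
  chk(num1(cfg$frame_interval_dt) && cfg$frame_interval_dt > 0,
      "frame_interval_dt")
  chk(num1(cfg$n_frames) && cfg$n_frames >= 1, "n_frames")
  chk(num1(cfg$division_trigger_length) && cfg$division_trigger_length > 0,
      "division_trigger_length")
  chk(cfg$division_trigger %in% c("length", "timer"), "division_trigger")
  chk(num1(cfg$division_duration) && cfg$division_duration > 0,
      "division_duration")
  chk(num1(cfg$n_motors) && cfg$n_motors >= 0, "n_motors")
  chk(is.list(cfg$motor_placement) &&
        (cfg$motor_placement$type %||% "") %in% c("uniform", "truncgauss"),
      "motor_placement")
  if (identical(cfg$motor_placement$type, "truncgauss")) {
    chk(num1(cfg$motor_placement$sigma %||% NULL) &&
          cfg$motor_placement$sigma > 0, "motor_placement$sigma")
  }
  chk(num1(cfg$localization_sigma) && cfg$localization_sigma >= 0,
      "localization_sigma")
  chk(num1(cfg$detection_miss_rate) && cfg$detection_miss_rate >= 0 &&
        cfg$detection_miss_rate < 1, "detection_miss_rate")
  chk(num1(cfg$rng_seed), "rng_seed")
  chk(num1(cfg$render$pixel_size) && cfg$render$pixel_size > 0,
      "render$pixel_size")
  chk(num1(cfg$render$psf_sigma) && cfg$render$psf_sigma > 0,
      "render$psf_sigma")
  chk(num1(cfg$render$photon_count) && cfg$render$photon_count >= 0,
      "render$photon_count")
  chk(num1(cfg$render$background) && cfg$render$background >= 0,
      "render$background")

  if (length(bad)) {
    stop("invalid simulation configuration; offending keys: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Growth-medium presets for the simulator
#'
#' Returns a [sim_config()] preconfigured with the inert-zone size and cell
#' diameter measured for cells grown in LB, TB or SOC medium
#' (inert zones 0.27, 0.22 and 0.37 um; diameters 1.06, 1.02 and 1.11 um).
#' The LB diameter is not a measured value; 1.06 um sits between the TB and
#' SOC diameters, consistent with LB's intermediate nutrient quality.
#'
#' @param medium One of `"LB"`, `"TB"`, `"SOC"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `wm_sim_config`.
#' @export
sim_preset <- function(medium = c("LB", "TB", "SOC"), ...) {
  medium <- match.arg(medium)
  p <- switch(medium,
    LB  = list(cap_size_c = 0.27, diameter_D = 1.06),
    TB  = list(cap_size_c = 0.22, diameter_D = 1.02),
    SOC = list(cap_size_c = 0.37, diameter_D = 1.11)
  )
  do.call(sim_config, utils::modifyList(p, list(...)))
}

# Active-zone growth factor L(t)/L(0) = exp(H0 * (t + beta * t^2 / 2)),
# the exact integral of dL/dt = H0 * (1 + beta * t) * L.
growth_factor <- function(t, H0, beta) exp(H0 * (t + beta * t^2 / 2))

#' Instantaneous per-length axial growth rate
#'
#' `H(t) = H0 * (1 + beta * t)`: the "Hubble" parameter of cell-wall
#' expansion at time `t`.
#'
#' @param t Time, minutes.
#' @param config A `wm_sim_config`.
#' @return Growth rate in 1/min.
#' @export
growth_rate_at <- function(t, config) {
  config$growth_rate_H0 * (1 + config$growth_acceleration_beta * t)
}
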