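#' Simulation configuration for a cage of rats
#'
#' Builds and validates the configuration for the cohort simulator: cage
#' geometry, photoperiod, movement model, posture schedule, implant site and
#' subcutaneous temperature model.  All times are seconds, lengths cm,
#' temperatures degrees Celsius.  The session clock starts at lights-on, so
#' the light phase occupies \code{[0, photoperiod[1])} hours of each day.
#'
#' @param cage_length Cage (and baseplate) length along x, cm.
#' @param cage_width Cage width along y, cm.
#' @param n_animals Number of co-housed rats.
#' @param photoperiod Hours of light and dark per day, in that order.
#' @param duration Session length in seconds.
#' @param timestep Ground-truth sampling interval in seconds.
#' @param dark_light_activity_ratio Multiplier applied to the step rate in the
#'   dark phase (rats are nocturnal; about 1.4 in group-housed cages).
#' @param base_step_rate Steps per second while in an active bout during the
#'   light phase.
#' @param step_length Distance advanced per step, cm.
#' @param turn_sd Heading turning-angle standard deviation (radians) per
#'   stepped timestep; smaller values give straighter paths.
#' @param rest_bout List with \code{mean_rest_s} and \code{mean_active_s},
#'   each a length-2 vector (light, dark) of mean exponential bout lengths for
#'   the two-state rest/active semi-Markov process.
#' @param rearing_rate Rearing events per hour, length-2 (light, dark).
#' @param rearing_duration Rearing bout length, seconds.
#' @param climbing_rate Climbing events per hour, length-2 (light, dark).
#' @param climbing_duration Climbing bout length, seconds.
#' @param implant_site One of \code{"ventral_midline"}, \code{"flank_vertical"},
#'   \code{"flank_horizontal"}, \code{"interscapular"}.
#' @param temp_baseline Light-phase mean subcutaneous temperature.
#' @param temp_dark_elevation Dark-phase elevation of the mean temperature.
#'   The default preset is 0.5; a 0.25 preset
#'   (\code{temp_presets$regression}) reflects the smaller phase contrast a
#'   binned regression typically attributes to photoperiod alone.
#' @param temp_noise_sd Stationary standard deviation of the AR(1) temperature
#'   noise.
#' @param temp_ar1 AR(1) coefficient of the temperature noise at the
#'   ground-truth timestep.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(cage_length = 50,
                       cage_width = 38,
                       n_animals = 3,
                       photoperiod = c(light = 12, dark = 12),
                       duration = 86400,
                       timestep = 0.1,
                       dark_light_activity_ratio = 1.4,
                       base_step_rate = 1.2,
                       step_length = 3,
                       turn_sd = 0.6,
                       rest_bout = list(mean_rest_s = c(light = 270, dark = 270),
                                        mean_active_s = c(light = 90, dark = 90)),
                       rearing_rate = c(light = 12, dark = 20),
                       rearing_duration = 2,
                       climbing_rate = c(light = 1, dark = 2),
                       climbing_duration = 5,
                       implant_site = "ventral_midline",
                       temp_baseline = 37.5,
                       temp_dark_elevation = 0.5,
                       temp_noise_sd = 0.1,
                       temp_ar1 = 0.999,
                       seed = 1) {
  cfg <- list(cage_length = cage_length, cage_width = cage_width,
              n_animals = n_animals, photoperiod = photoperiod,
              duration = duration, timestep = timestep,
              dark_light_activity_ratio = dark_light_activity_ratio,
              base_step_rate = base_step_rate, step_length = step_length,
              turn_sd = turn_sd, rest_bout = rest_bout,
              rearing_rate = rearing_rate, rearing_duration = rearing_duration,
              climbing_rate = climbing_rate, climbing_duration = climbing_duration,
              implant_site = implant_site, temp_baseline = temp_baseline,
              temp_dark_elevation = temp_dark_elevation,
              temp_noise_sd = temp_noise_sd, temp_ar1 = temp_ar1,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
temp_presets <- list(default = 0.5, regression = 0.25)

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$cage_length <= 0 || cfg$cage_width <= 0)
    stop("cage dimensions must be positive", call. = FALSE)
  if (cfg$timestep <= 0) stop("timestep must be positive", call. = FALSE)
  if (cfg$duration < 0) stop("duration must be non-negative", call. = FALSE)
  if (cfg$n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  if (cfg$dark_light_activity_ratio < 0)
    stop("dark_light_activity_ratio must be >= 0", call. = FALSE)
  if (length(cfg$photoperiod) != 2 || any(cfg$photoperiod < 0))
    stop("photoperiod must be two non-negative durations (hours)", call. = FALSE)
  if (!cfg$implant_site %in% site_names())
    stop("unknown implant_site '", cfg$implant_site, "'; valid sites: ",
         paste(site_names(), collapse = ", "), call. = FALSE)
  for (nm in c("rearing_rate", "climbing_rate"))
    if (length(cfg[[nm]]) != 2 || any(cfg[[nm]] < 0))
      stop(nm, " must be two non-negative rates (light, dark)", call. = FALSE)
  if (cfg$temp_ar1 < 0 || cfg$temp_ar1 >= 1)
    stop("temp_ar1 must be in [0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Perturbation event
#'
#' Describes a husbandry perturbation injected into a simulation: a weekly
#' cage change (activity spike of 30-60 min), 16 h single housing (sustained
#' subcutaneous temperature drop), or an oral gavage dosing procedure (brief
#' activity spike).
#'
#' @param kind One of \code{"cage_change"}, \code{"single_housing"},
#'   \code{"gavage"}.
#' @param t0 Event onset, seconds from session start.
#' @param duration Event length in seconds.  Defaults: 2700 (cage change),
#'   57600 (16 h single housing), 600 (gavage).
#' @param magnitude Step-rate multiplier for activity events (cage change,
#'   gavage) or temperature drop in degrees C for single housing.
#' @return A \code{perturbation_event} list.
#' @export
perturbation_event <- function(kind, t0, duration = NULL, magnitude = NULL) {
  defaults <- list(
    cage_change    = list(duration = 2700,  magnitude = 3),
    single_housing = list(duration = 57600, magnitude = 0.5),
    gavage         = list(duration = 600,   magnitude = 2.5))
  if (!kind %in% names(defaults))
    stop("unknown perturbation kind '", kind, "'", call. = FALSE)
  if (is.null(duration)) duration <- defaults[[kind]]$duration
  if (is.null(magnitude)) magnitude <- defaults[[kind]]$magnitude
  if (t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  structure(list(kind = kind, t0 = t0, duration = duration,
                 magnitude = magnitude), class = "perturbation_event")
}

#' Circadian phase of a time point
#'
#' @param t Time(s) in seconds from lights-on.
#' @param photoperiod Hours of light and dark per day.
#' @return Character vector, \code{"light"} or \code{"dark"}.
#' @export
phase_of <- function(t, photoperiod = c(light = 12, dark = 12)) {
  day_s <- sum(photoperiod) * 3600
  ifelse((t %% day_s) < photoperiod[[1]] * 3600, "light", "dark")
}

#' Circadian activity multiplier
#'
#' Piecewise-constant rate multiplier: 1 during the light phase and
#' \code{dark_light_activity_ratio} during the dark phase.
#'
#' @param t Time(s) in seconds from lights-on (t >= 0).
#' @param cfg A \code{\link{sim_config}}.
#' @return Numeric multiplier(s).
#' @export
circadian_intensity <- function(t, cfg) {
  stopifnot(all(t >= 0))
  ifelse(phase_of(t, cfg$photoperiod) == "dark",
         cfg$dark_light_activity_ratio, 1)
}
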