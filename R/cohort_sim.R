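# Ground-truth cohort simulator: bounded correlated random walk with
# phase-modulated step rate, rest bouts, posture events, implant-site tag
# pose, and AR(1) subcutaneous temperature.

# Walking tag heights (cm) per implant site are calibration constants (see
# calibration_constants()) chosen so that the simulated baseplate reproduces
# the in vivo read-rate ordering.  `axis` is the transponder long axis with
# the rat on all fours: "body" = horizontal along the body midline,
# "vertical" = dorsoventral.  Flank sites sit off the body midline.

postures <- c("walking", "resting", "rearing", "climbing")

#' Tag pose preset for an implant site and posture
#'
#' Returns the transponder height above the baseplate, its long-axis unit
#' vector (canonical frame: body axis along x), and the lateral offset from
#' the body midline.  Resting lowers the tag slightly; rearing and climbing
#' raise it and pitch the body upright, so body-axis tags become vertical and
#' dorsoventral (flank vertical) tags become horizontal.
#'
#' @param site Implant site name (see \code{\link{sim_config}}).
#' @param posture One of \code{"walking"}, \code{"resting"}, \code{"rearing"},
#'   \code{"climbing"}.
#' @return List with \code{tag_height} (cm), \code{tag_axis} (unit 3-vector)
#'   and \code{lateral_offset} (cm).
#' @export
tag_pose_for_site <- function(site, posture) {
  if (!posture %in% postures)
    stop("unknown posture '", posture, "'", call. = FALSE)
  p <- site_preset(site)
  h <- switch(posture,
              walking  = p$height,
              resting  = p$height * 0.85,
              rearing  = p$height + 8,
              climbing = p$height + 12)
  upright <- posture %in% c("rearing", "climbing")
  vertical <- if (upright) p$axis == "body" else p$axis == "vertical"
  axis <- if (vertical) c(0, 0, 1) else c(1, 0, 0)
  list(tag_height = h, tag_axis = axis, lateral_offset = p$lateral_offset)
}

# Reflect an unbounded coordinate into [0, L] (specular wall reflection).
fold_reflect <- function(p, L) {
  m <- p %% (2 * L)
  L - abs(m - L)
}

# Per-sample activity multiplier and temperature offset implied by events.
event_modulators <- function(t, events) {
  act <- rep(1, length(t))
  tmp <- rep(0, length(t))
  for (ev in events) {
    inwin <- t >= ev$t0 & t < ev$t0 + ev$duration
    if (ev$kind %in% c("cage_change", "gavage")) {
      act[inwin] <- act[inwin] * ev$magnitude
    } else if (ev$kind == "single_housing") {
      tmp[inwin] <- tmp[inwin] - ev$magnitude
    } else stop("unknown perturbation kind '", ev$kind, "'", call. = FALSE)
  }
  list(activity = act, temp = tmp)
}

# Alternating rest/active bout indicator over the time grid.  Bout lengths are
# exponential with phase-dependent means sampled at bout onset.
sample_bouts <- function(t, cfg) {
  n <- length(t)
  if (n == 0L) return(logical(0))
  dt <- cfg$timestep
  mr <- cfg$rest_bout$mean_rest_s
  ma <- cfg$rest_bout$mean_active_s
  frac <- ma[[1]] / (ma[[1]] + mr[[1]])
  active <- logical(n)
  i <- 1L
  state <- stats::runif(1) < frac
  while (i <= n) {
    ph <- if (phase_of(t[i], cfg$photoperiod) == "light") 1L else 2L
    mean_len <- if (state) ma[[ph]] else mr[[ph]]
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / mean_len) / dt)))
    j <- min(n, i + len - 1L)
    active[i:j] <- state
    state <- !state
    i <- j + 1L
  }
  active
}

# Poisson posture events expanded to fixed-length windows.
sample_posture_windows <- function(t, rate_per_h, duration_s, cfg) {
  n <- length(t)
  flag <- logical(n)
  if (n == 0L) return(flag)
  haz <- ifelse(phase_of(t, cfg$photoperiod) == "light",
                rate_per_h[[1]], rate_per_h[[2]]) / 3600 * cfg$timestep
  starts <- which(stats::runif(n) < haz)
  w <- max(1L, as.integer(round(duration_s / cfg$timestep)))
  for (s in starts) flag[s:min(n, s + w - 1L)] <- TRUE
  flag
}

#' Simulate a cohort of group-housed rats
#'
#' Generates per-animal ground truth at the configured timestep: planar
#' position (bounded correlated random walk with wall reflection), posture
#' (rest bouts plus Poisson rearing/climbing events), transponder pose for the
#' configured implant site, and subcutaneous temperature (two-level circadian
#' mean with AR(1) noise).  Step rate is modulated by circadian phase, rest
#' bouts and any perturbation events.  Identical config and seed give
#' identical output.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param events List of \code{\link{perturbation_event}}s applied during
#'   generation.
#' @return A \code{data.table} with one row per animal per timestep and
#'   columns \code{t}, \code{animal_id}, \code{x}, \code{y} (body centre, cm),
#'   \code{posture}, \code{tag_height}, \code{tag_axis_x/y/z},
#'   \code{true_temp}, \code{steps} (steps taken this timestep) and
#'   \code{tag_x}, \code{tag_y} (transponder planar position, including the
#'   flank lateral offset).  The event log and config are attached as
#'   attributes \code{"events"} and \code{"config"}.
#' @export
simulate_cohort <- function(cfg, events = list()) {
  cfg <- validate_sim_config(cfg)
  if (inherits(events, "perturbation_event")) events <- list(events)
  for (ev in events)
    if (ev$t0 > cfg$duration)
      stop("perturbation at t0 = ", ev$t0, " starts after the session ends",
           call. = FALSE)
  n <- as.integer(round(cfg$duration / cfg$timestep))
  empty <- data.table::data.table(
    t = numeric(0), animal_id = character(0), x = numeric(0), y = numeric(0),
    posture = character(0), tag_height = numeric(0), tag_axis_x = numeric(0),
    tag_axis_y = numeric(0), tag_axis_z = numeric(0), true_temp = numeric(0),
    steps = integer(0), tag_x = numeric(0), tag_y = numeric(0))
  if (n == 0L) {
    out <- empty
  } else {
    set.seed(cfg$seed)
    tt <- (seq_len(n) - 1L) * cfg$timestep
    mods <- event_modulators(tt, events)
    intensity <- circadian_intensity(tt, cfg)
    dark <- phase_of(tt, cfg$photoperiod) == "dark"
    site <- site_preset(cfg$implant_site)
    # fill preallocated columns per animal (no rbind copy of the full table)
    N <- n * cfg$n_animals
    col <- function(proto) rep(proto, N)
    out <- data.table::data.table(
      t = rep(tt, cfg$n_animals),
      animal_id = rep(sprintf("rat%02d", seq_len(cfg$n_animals)), each = n),
      x = col(0), y = col(0), posture = col(""), tag_height = col(0),
      tag_axis_x = col(0), tag_axis_y = col(0), tag_axis_z = col(0),
      true_temp = col(0), steps = col(0L), tag_x = col(0), tag_y = col(0))
    for (a in seq_len(cfg$n_animals)) {
      active <- sample_bouts(tt, cfg)
      rearing <- sample_posture_windows(tt, cfg$rearing_rate,
                                        cfg$rearing_duration, cfg)
      climbing <- sample_posture_windows(tt, cfg$climbing_rate,
                                         cfg$climbing_duration, cfg)
      posture <- ifelse(climbing, "climbing",
                 ifelse(rearing, "rearing",
                 ifelse(active, "walking", "resting")))
      moving <- posture == "walking"
      lambda <- cfg$base_step_rate * cfg$timestep * intensity *
        mods$activity * moving
      steps <- stats::rpois(n, lambda)
      theta <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n, 0, cfg$turn_sd) * (steps > 0))
      d <- steps * cfg$step_length
      x <- fold_reflect(stats::runif(1, 0, cfg$cage_length) +
                          cumsum(d * cos(theta)), cfg$cage_length)
      y <- fold_reflect(stats::runif(1, 0, cfg$cage_width) +
                          cumsum(d * sin(theta)), cfg$cage_width)
      # tag pose per posture (vectorised version of tag_pose_for_site)
      h <- ifelse(posture == "walking", site$height,
           ifelse(posture == "resting", site$height * 0.85,
           ifelse(posture == "rearing", site$height + 8, site$height + 12)))
      upright <- posture %in% c("rearing", "climbing")
      vert <- ifelse(upright, site$axis == "body", site$axis == "vertical")
      ax <- ifelse(vert, 0, cos(theta))
      ay <- ifelse(vert, 0, sin(theta))
      az <- ifelse(vert, 1, 0)
      off <- site$lateral_offset
      if (off == 0) {
        tag_x <- x
        tag_y <- y
      } else {
        tag_x <- pmin(pmax(x + off * -sin(theta), 0), cfg$cage_length)
        tag_y <- pmin(pmax(y + off * cos(theta), 0), cfg$cage_width)
      }
      innov_sd <- cfg$temp_noise_sd * sqrt(1 - cfg$temp_ar1^2)
      noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                        cfg$temp_ar1, method = "recursive"))
      true_temp <- cfg$temp_baseline + cfg$temp_dark_elevation * dark +
        mods$temp + noise
      rows <- ((a - 1L) * n + 1L):(a * n)
      vals <- list(x = x, y = y, posture = posture, tag_height = h,
                   tag_axis_x = ax, tag_axis_y = ay, tag_axis_z = az,
                   true_temp = true_temp, steps = as.integer(steps),
                   tag_x = tag_x, tag_y = tag_y)
      for (nm in names(vals)) data.table::set(out, rows, nm, vals[[nm]])
    }
  }
  log <- data.table::rbindlist(lapply(events, function(ev)
    data.table::data.table(kind = ev$kind, t0_s = ev$t0,
                           duration_s = ev$duration, magnitude = ev$magnitude)))
  if (length(events) == 0L)
    log <- data.table::data.table(kind = character(0), t0_s = numeric(0),
                                  duration_s = numeric(0), magnitude = numeric(0))
  data.table::setattr(out, "events", log)
  data.table::setattr(out, "config", cfg)
  out[]
}

#' Apply a perturbation to an already generated series
#'
#' Temperature perturbations (single housing) subtract the configured drop
#' from \code{true_temp} inside the event window.  Activity perturbations
#' (cage change, gavage) scale the per-sample step counts by the event
#' magnitude inside the window; positions are left unchanged, so this
#' post-hoc route is intended for step-count analyses.  The simulation
#' pipeline instead passes events to \code{\link{simulate_cohort}}, which
#' modulates the full movement path at generation time.
#'
#' @param series Output of \code{\link{simulate_cohort}}.
#' @param event A \code{\link{perturbation_event}}.
#' @return The modified series (a copy).
#' @export
apply_perturbation <- function(series, event) {
  if (!inherits(event, "perturbation_event"))
    stop("event must be a perturbation_event", call. = FALSE)
  out <- data.table::copy(series)
  i <- which(out$t >= event$t0 & out$t < event$t0 + event$duration)
  if (event$kind == "single_housing") {
    data.table::set(out, i, "true_temp", out$true_temp[i] - event$magnitude)
  } else if (event$kind %in% c("cage_change", "gavage")) {
    data.table::set(out, i, "steps",
                    as.integer(round(out$steps[i] * event$magnitude)))
  } else stop("unknown perturbation kind '", event$kind, "'", call. = FALSE)
  out
}
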