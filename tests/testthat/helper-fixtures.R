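# Fixture builders shared across tests: hand-made ground-truth tables for
# the baseplate and renderer, and a noise-free coupling model.

# Ground truth for stationary (or scripted) tags on the regular 0.1 s grid.
# `spec` is a list per animal: list(x=, y=, height=, axis=c(x,y,z),
# posture=, temp=); scalars are recycled over the grid.
make_gt <- function(spec, duration, timestep = 0.1) {
  n <- as.integer(round(duration / timestep))
  tt <- (seq_len(n) - 1L) * timestep
  rows <- lapply(seq_along(spec), function(a) {
    s <- spec[[a]]
    ax <- s$axis %||% c(0, 0, 1)
    data.table::data.table(
      t = tt, animal_id = s$id %||% sprintf("rat%02d", a),
      x = rep_len(s$x, n), y = rep_len(s$y, n),
      posture = rep_len(s$posture %||% "walking", n),
      tag_height = rep_len(s$height %||% 2.5, n),
      tag_axis_x = rep_len(ax[1], n), tag_axis_y = rep_len(ax[2], n),
      tag_axis_z = rep_len(ax[3], n),
      true_temp = rep_len(s$temp %||% 37.5, n), steps = 0L,
      tag_x = rep_len(s$x, n), tag_y = rep_len(s$y, n))
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "config", sim_config(duration = duration,
                                                timestep = timestep))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free, generously coupled model for deterministic read tests.
noise_free_model <- function(...) {
  calibrated_model(coupling_noise_sd = 0, ...)
}

# Pose table for a single activation window: tag crossing the plate along x
# at constant speed, sampled on the fine subsample grid.
crossing_poses <- function(x0, v, y = 6 + 1 / 3, height = 6,
                           axis = c(0, 0, 1), act_s = 0.075, dt = 0.005,
                           tag_id = "tagA") {
  tt <- seq(0, act_s, by = dt)
  data.table::data.table(
    t = tt, tag_id = tag_id, x = x0 + v * tt, y = y, tag_height = height,
    tag_axis_x = axis[1], tag_axis_y = axis[2], tag_axis_z = axis[3])
}
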