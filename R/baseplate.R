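# RFID baseplate reader model: 3 x 4 antenna array polled sequentially,
# magnetic-dipole tag coupling, charge-dwell and collision rules, and
# transponder temperature reads.

#' Baseplate antenna array
#'
#' Describes the 12-coil reader under the cage: a 3 x 4 grid of transceiver
#' coils polled one at a time.  Each polling slot lasts \code{slot_duration}
#' seconds with the coil energised for the first \code{active_duration}; the
#' remainder is a settle gap.  At the defaults a full scan cycle takes
#' 12 x 0.090 = 1.080 s.
#'
#' @param plate_length Plate length along x, cm.
#' @param plate_width Plate width along y, cm.
#' @param n_rows,n_cols Grid dimensions (rows along y).
#' @param slot_duration Polling slot length, seconds.
#' @param active_duration Coil activation length within a slot, seconds.
#' @param read_order Permutation of 1..12 giving the polling sequence;
#'   default is a row-major serpentine over the grid.
#' @return An \code{antenna_array} list with a \code{centroids} table of coil
#'   centre positions (antennas are numbered 1..12, row-major).
#' @export
antenna_array <- function(plate_length = 50, plate_width = 38,
                          n_rows = 3, n_cols = 4,
                          slot_duration = 0.090, active_duration = 0.075,
                          read_order = NULL) {
  n <- n_rows * n_cols
  if (is.null(read_order)) {
    idx <- matrix(seq_len(n), nrow = n_rows, ncol = n_cols, byrow = TRUE)
    read_order <- as.integer(unlist(lapply(seq_len(n_rows), function(r)
      if (r %% 2 == 1) idx[r, ] else rev(idx[r, ]))))
  }
  if (!identical(sort(as.integer(read_order)), seq_len(n)))
    stop("read_order must be a permutation of 1..", n, call. = FALSE)
  if (slot_duration < active_duration)
    stop("slot_duration must be >= active_duration", call. = FALSE)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  centroids <- data.table::data.table(
    antenna = seq_len(n),
    x = (grid$col - 0.5) * plate_length / n_cols,
    y = (grid$row - 0.5) * plate_width / n_rows)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 plate_length = plate_length, plate_width = plate_width,
                 slot_duration = slot_duration,
                 active_duration = active_duration,
                 read_order = as.integer(read_order),
                 centroids = centroids),
            class = "antenna_array")
}

#' Maximum theoretical per-tag read frequency
#'
#' One read per full polling cycle: \code{1 / (n_antennae * slot_duration)},
#' 0.926 Hz (0.93 to two decimals) at the defaults.
#'
#' @param array An \code{\link{antenna_array}}.
#' @return Frequency in Hz.
#' @export
max_read_frequency <- function(array = antenna_array()) {
  1 / (nrow(array$centroids) * array$slot_duration)
}

#' Antenna active at a given time
#'
#' Antennae are energised sequentially in \code{read_order}; within each slot
#' the coil is active for \code{active_duration} then off for the settle gap.
#'
#' @param t Time(s) in seconds, t >= 0.
#' @param array An \code{\link{antenna_array}}.
#' @return Integer antenna index (1..12), or \code{NA} during a gap.
#' @export
active_antenna <- function(t, array = antenna_array()) {
  stopifnot(all(t >= 0))
  n <- nrow(array$centroids)
  cyc <- n * array$slot_duration
  pos <- t %% cyc
  slot <- pmin(floor(pos / array$slot_duration) + 1, n)
  within <- pos - (slot - 1) * array$slot_duration
  out <- array$read_order[slot]
  out[within >= array$active_duration] <- NA_integer_
  out
}

#' Tag-antenna coupling model
#'
#' Each coil is approximated as a vertical magnetic dipole at its centroid.
#' The induced tag signal is proportional to the projection of the coil field
#' onto the transponder long axis; a tag is readable during an activation only
#' if its coupling stays at or above \code{read_threshold} for at least
#' \code{min_dwell} seconds (the charge-and-read time), and only the
#' strongest readable tag is reported.  \code{field_scale},
#' \code{read_threshold} and \code{shielding_gain} are calibration constants
#' (see \code{\link{calibration_constants}}); the shielding gain multiplies
#' the field when \code{upgraded = TRUE}, emulating the Faraday-shielding and
#' baseplate-tuning hardware upgrade.
#'
#' @param field_scale Dimensionless field amplitude.
#' @param read_threshold Minimum coupling for a successful charge.
#' @param shielding_gain Multiplicative field gain when upgraded (>= 1).
#' @param upgraded Logical; apply the shielding gain.
#' @param min_dwell Minimum continuous supra-threshold dwell, seconds.
#' @param coil_radius Nominal coil radius, cm (documentation scale for the
#'   dipole approximation).
#' @param subsample Pose sampling interval within an activation, seconds.
#' @param cull_radius Horizontal distance beyond which coupling is treated as
#'   zero when streaming (cm).
#' @param dwell_tol Numerical tolerance on the dwell comparison, seconds.
#' @param coupling_noise_sd Log-normal sigma of the multiplicative coupling
#'   noise applied by \code{\link{simulate_readstream}} (stray RF
#'   variability; 0 = noise free).  The noise affects whether a tag charges,
#'   not the reported strength ranking, and is constant within one
#'   activation, so the dwell rule is unaffected.
#' @param coupling_noise_tau Correlation time (seconds) of the RF noise: the
#'   log-noise evolves as an AR(1) process per tag-antenna pair across scan
#'   cycles, so interference episodes persist for minutes rather than
#'   flickering cycle to cycle.
#' @return A \code{coupling_model} list.
#' @export
coupling_model <- function(field_scale = 1,
                           read_threshold = 1,
                           shielding_gain = 1.25,
                           upgraded = FALSE,
                           min_dwell = 0.060,
                           coil_radius = 5,
                           subsample = 0.005,
                           cull_radius = 22,
                           dwell_tol = 5e-4,
                           coupling_noise_sd = 0.6,
                           coupling_noise_tau = 300) {
  if (read_threshold <= 0) stop("read_threshold must be > 0", call. = FALSE)
  if (min_dwell <= 0) stop("min_dwell must be > 0", call. = FALSE)
  if (shielding_gain < 1) stop("shielding_gain must be >= 1", call. = FALSE)
  structure(list(field_scale = field_scale, read_threshold = read_threshold,
                 shielding_gain = shielding_gain, upgraded = upgraded,
                 min_dwell = min_dwell, coil_radius = coil_radius,
                 subsample = subsample, cull_radius = cull_radius,
                 dwell_tol = dwell_tol, coupling_noise_sd = coupling_noise_sd,
                 coupling_noise_tau = coupling_noise_tau),
            class = "coupling_model")
}

# Vectorised dipole coupling at horizontal displacement (dx, dy) and height h
# (cm) from the coil centre, for tag long axis (ax, ay, az).
coupling_field <- function(dx, dy, h, ax, ay, az, model) {
  gain <- model$field_scale * if (isTRUE(model$upgraded)) model$shielding_gain else 1
  r2 <- dx * dx + dy * dy + h * h
  r5 <- r2 * r2 * sqrt(r2)
  bx <- 3 * h * dx / r5
  by <- 3 * h * dy / r5
  bz <- (2 * h * h - dx * dx - dy * dy) / r5
  gain * abs(bx * ax + by * ay + bz * az)
}

#' Tag-coil coupling strength
#'
#' Signal strength for a tag at \code{lateral_offset} cm horizontally from
#' the active coil centre and \code{tag_height} cm above the plate, with the
#' given long-axis orientation.  Strictly decreasing in height directly above
#' the coil centre and vanishing at large distance.
#'
#' @param tag_height Height above the plate, cm (> 0).
#' @param tag_axis Unit 3-vector, tag long axis (x = towards the coil when
#'   offset).
#' @param lateral_offset Horizontal distance from the coil centre, cm.
#' @param model A \code{\link{coupling_model}}.
#' @return Dimensionless signal strength >= 0.
#' @export
coupling <- function(tag_height, tag_axis, lateral_offset = 0,
                     model = coupling_model()) {
  if (any(tag_height <= 0)) stop("tag_height must be > 0", call. = FALSE)
  coupling_field(lateral_offset, 0, tag_height,
                 tag_axis[1], tag_axis[2], tag_axis[3], model)
}

# Longest supra-threshold dwell (seconds) of a coupling series sampled at
# times tt, with run boundaries refined by linear interpolation.
longest_dwell <- function(tt, s, thr) {
  supra <- s >= thr
  if (!any(supra)) return(0)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    t_enter <- tt[i]
    if (i > 1L) {
      f <- (thr - s[i - 1L]) / (s[i] - s[i - 1L])
      t_enter <- tt[i - 1L] + f * (tt[i] - tt[i - 1L])
    }
    t_exit <- tt[j]
    if (j < length(tt)) {
      f <- (s[j] - thr) / (s[j] - s[j + 1L])
      t_exit <- tt[j] + f * (tt[j + 1L] - tt[j])
      t_exit <- min(t_exit, tt[length(tt)])
    }
    best <- max(best, t_exit - t_enter)
  }
  best
}

#' Resolve tag reads for one antenna activation
#'
#' Applies the charge-dwell and collision rules to tag poses sampled over a
#' single activation window: a tag is readable only if its coupling stays at
#' or above the read threshold continuously for at least \code{min_dwell};
#' among readable tags only the one with the highest time-averaged coupling
#' is reported.
#'
#' @param poses Data frame of tag poses sampled over the activation, with
#'   columns \code{t} (s), \code{tag_id}, \code{x}, \code{y} (tag position,
#'   cm), \code{tag_height}, \code{tag_axis_x}, \code{tag_axis_y},
#'   \code{tag_axis_z}.
#' @param antenna Antenna index (1..12).
#' @param array An \code{\link{antenna_array}}.
#' @param model A \code{\link{coupling_model}}.
#' @return A one-row \code{data.table} (\code{t}, \code{antenna},
#'   \code{tag_id}, \code{mean_coupling}) or \code{NULL} when no tag is
#'   readable.
#' @export
resolve_reads <- function(poses, antenna, array = antenna_array(),
                          model = coupling_model()) {
  cen <- array$centroids[antenna, ]
  thr <- model$read_threshold
  best_id <- NULL; best_mean <- -Inf
  for (id in unique(poses$tag_id)) {
    p <- poses[poses$tag_id == id, ]
    p <- p[order(p$t), ]
    s <- coupling_field(p$x - cen$x, p$y - cen$y, p$tag_height,
                        p$tag_axis_x, p$tag_axis_y, p$tag_axis_z, model)
    if (longest_dwell(p$t, s, thr) >= model$min_dwell - model$dwell_tol) {
      m <- mean(s)
      if (m > best_mean) { best_mean <- m; best_id <- id }
    }
  }
  if (is.null(best_id)) return(NULL)
  data.table::data.table(t = min(poses$t), antenna = antenna,
                         tag_id = best_id, mean_coupling = best_mean)
}

#' Transponder temperature reading
#'
#' Adds uniform read error of +/- 0.5 degrees C, clamps to the transponder's
#' recording range 33.0-43.0 and quantises to 0.1 degrees C.  Uses the
#' current RNG state; seed upstream for determinism.
#'
#' @param true_temp True subcutaneous temperature(s), degrees C.
#' @param model A \code{\link{coupling_model}} (carries no temperature
#'   parameters at present; accepted for interface stability).
#' @return \code{data.table} with columns \code{temp_c} and \code{clamped}.
#' @export
temperature_reading <- function(true_temp, model = coupling_model()) {
  raw <- true_temp + stats::runif(length(true_temp), -0.5, 0.5)
  clamped <- raw < 33 | raw > 43
  data.table::data.table(temp_c = round(pmin(pmax(raw, 33), 43), 1),
                         clamped = clamped)
}

# Linear interpolation on the regular ground-truth grid (O(1) per query).
grid_interp <- function(v, tq, dt, nearest = FALSE) {
  n <- length(v)
  u <- tq / dt
  if (nearest) return(v[pmin(pmax(round(u) + 1, 1), n)])
  i0 <- pmin(pmax(floor(u) + 1, 1), n - 1L)
  w <- pmin(pmax(u - (i0 - 1), 0), 1)
  v[i0] * (1 - w) + v[i0 + 1L] * w
}

#' Simulate the raw tag-read stream for a session
#'
#' Iterates the polling schedule over the whole session, applying the dipole
#' coupling, charge-dwell and collision rules per activation, and emits a
#' chronologically ordered stream of tag reads with temperature readings.
#' Within each full scan cycle a tag is reported at most once (on the antenna
#' where its mean coupling was highest), so per-tag read rates are bounded by
#' \code{\link{max_read_frequency}}.
#'
#' Couplings are evaluated at the start, middle and end of each activation;
#' only activations where the tag crosses the read threshold within the
#' window are re-evaluated on the fine \code{subsample} grid with
#' interpolated threshold-crossing times.
#'
#' @param ground_truth Output of \code{\link{simulate_cohort}}.
#' @param array An \code{\link{antenna_array}}.
#' @param model A \code{\link{coupling_model}}.
#' @param seed Integer seed for the temperature read error.
#' @param duration Session length in seconds; defaults to the ground-truth
#'   extent.  Must not exceed the ground-truth extent.
#' @return \code{data.table} with columns \code{t} (activation start, s),
#'   \code{cycle}, \code{antenna}, \code{tag_id}, \code{temp_c},
#'   \code{clamped}, sorted by time.
#' @export
simulate_readstream <- function(ground_truth, array = antenna_array(),
                                model = coupling_model(), seed = 1,
                                duration = NULL) {
  cfg <- attr(ground_truth, "config")
  dt <- if (!is.null(cfg)) cfg$timestep else 0.1
  gt_dur <- if (nrow(ground_truth)) max(ground_truth$t) + dt else 0
  if (is.null(duration)) duration <- gt_dur
  if (duration > gt_dur + 1e-9)
    stop("ground truth (", gt_dur, " s) is shorter than the requested session (",
         duration, " s)", call. = FALSE)
  empty <- data.table::data.table(
    t = numeric(0), cycle = integer(0), antenna = integer(0),
    tag_id = character(0), temp_c = numeric(0), clamped = logical(0))
  ids <- unique(ground_truth$animal_id)
  n_ant <- nrow(array$centroids)
  cyc_s <- n_ant * array$slot_duration
  n_cycles <- floor(duration / cyc_s + 1e-9)
  if (nrow(ground_truth) == 0L || n_cycles == 0L) return(empty)

  set.seed(seed)
  per_tag <- lapply(ids, function(id) {
    sel <- which(ground_truth$animal_id == id)
    sel <- sel[order(ground_truth$t[sel])]
    list(tag_x = ground_truth$tag_x[sel], tag_y = ground_truth$tag_y[sel],
         tag_height = ground_truth$tag_height[sel],
         tag_axis_x = ground_truth$tag_axis_x[sel],
         tag_axis_y = ground_truth$tag_axis_y[sel],
         tag_axis_z = ground_truth$tag_axis_z[sel],
         true_temp = ground_truth$true_temp[sel])
  })
  names(per_tag) <- ids
  thr <- model$read_threshold
  act_s <- array$active_duration
  ax_x <- array$centroids$x; ax_y <- array$centroids$y

  chunk <- 20834L * n_ant
  n_act <- n_cycles * n_ant
  out <- list()
  noise_state <- matrix(NA_real_, n_ant, length(ids))
  phi <- exp(-cyc_s / model$coupling_noise_tau)
  isd <- model$coupling_noise_sd * sqrt(1 - phi^2)
  for (lo in seq(0L, n_act - 1L, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_act - 1L)
    k <- lo:hi
    cycle <- k %/% n_ant
    slot <- k %% n_ant
    t0 <- cycle * cyc_s + slot * array$slot_duration
    ant <- array$read_order[slot + 1L]
    cyc_lo <- lo %/% n_ant
    n_cyc <- (hi %/% n_ant) - cyc_lo + 1L
    cand <- list()
    for (ai in seq_along(ids)) {
      id <- ids[ai]
      g <- per_tag[[id]]
      # Slowly varying RF interference per tag-antenna pair: AR(1) log-noise
      # across scan cycles.  It gates whether the tag charges (readability);
      # the reported strength ranking stays at the noise-free coupling.
      lnoise <- NULL
      if (model$coupling_noise_sd > 0) {
        st <- noise_state[, ai]
        if (anyNA(st)) st <- stats::rnorm(n_ant, 0, model$coupling_noise_sd)
        innov <- matrix(stats::rnorm(n_ant * n_cyc, 0, isd), n_ant, n_cyc)
        lnoise <- matrix(0, n_ant, n_cyc)
        for (r in seq_len(n_ant))
          lnoise[r, ] <- stats::filter(innov[r, ], phi, "recursive",
                                       init = st[r])
        noise_state[, ai] <- lnoise[, n_cyc]
      }
      tm <- t0 + act_s / 2
      px <- grid_interp(g$tag_x, tm, dt)
      py <- grid_interp(g$tag_y, tm, dt)
      near <- which((px - ax_x[ant])^2 + (py - ax_y[ant])^2 <=
                      model$cull_radius^2)
      if (!length(near)) next
      eps <- if (is.null(lnoise)) rep(1, length(near)) else
        exp(lnoise[cbind(ant[near], cycle[near] - cyc_lo + 1L)])
      thr_i <- thr / eps
      s3 <- matrix(0, length(near), 3)
      hN <- grid_interp(g$tag_height, tm[near], dt, nearest = TRUE)
      axxN <- grid_interp(g$tag_axis_x, tm[near], dt, nearest = TRUE)
      axyN <- grid_interp(g$tag_axis_y, tm[near], dt, nearest = TRUE)
      axzN <- grid_interp(g$tag_axis_z, tm[near], dt, nearest = TRUE)
      for (j in 1:3) {
        tq <- t0[near] + (j - 1) * act_s / 2
        pxj <- grid_interp(g$tag_x, tq, dt)
        pyj <- grid_interp(g$tag_y, tq, dt)
        s3[, j] <- coupling_field(pxj - ax_x[ant[near]],
                                  pyj - ax_y[ant[near]],
                                  hN, axxN, axyN, axzN, model)
      }
      smin <- pmin(s3[, 1], s3[, 2], s3[, 3])
      smax <- pmax(s3[, 1], s3[, 2], s3[, 3])
      readable <- smin >= thr_i
      smean <- rowMeans(s3)
      # boundary crossers: refine on the fine subsample grid
      amb <- which(!readable & smax >= thr_i)
      for (q in amb) {
        tq <- t0[near[q]] + seq(0, act_s, by = model$subsample)
        pxq <- grid_interp(g$tag_x, tq, dt)
        pyq <- grid_interp(g$tag_y, tq, dt)
        sq <- coupling_field(pxq - ax_x[ant[near[q]]],
                             pyq - ax_y[ant[near[q]]],
                             hN[q], axxN[q], axyN[q], axzN[q], model)
        if (longest_dwell(tq, sq, thr_i[q]) >= model$min_dwell - model$dwell_tol) {
          readable[q] <- TRUE
          smean[q] <- mean(sq)
        }
      }
      sel <- which(readable)
      if (!length(sel)) next
      cand[[id]] <- data.table::data.table(
        k = k[near[sel]], cycle = cycle[near[sel]], antenna = ant[near[sel]],
        t = t0[near[sel]], tag_id = id, strength = smean[sel])
    }
    if (!length(cand)) next
    cd <- data.table::rbindlist(cand)
    # collision rule: one tag per activation (strongest wins)
    data.table::setorder(cd, k, -strength)
    cd <- cd[!duplicated(cd$k), ]
    # one read per tag per cycle (strongest activation wins)
    data.table::setorder(cd, tag_id, cycle, -strength, k)
    cd <- cd[!duplicated(cd[, c("tag_id", "cycle")]), ]
    out[[length(out) + 1L]] <- cd
  }
  if (!length(out)) return(empty)
  reads <- data.table::rbindlist(out)
  data.table::setorder(reads, t)
  temp_true <- numeric(nrow(reads))
  for (id in ids) {
    idx <- which(reads$tag_id == id)
    if (length(idx))
      temp_true[idx] <- grid_interp(per_tag[[id]]$true_temp, reads$t[idx], dt)
  }
  tr <- temperature_reading(temp_true, model)
  data.table::data.table(t = reads$t, cycle = as.integer(reads$cycle),
                         antenna = as.integer(reads$antenna),
                         tag_id = reads$tag_id,
                         temp_c = tr$temp_c, clamped = tr$clamped)
}

#' Minimum supra-threshold dwell for a successful read
#'
#' Sweeps a tag across one antenna's active detection field at crossing
#' speeds chosen so that its coupling stays above the read threshold for a
#' controlled dwell time (noise off), and reports the smallest dwell on the
#' grid that yields a read.  At the defaults this recovers the transponder's
#' 60 ms charge-and-read time.
#'
#' @param model A \code{\link{coupling_model}}; noise is disabled for the
#'   sweep.
#' @param array An \code{\link{antenna_array}}.
#' @param dwell_grid Candidate dwell times in milliseconds.
#' @param tag_height Crossing height, cm.
#' @return Smallest dwell (ms) producing a \code{TagRead}, or \code{NA} if
#'   none does.
#' @export
minimum_read_dwell <- function(model = calibrated_model(coupling_noise_sd = 0),
                               array = antenna_array(),
                               dwell_grid = seq(10, 150, by = 10),
                               tag_height = 6) {
  model$coupling_noise_sd <- 0
  cen <- array$centroids[1, ]
  axis <- c(0, 0, 1)
  f <- function(rho) coupling(tag_height, axis, rho, model) - model$read_threshold
  if (f(0) <= 0) stop("tag is sub-threshold above the coil centre; lower ",
                      "tag_height", call. = FALSE)
  rho_thr <- stats::uniroot(f, c(0, sqrt(2) * tag_height - 1e-6))$root
  tt <- seq(0, array$active_duration, by = model$subsample)
  for (d_ms in sort(dwell_grid)) {
    v <- 2 * rho_thr / (d_ms / 1000)  # crossing speed for this dwell
    poses <- data.table::data.table(
      t = tt, tag_id = "sweep", x = cen$x - rho_thr + v * tt, y = cen$y,
      tag_height = tag_height, tag_axis_x = axis[1], tag_axis_y = axis[2],
      tag_axis_z = axis[3])
    if (!is.null(resolve_reads(poses, 1L, array, model))) return(d_ms)
  }
  NA_real_
}

#' Per-tag read rate
#'
#' @param reads Read stream from \code{\link{simulate_readstream}}.
#' @param duration Session length, seconds.
#' @param tag_ids Optional tag ids to include (zero-read tags count as 0 Hz).
#' @return \code{data.table} with \code{tag_id}, \code{n_reads},
#'   \code{read_rate_hz}.
#' @export
read_rate <- function(reads, duration, tag_ids = NULL) {
  if (is.null(tag_ids)) tag_ids <- unique(reads$tag_id)
  n <- vapply(tag_ids, function(id) sum(reads$tag_id == id), integer(1))
  data.table::data.table(tag_id = tag_ids, n_reads = n,
                         read_rate_hz = n / duration)
}
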