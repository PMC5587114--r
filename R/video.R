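# Synthetic side-view grayscale video and whole-cage motion analytics:
# frame differencing, vertical-activity (rearing proxy) episode detection
# above a calibrated height line, and per-individual assignment via the
# RFID track.

#' Side-view camera configuration
#'
#' Orthographic side projection of the cage: columns map to the cage x axis,
#' rows to height above the floor.  \code{cm_per_px} and \code{floor_row}
#' form the calibration record that converts the vertical-activity height
#' threshold (8 cm at the far wall) into a pixel row.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frames per second.
#' @param cm_per_px Centimetres per pixel at the far wall.
#' @param floor_row Pixel row (from the top) of the cage floor at the far
#'   wall.
#' @param x_origin_px Column of cage coordinate x = 0.
#' @param line_cm Vertical-activity height threshold, cm.
#' @param background Background intensity (0-255).
#' @param rat_intensity Rat body intensity (0-255).
#' @param noise_sd Additive Gaussian pixel noise SD; 0 = noise-free.  Kept
#'   well below \code{diff_threshold} so that differenced noise (SD
#'   \code{noise_sd * sqrt(2)}) essentially never crosses it.
#' @return A \code{camera_config} list.
#' @export
camera_config <- function(width = 320, height = 180, fps = 25,
                          cm_per_px = 1 / 6, floor_row = 170,
                          x_origin_px = 10, line_cm = 8,
                          background = 40, rat_intensity = 150,
                          noise_sd = 1) {
  stopifnot(width > 0, height > 0, fps > 0, cm_per_px > 0)
  structure(list(width = width, height = height, fps = fps,
                 cm_per_px = cm_per_px, floor_row = floor_row,
                 x_origin_px = x_origin_px, line_cm = line_cm,
                 background = background, rat_intensity = rat_intensity,
                 noise_sd = noise_sd),
            class = "camera_config")
}

#' Pixel row of a height threshold
#'
#' @param camera A \code{\link{camera_config}}.
#' @param height_cm Height above the floor, cm; defaults to the camera's
#'   vertical-activity line.
#' @return Integer row; pixels in rows strictly above (smaller than) this
#'   row are above the line.
#' @export
line_row <- function(camera, height_cm = camera$line_cm) {
  as.integer(round(camera$floor_row - height_cm / camera$cm_per_px))
}

# Body ellipse parameters (cm) per posture: horizontal and vertical
# semi-axes and centre height.  Rearing doubles the body height and raises
# the centre so the blob top clears the 8 cm line; walking stays below it.
# Upright postures bob slightly over time (rats sway while rearing), so the
# blob produces continuous image motion like a real animal.
posture_shape <- function(posture, t = 0) {
  # sawtooth bob (1 cm, 0.2 s period): at 25 fps the centre moves by 0.2 cm
  # (>1 px) every frame, so an upright animal is never motionless on camera
  bob <- ((t / 0.2) %% 1)
  switch(posture,
         walking  = c(hw = 10, hh = 3.5, ch = 3.5),
         resting  = c(hw = 10, hh = 3.0, ch = 3.0),
         rearing  = c(hw = 5,  hh = 7.0, ch = 7.0 + bob),
         climbing = c(hw = 5,  hh = 7.0, ch = 11.0 + bob),
         stop("unknown posture '", posture, "'", call. = FALSE))
}

#' Render synthetic side-view frames from ground truth
#'
#' Orthographic projection: each rat is a filled ellipse at its ground-truth
#' x position, with posture-dependent size (the blob height doubles and the
#' centre rises during rearing).  The static background carries a
#' tunnel-shaped enrichment fixture.  Additive Gaussian pixel noise is
#' seeded, so identical inputs give identical frames.
#'
#' @param ground_truth Output of \code{\link{simulate_cohort}}.
#' @param camera A \code{\link{camera_config}}.
#' @param seed Integer seed for the pixel noise.
#' @param t_start First frame time, seconds.
#' @param n_frames Number of frames; defaults to covering the ground truth.
#' @return A \code{frame_stream} list: \code{frames} (height x width x n
#'   integer array), \code{times}, \code{camera}.
#' @export
render_frames <- function(ground_truth, camera = camera_config(), seed = 1,
                          t_start = 0, n_frames = NULL) {
  cfg <- attr(ground_truth, "config")
  dt <- if (!is.null(cfg)) cfg$timestep else 0.1
  gt_dur <- if (nrow(ground_truth)) max(ground_truth$t) + dt else 0
  if (is.null(n_frames))
    n_frames <- max(0L, as.integer(floor((gt_dur - t_start) * camera$fps)))
  times <- t_start + (seq_len(n_frames) - 1L) / camera$fps
  if (n_frames > 0 && nrow(ground_truth) && max(times) > gt_dur + 1e-9)
    stop("ground truth does not cover the requested frames", call. = FALSE)
  set.seed(seed)
  h <- camera$height; w <- camera$width
  bg <- matrix(camera$background, h, w)
  # tunnel fixture: static half-ellipse, 10 cm tall, at x = 35..45 cm
  tun <- list(x = 40, hw = 5, hh = 10)
  cols_cm <- ((seq_len(w)) - camera$x_origin_px) * camera$cm_per_px
  rows_cm <- (camera$floor_row - seq_len(h)) * camera$cm_per_px
  tun_mask <- outer(rows_cm, cols_cm, function(z, x)
    (x - tun$x)^2 / tun$hw^2 + (z / tun$hh)^2 <= 1 & z >= 0)
  bg[tun_mask] <- 90
  ids <- unique(ground_truth$animal_id)
  gt_by <- lapply(ids, function(id) {
    sel <- which(ground_truth$animal_id == id)
    sel <- sel[order(ground_truth$t[sel])]
    list(x = ground_truth$x[sel], posture = ground_truth$posture[sel])
  })
  frames <- array(0L, dim = c(h, w, n_frames))
  for (f in seq_len(n_frames)) {
    img <- bg
    for (g in gt_by) {
      u <- times[f] / dt
      i <- pmin(pmax(round(u) + 1, 1), length(g$x))
      xc <- grid_interp(g$x, times[f], dt)
      sh <- posture_shape(g$posture[i], times[f])
      cl <- which(abs(cols_cm - xc) <= sh[["hw"]])
      rw <- which(abs(rows_cm - sh[["ch"]]) <= sh[["hh"]])
      if (!length(cl) || !length(rw)) next
      mask <- outer(rows_cm[rw], cols_cm[cl], function(z, x)
        (x - xc)^2 / sh[["hw"]]^2 + (z - sh[["ch"]])^2 / sh[["hh"]]^2 <= 1)
      sub <- img[rw, cl, drop = FALSE]
      sub[mask] <- camera$rat_intensity
      img[rw, cl] <- sub
    }
    if (camera$noise_sd > 0)
      img <- img + round(stats::rnorm(h * w, 0, camera$noise_sd))
    frames[, , f] <- pmin(pmax(as.integer(img), 0L), 255L)
  }
  structure(list(frames = frames, times = times, camera = camera),
            class = "frame_stream")
}

as_frame_array <- function(frames) {
  if (inherits(frames, "frame_stream")) frames$frames else frames
}

#' Whole-cage pixel motion by frame differencing
#'
#' For each consecutive frame pair, counts pixels whose absolute intensity
#' difference exceeds \code{diff_threshold}.
#'
#' @param frames A \code{frame_stream} or a height x width x n array.
#' @param diff_threshold Intensity difference threshold (0-255).
#' @return Integer vector of length n - 1 (empty for a single frame).
#' @export
pixel_motion <- function(frames, diff_threshold = 10) {
  a <- as_frame_array(frames)
  n <- dim(a)[3]
  if (n < 2L) return(integer(0))
  vapply(seq_len(n - 1L), function(i)
    sum(abs(a[, , i + 1L] - a[, , i]) > diff_threshold), integer(1))
}

#' Detect vertical-activity episodes
#'
#' A frame is "vertical" when any differenced pixel above the height line
#' (rows strictly above \code{line_row}) exceeds \code{diff_threshold}.
#' Runs of vertical frames form episodes; runs separated by fewer than
#' \code{min_frames} quiet frames are merged (hysteresis), and episodes
#' shorter than \code{min_frames} are discarded as single-frame noise.
#' Motion strictly below the line never contributes.
#'
#' @param frames A \code{frame_stream} or array.
#' @param line_row Pixel row of the height threshold (see
#'   \code{\link{line_row}}).
#' @param diff_threshold Intensity difference threshold.
#' @param min_frames Minimum episode length in frames.
#' @return \code{data.table} of episodes: \code{start_frame},
#'   \code{end_frame} (1-based frame indices, change attributed to the later
#'   frame), \code{peak_row}, \code{centroid_col}, \code{animal_id}
#'   (\code{NA} until assigned).  The per-frame vertical flag is attached as
#'   attribute \code{"vertical_frames"}.
#' @export
vertical_activity <- function(frames, line_row, diff_threshold = 10,
                              min_frames = 3) {
  a <- as_frame_array(frames)
  n <- dim(a)[3]
  stopifnot(line_row >= 1, line_row <= dim(a)[1], min_frames >= 1)
  rows_above <- seq_len(max(line_row - 1L, 0L))
  vert <- logical(max(n - 1L, 0L))
  peak <- rep(NA_integer_, max(n - 1L, 0L))
  cent <- rep(NA_real_, max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    d <- abs(a[rows_above, , i + 1L] - a[rows_above, , i]) > diff_threshold
    if (any(d)) {
      vert[i] <- TRUE
      wj <- which(d, arr.ind = TRUE)
      peak[i] <- min(wj[, 1])
      cent[i] <- mean(wj[, 2])
    }
  }
  ep <- data.table::data.table(start_frame = integer(0), end_frame = integer(0),
                               peak_row = integer(0), centroid_col = numeric(0),
                               animal_id = NA_character_[0])
  if (any(vert)) {
    r <- rle(vert)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # hysteresis: bridge quiet gaps shorter than min_frames
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < min_frames) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else merged <- rbind(merged, runs[i, ])
    }
    merged <- merged[merged$end - merged$start + 1L >= min_frames, ,
                     drop = FALSE]
    if (nrow(merged)) {
      ep <- data.table::data.table(
        start_frame = merged$start + 1L,  # diff attributed to later frame
        end_frame = merged$end + 1L,
        peak_row = vapply(seq_len(nrow(merged)), function(k)
          min(peak[merged$start[k]:merged$end[k]], na.rm = TRUE), integer(1)),
        centroid_col = vapply(seq_len(nrow(merged)), function(k)
          mean(cent[merged$start[k]:merged$end[k]], na.rm = TRUE), numeric(1)),
        animal_id = NA_character_)
    }
  }
  flag <- c(FALSE, vert)  # per-frame label, first frame has no diff
  data.table::setattr(ep, "vertical_frames", flag)
  ep
}

#' Assign individual identity to vertical-activity episodes
#'
#' Each episode is assigned to the animal whose RFID track x position is
#' horizontally nearest the episode's motion centroid at the episode
#' midpoint.  Ties and missing positions give an unassigned episode.
#'
#' @param episodes Output of \code{\link{vertical_activity}}.
#' @param track Output of \code{\link{build_tracks}}.
#' @param camera A \code{\link{camera_config}} (pixel-to-cm calibration).
#' @param times Frame timestamps (seconds), as in a \code{frame_stream}.
#' @return The episodes table with \code{animal_id} filled in.
#' @export
assign_episode_identity <- function(episodes, track, camera, times) {
  if (!nrow(episodes)) return(episodes)
  ids <- sort(unique(track$animal_id))
  out <- data.table::copy(episodes)
  for (e in seq_len(nrow(out))) {
    fmid <- as.integer(round((out$start_frame[e] + out$end_frame[e]) / 2))
    tmid <- times[min(max(fmid, 1L), length(times))]
    cx <- (out$centroid_col[e] - camera$x_origin_px) * camera$cm_per_px
    dist <- vapply(ids, function(id) {
      tr <- track[track$animal_id == id & !is.na(track$x), ]
      if (!nrow(tr)) return(NA_real_)
      j <- which.min(abs(tr$t - tmid))
      abs(tr$x[j] - cx)
    }, numeric(1))
    if (all(is.na(dist))) next
    best <- min(dist, na.rm = TRUE)
    hit <- which(!is.na(dist) & abs(dist - best) < 1e-9)
    if (length(hit) == 1L)
      data.table::set(out, e, "animal_id", ids[hit])
  }
  out
}

#' Frame-by-frame percent agreement
#'
#' @param labels_auto,labels_manual Equal-length logical (or 0/1) series.
#' @return Percent agreement in [0, 100].
#' @export
frame_accuracy <- function(labels_auto, labels_manual) {
  if (length(labels_auto) != length(labels_manual))
    stop("label series must have equal length", call. = FALSE)
  100 * mean(as.logical(labels_auto) == as.logical(labels_manual))
}
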