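# File formats and configuration: YAML/JSON run configuration with strict
# schema validation, CSV stream files (ground truth, reads, tracks, bins)
# with lossless round-trips, and PNG frame sequences with a JSON index.

default_run_config <- function() {
  list(
    schema_version = "1.0",
    seed = 1L,
    sim = list(
      cage_length = 50, cage_width = 38, n_animals = 3L,
      photoperiod = c(light = 12, dark = 12), duration = 86400,
      timestep = 0.1, dark_light_activity_ratio = 1.4,
      base_step_rate = 1.2, step_length = 3, turn_sd = 0.6,
      rest_bout = list(mean_rest_s = c(light = 270, dark = 270),
                       mean_active_s = c(light = 90, dark = 90)),
      rearing_rate = c(light = 12, dark = 20), rearing_duration = 2,
      climbing_rate = c(light = 1, dark = 2), climbing_duration = 5,
      implant_site = "ventral_midline", temp_baseline = 37.5,
      temp_dark_elevation = 0.5, temp_noise_sd = 0.1, temp_ar1 = 0.999),
    array = list(plate_length = 50, plate_width = 38, n_rows = 3L,
                 n_cols = 4L, slot_duration = 0.090,
                 active_duration = 0.075),
    coupling = list(upgraded = FALSE, min_dwell = 0.060, subsample = 0.005,
                    cull_radius = 22),
    camera = list(width = 320L, height = 180L, fps = 25, cm_per_px = 1 / 6,
                  floor_row = 170L, x_origin_px = 10L, line_cm = 8,
                  background = 40, rat_intensity = 150, noise_sd = 1),
    analysis = list(bin_size = 900, min_reads = 3L, max_gap = 5,
                    filter_variant = "confirm2", diff_threshold = 10,
                    min_frames = 3L, video_duration = 60),
    events = list())
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key '", here, "'", call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "events") {
      if (!is.list(user[[nm]]))
        stop("configuration key '", here, "' must be a mapping", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML or JSON run configuration, fills defaults for absent keys,
#' rejects unknown keys (naming the offending key) and checks the schema
#' version.  An empty file yields the all-defaults configuration.
#'
#' @param path File path (\code{.yaml}/\code{.yml}/\code{.json}), or
#'   \code{NULL} for the defaults.
#' @return A \code{run_config} list with sections \code{sim}, \code{array},
#'   \code{coupling}, \code{camera}, \code{analysis}, \code{events}.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  rc <- merge_config(default_run_config(), user)
  if (!identical(as.character(rc$schema_version), "1.0"))
    stop("unsupported schema_version '", rc$schema_version,
         "' (expected \"1.0\")", call. = FALSE)
  rc$seed <- as.integer(rc$seed)
  structure(rc, class = "run_config")
}

#' Write a run configuration
#'
#' @param rc A \code{run_config}.
#' @param path Destination (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(rc, path) {
  x <- unclass(rc)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else yaml::write_yaml(x, path)
  invisible(path)
}

unlist_num <- function(x) if (is.list(x)) unlist(x) else x

#' @rdname load_config
#' @export
as_sim_config <- function(rc) {
  s <- rc$sim
  s$photoperiod <- unlist_num(s$photoperiod)
  s$rearing_rate <- unlist_num(s$rearing_rate)
  s$climbing_rate <- unlist_num(s$climbing_rate)
  s$rest_bout <- lapply(s$rest_bout, unlist_num)
  do.call(sim_config, c(s, list(seed = rc$seed)))
}

#' @rdname load_config
#' @export
as_antenna_array <- function(rc) do.call(antenna_array, rc$array)

#' @rdname load_config
#' @export
as_coupling_model <- function(rc) {
  do.call(calibrated_model, rc$coupling)
}

#' @rdname load_config
#' @export
as_camera_config <- function(rc) do.call(camera_config, rc$camera)

#' @rdname load_config
#' @export
as_events <- function(rc) {
  lapply(rc$events, function(ev)
    perturbation_event(ev$kind, ev$t0, ev$duration, ev$magnitude))
}

stop_missing_cols <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Stream file input/output
#'
#' Reads and writes the pipeline's CSV stream files (RFC-4180, header row,
#' '.' decimal, UTF-8): ground truth, raw tag reads, tracks and bins.
#' Round-trips are lossless and order-preserving; basic validation reports
#' the offending column or line.
#'
#' @param series,reads,track,bins The table to write.
#' @param path CSV file path.
#' @name stream_io
#' @return Readers return a \code{data.table}; writers return \code{path}
#'   invisibly.
NULL

#' @rdname stream_io
#' @export
write_ground_truth <- function(series, path) {
  out <- data.table::data.table(
    time_s = series$t, animal_id = series$animal_id, x_cm = series$x,
    y_cm = series$y, posture = series$posture,
    tag_height_cm = series$tag_height, tag_axis_x = series$tag_axis_x,
    tag_axis_y = series$tag_axis_y, tag_axis_z = series$tag_axis_z,
    temp_c = series$true_temp, steps = series$steps,
    tag_x_cm = series$tag_x, tag_y_cm = series$tag_y)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_ground_truth <- function(path) {
  d <- data.table::fread(path)
  stop_missing_cols(d, c("time_s", "animal_id", "x_cm", "y_cm", "posture",
                         "tag_height_cm", "tag_axis_x", "tag_axis_y",
                         "tag_axis_z", "temp_c"), path)
  if (!"steps" %in% names(d)) d$steps <- NA_integer_
  if (!"tag_x_cm" %in% names(d)) d$tag_x_cm <- d$x_cm
  if (!"tag_y_cm" %in% names(d)) d$tag_y_cm <- d$y_cm
  for (id in unique(d$animal_id)) {
    ts <- d$time_s[d$animal_id == id]
    if (is.unsorted(ts))
      stop(path, ": non-monotone timestamps for animal ", id, call. = FALSE)
  }
  data.table::data.table(
    t = d$time_s, animal_id = as.character(d$animal_id), x = d$x_cm,
    y = d$y_cm, posture = d$posture, tag_height = d$tag_height_cm,
    tag_axis_x = d$tag_axis_x, tag_axis_y = d$tag_axis_y,
    tag_axis_z = d$tag_axis_z, true_temp = d$temp_c,
    steps = as.integer(d$steps), tag_x = d$tag_x_cm, tag_y = d$tag_y_cm)
}

#' @rdname stream_io
#' @export
write_reads <- function(reads, path) {
  out <- data.table::data.table(
    time_s = reads$t, cycle = reads$cycle, antenna = reads$antenna,
    tag_id = reads$tag_id, temp_c = reads$temp_c,
    clamped_flag = as.integer(reads$clamped))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_reads <- function(path, n_antennae = 12L) {
  d <- data.table::fread(path)
  stop_missing_cols(d, c("time_s", "cycle", "antenna", "tag_id", "temp_c",
                         "clamped_flag"), path)
  bad <- which(d$antenna < 1 | d$antenna > n_antennae)
  if (length(bad))
    stop(path, ": antenna out of range 1..", n_antennae, " at line ",
         bad[1] + 1L, call. = FALSE)
  if (is.unsorted(d$time_s))
    stop(path, ": non-monotone timestamps", call. = FALSE)
  data.table::data.table(t = d$time_s, cycle = as.integer(d$cycle),
                         antenna = as.integer(d$antenna),
                         tag_id = as.character(d$tag_id), temp_c = d$temp_c,
                         clamped = d$clamped_flag > 0)
}

#' @rdname stream_io
#' @export
write_track <- function(track, path) {
  out <- data.table::data.table(
    time_s = track$t, animal_id = track$animal_id, antenna = track$antenna,
    x_cm = track$x, y_cm = track$y, source = track$source)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_track <- function(path) {
  d <- data.table::fread(path)
  stop_missing_cols(d, c("time_s", "animal_id", "antenna", "x_cm", "y_cm",
                         "source"), path)
  data.table::data.table(t = d$time_s, animal_id = as.character(d$animal_id),
                         antenna = as.integer(d$antenna), x = d$x_cm,
                         y = d$y_cm, source = d$source)
}

#' @rdname stream_io
#' @export
write_bins <- function(bins, path) {
  out <- data.table::data.table(
    window_start_s = bins$window_start, window_end_s = bins$window_end,
    animal_id = bins$animal_id, n_transitions = bins$n_transitions,
    distance_cm = bins$distance_cm, mean_temp_c = bins$mean_temp,
    n_temp_reads = bins$n_reads, phase = bins$phase)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_bins <- function(path) {
  d <- data.table::fread(path)
  stop_missing_cols(d, c("window_start_s", "window_end_s", "animal_id",
                         "n_transitions", "distance_cm", "mean_temp_c",
                         "n_temp_reads", "phase"), path)
  data.table::data.table(
    window_start = d$window_start_s, window_end = d$window_end_s,
    animal_id = as.character(d$animal_id),
    n_transitions = as.integer(d$n_transitions), distance_cm = d$distance_cm,
    mean_temp = d$mean_temp_c, n_reads = as.integer(d$n_temp_reads),
    phase = d$phase)
}

#' Write/read a frame stream as a PNG sequence
#'
#' Frames are written as 8-bit grayscale PNGs plus an \code{index.json}
#' mapping frame number to timestamp and carrying the camera calibration.
#'
#' @param fs A \code{frame_stream}.
#' @param dir Directory for the sequence.
#' @return \code{write_frames} returns \code{dir} invisibly;
#'   \code{read_frames} returns a \code{frame_stream}.
#' @export
write_frames <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(fs$frames)[3]
  files <- sprintf("frame_%06d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(fs$frames[, , i] / 255, file.path(dir, files[i]))
  idx <- list(fps = fs$camera$fps, camera = unclass(fs$camera),
              frames = data.frame(file = files, time_s = fs$times))
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  idx <- jsonlite::fromJSON(file.path(dir, "index.json"))
  camera <- do.call(camera_config, idx$camera)
  n <- nrow(idx$frames)
  frames <- array(0L, dim = c(camera$height, camera$width, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, idx$frames$file[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[, , i] <- as.integer(round(img * 255))
  }
  structure(list(frames = frames, times = idx$frames$time_s, camera = camera),
            class = "frame_stream")
}
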