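# End-to-end pipeline: chains the simulator, baseplate reader, tracker,
# video analytics and validation statistics over a session bundle on disk.
# Every artifact is recorded in a manifest with its md5 and the producing
# configuration checksum, so mixed-provenance bundles are detected.

config_checksum <- function(rc) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(rc), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

manifest_path <- function(out) file.path(out, "manifest.json")

read_manifest <- function(out) {
  p <- manifest_path(out)
  if (!file.exists(p)) return(list(files = list()))
  jsonlite::fromJSON(p, simplifyVector = FALSE)
}

record_artifacts <- function(out, rc, paths) {
  man <- read_manifest(out)
  cs <- config_checksum(rc)
  man$seed <- rc$seed
  for (p in paths) {
    rel <- basename(p)
    md5 <- if (dir.exists(p)) unname(tools::md5sum(file.path(p, "index.json")))
           else unname(tools::md5sum(p))
    man$files[[rel]] <- list(md5 = md5, config_checksum = cs)
  }
  jsonlite::write_json(man, manifest_path(out), auto_unbox = TRUE, digits = NA)
  invisible(man)
}

require_artifact <- function(out, name, step) {
  p <- file.path(out, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run the '", step, "' step first",
         call. = FALSE)
  p
}

#' Run a pipeline step on a session bundle
#'
#' Subcommands: \code{simulate} (ground truth + event log), \code{reads}
#' (raw tag-read stream), \code{track} (flicker-filtered, interpolated
#' tracks), \code{video} (synthetic side-view frames + motion and
#' vertical-activity detection), \code{analyze} (activity/temperature bins,
#' light-dark summaries, regressions), \code{validate} (ICC, Bland-Altman
#' and rubric scores comparing baseplate-derived distance to the
#' ground-truth path), \code{report} (manifest check + summary).  Every
#' artifact records the producing configuration checksum and seed in
#' \code{manifest.json}; \code{report} refuses bundles with mixed checksums.
#'
#' @param cmd Subcommand name.
#' @param config A \code{run_config}, a path to one, or \code{NULL} for
#'   defaults.
#' @param out Output directory (the session bundle).
#' @param seed,duration,site,upgraded Optional overrides of the
#'   configuration.
#' @return Invisibly, a named list of artifact paths produced by the step.
#' @export
run_pipeline <- function(cmd, config = NULL, out = ".", seed = NULL,
                         duration = NULL, site = NULL, upgraded = NULL) {
  rc <- if (inherits(config, "run_config")) config else load_config(config)
  if (!is.null(seed)) rc$seed <- as.integer(seed)
  if (!is.null(duration)) rc$sim$duration <- duration
  if (!is.null(site)) rc$sim$implant_site <- site
  if (!is.null(upgraded)) rc$coupling$upgraded <- upgraded
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  arr <- as_antenna_array(rc)
  switch(cmd,
    simulate = {
      gt <- simulate_cohort(as_sim_config(rc), as_events(rc))
      p1 <- write_ground_truth(gt, file.path(out, "ground_truth.csv"))
      ev <- attr(gt, "events")
      p2 <- file.path(out, "events.csv")
      data.table::fwrite(ev, p2)
      record_artifacts(out, rc, c(p1, p2))
      invisible(list(ground_truth = p1, events = p2))
    },
    reads = {
      gt <- read_ground_truth(require_artifact(out, "ground_truth.csv",
                                               "simulate"))
      data.table::setattr(gt, "config", as_sim_config(rc))
      rd <- simulate_readstream(gt, arr, as_coupling_model(rc), seed = rc$seed)
      p <- write_reads(rd, file.path(out, "reads.csv"))
      record_artifacts(out, rc, p)
      invisible(list(reads = p))
    },
    track = {
      rd <- read_reads(require_artifact(out, "reads.csv", "reads"))
      tr <- build_tracks(rd, arr, duration = rc$sim$duration,
                         max_gap = rc$analysis$max_gap,
                         variant = rc$analysis$filter_variant)
      p <- write_track(tr, file.path(out, "track.csv"))
      record_artifacts(out, rc, p)
      invisible(list(track = p))
    },
    video = {
      gt <- read_ground_truth(require_artifact(out, "ground_truth.csv",
                                               "simulate"))
      data.table::setattr(gt, "config", as_sim_config(rc))
      cam <- as_camera_config(rc)
      nf <- as.integer(min(rc$analysis$video_duration, rc$sim$duration) *
                         cam$fps)
      fs <- render_frames(gt, cam, seed = rc$seed, n_frames = nf)
      pd <- write_frames(fs, file.path(out, "frames"))
      motion <- pixel_motion(fs, rc$analysis$diff_threshold)
      pm <- file.path(out, "motion.csv")
      data.table::fwrite(data.table::data.table(
        frame = seq_along(motion) + 1L, changed_pixels = motion), pm)
      ep <- vertical_activity(fs, line_row(cam), rc$analysis$diff_threshold,
                              rc$analysis$min_frames)
      trp <- file.path(out, "track.csv")
      if (file.exists(trp))
        ep <- assign_episode_identity(ep, read_track(trp), cam, fs$times)
      pe <- file.path(out, "episodes.csv")
      data.table::fwrite(ep, pe)
      record_artifacts(out, rc, c(pd, pm, pe))
      invisible(list(frames = pd, motion = pm, episodes = pe))
    },
    analyze = {
      rd <- read_reads(require_artifact(out, "reads.csv", "reads"))
      tr <- read_track(require_artifact(out, "track.csv", "track"))
      pp <- unlist_num(rc$sim$photoperiod)
      act <- count_transitions(tr, rc$analysis$bin_size,
                               duration = rc$sim$duration, photoperiod = pp)
      tmp <- bin_temperature(rd, rc$analysis$bin_size,
                             rc$analysis$min_reads,
                             duration = rc$sim$duration, photoperiod = pp)
      bins <- merge(act, tmp[, c("window_start", "animal_id", "mean_temp",
                                 "n_reads")],
                    by = c("window_start", "animal_id"), all.x = TRUE)
      data.table::setorder(bins, animal_id, window_start)
      pb <- write_bins(bins, file.path(out, "bins.csv"))
      res <- list(
        read_rate = as.list(stats::setNames(
          read_rate(rd, rc$sim$duration)$read_rate_hz,
          read_rate(rd, rc$sim$duration)$tag_id)),
        activity = light_dark_summary(act, "n_transitions"),
        temperature = light_dark_summary(tmp, "mean_temp"))
      res$regressions <- analyze_regressions(bins)
      pj <- file.path(out, "results.json")
      jsonlite::write_json(res, pj, auto_unbox = TRUE, digits = NA,
                           na = "null", force = TRUE)
      record_artifacts(out, rc, c(pb, pj))
      invisible(list(bins = pb, results = pj))
    },
    validate = {
      gt <- read_ground_truth(require_artifact(out, "ground_truth.csv",
                                               "simulate"))
      tr <- read_track(require_artifact(out, "track.csv", "track"))
      rd <- read_reads(require_artifact(out, "reads.csv", "reads"))
      v <- validate_tracking(gt, tr, rd, rc)
      pv <- file.path(out, "validate.json")
      jsonlite::write_json(v, pv, auto_unbox = TRUE, digits = NA,
                           na = "null", force = TRUE)
      record_artifacts(out, rc, pv)
      invisible(list(validate = pv))
    },
    report = {
      man <- read_manifest(out)
      if (!length(man$files)) stop("empty bundle: nothing to report",
                                   call. = FALSE)
      cs <- unique(vapply(man$files, function(f) f$config_checksum,
                          character(1)))
      if (length(cs) > 1)
        stop("mixed configuration checksums in bundle: ",
             paste(cs, collapse = ", "), call. = FALSE)
      for (nm in names(man$files)) {
        p <- file.path(out, nm)
        cur <- if (dir.exists(p)) unname(tools::md5sum(file.path(p, "index.json")))
               else unname(tools::md5sum(p))
        if (!identical(cur, man$files[[nm]]$md5))
          stop("artifact '", nm, "' does not match its manifest checksum",
               call. = FALSE)
      }
      txt <- c("session bundle report",
               paste0("  config checksum: ", cs),
               paste0("  seed: ", man$seed),
               paste0("  artifacts: ", paste(names(man$files), collapse = ", ")))
      pr <- file.path(out, "report.txt")
      writeLines(txt, pr)
      invisible(list(report = pr))
    },
    stop("unknown subcommand '", cmd, "'", call. = FALSE))
}

# Mixed-model (and fallback) fits over the binned data, mirroring the
# temperature/transition variance analyses: response ~ day + phase + (1|rat).
analyze_regressions <- function(bins) {
  d <- data.frame(
    y_act = bins$n_transitions,
    y_temp = bins$mean_temp,
    day = factor(floor(bins$window_start / 86400) + 1),
    phase = factor(bins$phase, levels = c("dark", "light")),
    rat = factor(bins$animal_id))
  out <- list()
  tidy <- function(fit) list(label = fit$label, sigma2 = fit$sigma2,
                             tau2 = fit$tau2,
                             terms = as.data.frame(fit$coefficients))
  multi_day <- nlevels(droplevels(d$day)) > 1
  f_act <- if (multi_day) y_act ~ day + phase + (1 | rat)
           else y_act ~ phase + (1 | rat)
  out$transitions <- tryCatch(tidy(fit_random_intercept(f_act, d)),
                              error = function(e) list(error = conditionMessage(e)))
  dt <- d[!is.na(d$y_temp), ]
  f_tmp <- if (multi_day) y_temp ~ day + phase + (1 | rat)
           else y_temp ~ phase + (1 | rat)
  out$temperature <- tryCatch(tidy(fit_random_intercept(f_tmp, dt)),
                              error = function(e) list(error = conditionMessage(e)))
  out
}

# Agreement between baseplate-derived distance and the ground-truth path,
# per animal per bin: ICC(1,k), Bland-Altman and the rubric scores.
validate_tracking <- function(gt, track, reads, rc) {
  bin <- rc$analysis$bin_size
  dur <- rc$sim$duration
  pp <- unlist_num(rc$sim$photoperiod)
  base <- count_transitions(track, bin, duration = dur, photoperiod = pp)
  truth <- true_path_bins(gt, bin, duration = dur,
                          step_length = rc$sim$step_length)
  m <- merge(base[, c("window_start", "animal_id", "distance_cm")],
             truth, by = c("window_start", "animal_id"))
  icc <- icc_1k(cbind(m$distance_cm, m$true_distance_cm))
  ba <- bland_altman(m$distance_cm, m$true_distance_cm)
  rr <- mean(read_rate(reads, dur)$read_rate_hz)
  list(icc = icc, bland_altman = ba,
       rubric = rubric_scores(read_freq_hz = rr, icc_tracking = icc$icc),
       n_bins = nrow(m))
}

#' Ground-truth activity per time bin
#'
#' Bins the generator's own step counts and path length: the reference
#' against which baseplate-derived distance is compared (truncation) and the
#' generator-level route for recovering the configured dark:light activity
#' ratio.
#'
#' @param gt Ground truth from \code{\link{simulate_cohort}}.
#' @param bin_size Bin width, seconds.
#' @param duration Session length, seconds.
#' @param step_length Step length used by the generator, cm.
#' @param photoperiod Hours of light and dark, for the phase label.
#' @return \code{data.table} with \code{window_start}, \code{window_end},
#'   \code{animal_id}, \code{true_steps}, \code{true_distance_cm},
#'   \code{phase}.
#' @export
true_path_bins <- function(gt, bin_size = 900, duration = NULL,
                           step_length = 3,
                           photoperiod = c(light = 12, dark = 12)) {
  if (is.null(duration)) duration <- max(gt$t) + 1e-9
  n_bins <- max(1L, as.integer(ceiling(duration / bin_size)))
  starts <- (seq_len(n_bins) - 1L) * bin_size
  ids <- sort(unique(gt$animal_id))
  out <- lapply(ids, function(id) {
    sel <- which(gt$animal_id == id)
    bin <- pmin(as.integer(floor(gt$t[sel] / bin_size)) + 1L, n_bins)
    stp <- tapply(gt$steps[sel], bin, sum)
    res <- data.table::data.table(
      window_start = starts, window_end = starts + bin_size, animal_id = id,
      true_steps = 0L, true_distance_cm = 0,
      phase = phase_of(starts, photoperiod))
    bi <- as.integer(names(stp))
    data.table::set(res, bi, "true_steps", as.integer(stp))
    data.table::set(res, bi, "true_distance_cm",
                    as.numeric(stp) * step_length)
    res
  })
  data.table::rbindlist(out)
}
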