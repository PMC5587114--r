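# Raw read streams -> per-animal tracks and binned activity/temperature.
# Raw reads are never modified: every track sample carries a source flag
# (read / filtered / interpolated / missing) so the raw stream is
# recoverable.

#' Flicker filter for antenna assignment series
#'
#' Removes spurious alternation between adjacent antennae when an animal sits
#' near a cell boundary.  Default rule (\code{"confirm2"}): a change of
#' antenna is accepted only when confirmed by the immediately following read
#' on the same new antenna; unconfirmed single-read excursions are replaced
#' by the held antenna.  The filter is idempotent and never reorders time.
#' A majority-of-3 median variant is available as \code{"majority3"}.
#'
#' @param s Integer (or factor/character) antenna assignment series in
#'   chronological order; \code{NA}s (missed cycles) are passed through
#'   untouched and ignored by the rule.
#' @param variant \code{"confirm2"} (default) or \code{"majority3"}.
#' @return Filtered series, same length and type.
#' @export
flicker_filter <- function(s, variant = c("confirm2", "majority3")) {
  variant <- match.arg(variant)
  obs <- which(!is.na(s))
  v <- s[obs]
  m <- length(v)
  if (m <= 1L) return(s)
  if (variant == "confirm2") {
    conf <- c(v[-m] == v[-1L], FALSE)
    anchor <- cummax(ifelse(conf, seq_len(m), 0L))
    out <- ifelse(anchor == 0L, v[1L], v[pmax(anchor, 1L)])
  } else {
    out <- v
    if (m >= 3L) {
      mid <- 2:(m - 1L)
      agree <- v[mid - 1L] == v[mid + 1L]
      out[mid][agree] <- v[mid - 1L][agree]
    }
  }
  s[obs] <- out
  s
}

#' Build per-animal tracks from a raw read stream
#'
#' Snaps each read to its antenna centroid, applies the flicker filter to the
#' per-animal assignment sequence, and fills missed polling cycles: gaps of
#' at most \code{max_gap} seconds are linearly interpolated in (x, y) and
#' flagged \code{"interpolated"}; longer gaps are flagged \code{"missing"}
#' with no invented positions.  Samples where the filter changed the raw
#' antenna are flagged \code{"filtered"}, untouched reads \code{"read"}.
#'
#' @param reads Read stream from \code{\link{simulate_readstream}}.
#' @param array An \code{\link{antenna_array}}.
#' @param duration Session length, seconds.
#' @param max_gap Longest gap (seconds) bridged by interpolation.
#' @param variant Flicker-filter variant, see \code{\link{flicker_filter}}.
#' @return \code{data.table} with one row per animal per polling cycle:
#'   \code{t} (cycle start, s), \code{animal_id}, \code{antenna} (\code{NA}
#'   when not read), \code{x}, \code{y} (cm; \code{NA} when missing),
#'   \code{source}.
#' @export
build_tracks <- function(reads, array = antenna_array(), duration,
                         max_gap = 5, variant = "confirm2") {
  cyc_s <- nrow(array$centroids) * array$slot_duration
  n_cycles <- max(1L, as.integer(floor(duration / cyc_s + 1e-9)))
  ids <- sort(unique(reads$tag_id))
  out <- lapply(ids, function(id) {
    r <- reads[reads$tag_id == id, ]
    assign <- rep(NA_integer_, n_cycles)
    assign[r$cycle + 1L] <- r$antenna
    interpolate_track(assign, array, max_gap = max_gap, animal_id = id,
                      variant = variant)
  })
  data.table::rbindlist(out)
}

#' Interpolate a filtered assignment series into a track
#'
#' @param assign Per-cycle antenna assignment (integer, \code{NA} = missed
#'   cycle), one element per polling cycle starting at cycle 0.
#' @param array An \code{\link{antenna_array}}.
#' @param max_gap Longest gap (seconds) bridged by linear interpolation.
#' @param animal_id Identifier stored in the output.
#' @param variant Flicker-filter variant applied before interpolation.
#' @return \code{data.table} as described in \code{\link{build_tracks}}.
#' @export
interpolate_track <- function(assign, array = antenna_array(), max_gap = 5,
                              animal_id = "animal", variant = "confirm2") {
  n <- length(assign)
  cyc_s <- nrow(array$centroids) * array$slot_duration
  filt <- flicker_filter(assign, variant = variant)
  x <- array$centroids$x[filt]
  y <- array$centroids$y[filt]
  source <- rep("missing", n)
  obs <- which(!is.na(filt))
  source[obs] <- ifelse(filt[obs] == assign[obs], "read", "filtered")
  if (length(obs) >= 2L) {
    gap_lo <- obs[-length(obs)]
    gap_hi <- obs[-1L]
    fill <- which(gap_hi - gap_lo > 1L &
                    (gap_hi - gap_lo) * cyc_s <= max_gap + 1e-9)
    for (g in fill) {
      i <- gap_lo[g]; j <- gap_hi[g]
      mid <- (i + 1L):(j - 1L)
      w <- (mid - i) / (j - i)
      x[mid] <- x[i] * (1 - w) + x[j] * w
      y[mid] <- y[i] * (1 - w) + y[j] * w
      source[mid] <- "interpolated"
    }
  }
  data.table::data.table(
    t = (seq_len(n) - 1L) * cyc_s, animal_id = animal_id,
    antenna = filt, x = x, y = y, source = source)
}

#' Count antenna transitions in time bins
#'
#' A transition is a change of the filtered antenna label between consecutive
#' labelled samples of one animal's track; \code{distance_cm} sums the
#' Euclidean centroid-to-centroid distances of those changes.  Each
#' transition is assigned to the bin containing the later sample.  Bins tile
#' \code{[0, duration)} without overlap.
#'
#' @param track Output of \code{\link{build_tracks}}.
#' @param bin_size Bin width, seconds (default 900 = 15 min).
#' @param duration Session length, seconds; defaults to the track extent.
#' @param photoperiod Hours of light and dark, for the phase label.
#' @return \code{data.table} with \code{window_start}, \code{window_end},
#'   \code{animal_id}, \code{n_transitions}, \code{distance_cm},
#'   \code{phase}.
#' @export
count_transitions <- function(track, bin_size = 900, duration = NULL,
                              photoperiod = c(light = 12, dark = 12)) {
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  if (is.null(duration)) duration <- max(track$t) + 1e-9
  n_bins <- max(1L, as.integer(ceiling(duration / bin_size)))
  starts <- (seq_len(n_bins) - 1L) * bin_size
  ids <- sort(unique(track$animal_id))
  out <- lapply(ids, function(id) {
    tr <- track[track$animal_id == id & !is.na(track$antenna), ]
    tr <- tr[order(tr$t), ]
    res <- data.table::data.table(
      window_start = starts, window_end = starts + bin_size, animal_id = id,
      n_transitions = 0L, distance_cm = 0,
      phase = phase_of(starts, photoperiod))
    if (nrow(tr) >= 2L) {
      chg <- which(tr$antenna[-1L] != tr$antenna[-nrow(tr)]) + 1L
      if (length(chg)) {
        bin <- pmin(as.integer(floor(tr$t[chg] / bin_size)) + 1L, n_bins)
        d <- sqrt((tr$x[chg] - tr$x[chg - 1L])^2 +
                    (tr$y[chg] - tr$y[chg - 1L])^2)
        cnt <- tapply(rep(1L, length(chg)), bin, sum)
        dst <- tapply(d, bin, sum)
        bi <- as.integer(names(cnt))
        data.table::set(res, bi, "n_transitions", as.integer(cnt))
        data.table::set(res, bi, "distance_cm", as.numeric(dst))
      }
    }
    res
  })
  data.table::rbindlist(out)
}

#' Bin transponder temperature readings
#'
#' Arithmetic mean of non-clamped temperature readings per animal per bin;
#' the mean is reported only when at least \code{min_reads} readings fall in
#' the bin.
#'
#' @param reads Read stream from \code{\link{simulate_readstream}}.
#' @param bin_size Bin width, seconds.
#' @param min_reads Minimum readings for a defined bin mean.
#' @param duration Session length, seconds; defaults to the read extent.
#' @param photoperiod Hours of light and dark, for the phase label.
#' @return \code{data.table} with \code{window_start}, \code{window_end},
#'   \code{animal_id}, \code{mean_temp} (\code{NA} when under-read),
#'   \code{n_reads}, \code{phase}.
#' @export
bin_temperature <- function(reads, bin_size = 900, min_reads = 3,
                            duration = NULL,
                            photoperiod = c(light = 12, dark = 12)) {
  if (is.null(duration)) duration <- if (nrow(reads)) max(reads$t) + 1e-9 else bin_size
  n_bins <- max(1L, as.integer(ceiling(duration / bin_size)))
  starts <- (seq_len(n_bins) - 1L) * bin_size
  ids <- sort(unique(reads$tag_id))
  out <- lapply(ids, function(id) {
    r <- reads[reads$tag_id == id & !reads$clamped, ]
    bin <- pmin(as.integer(floor(r$t / bin_size)) + 1L, n_bins)
    res <- data.table::data.table(
      window_start = starts, window_end = starts + bin_size, animal_id = id,
      mean_temp = NA_real_, n_reads = 0L,
      phase = phase_of(starts, photoperiod))
    if (nrow(r)) {
      cnt <- tapply(rep(1L, nrow(r)), bin, sum)
      mn <- tapply(r$temp_c, bin, mean)
      bi <- as.integer(names(cnt))
      data.table::set(res, bi, "n_reads", as.integer(cnt))
      data.table::set(res, bi, "mean_temp", as.numeric(mn))
    }
    under <- which(res$n_reads < min_reads)
    if (length(under)) data.table::set(res, under, "mean_temp", NA_real_)
    res
  })
  data.table::rbindlist(out)
}
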