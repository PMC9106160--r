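# The dual-minima detector: midswing positive peaks anchor each cycle; the
# negative velocity minimum before the peak is toe-off, the one after is heel
# strike. Also: GRF-threshold reference events and the zero-crossing TO
# estimate.

#' Detect midswing events (dominant positive velocity peaks)
#'
#' Midswing (MS) is the dominant positive peak of the shank angular velocity
#' in each gait cycle. Candidate peaks are interior local maxima with
#' positive value; a peak qualifies when its height reaches `peak_frac`
#' times the typical height of the tall-peak cluster (the median of all
#' candidate heights within a factor of two of the tallest), and qualifying
#' peaks closer together than `min_cycle_s` are thinned keeping the taller.
#' Both criteria are relative, so detection is invariant to positive
#' rescaling of the signal.
#'
#' @param x a `shank_signal` or a numeric filtered angular-velocity series.
#' @param fs sampling rate in Hz (ignored when `x` is a `shank_signal`).
#' @param peak_frac relative height criterion in (0, 1] (default 0.5).
#' @param min_cycle_s minimum separation between MS events in seconds
#'   (default 0.4, i.e. a cadence ceiling of 150 strides/min).
#' @param side,trial_id metadata stamped on the returned events.
#' @return gait-event data frame (`kind = "MS"`, `source = "kinematic"`)
#'   sorted by time, with `cycle_index` numbering the peaks.
#' @export
detect_midswing <- function(x, fs = NULL, peak_frac = 0.5, min_cycle_s = 0.4,
                            side = "left", trial_id = "trial") {
  sig <- as_omega(x, fs, side)
  omega <- sig$omega; fs <- sig$fs; side <- sig$side
  if (anyNA(omega)) stop("omega contains NA/NaN", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  stopifnot(peak_frac > 0)
  idx <- local_maxima(omega)
  idx <- idx[omega[idx] > 0]
  if (length(idx) == 0L) return(empty_events())
  h <- omega[idx]
  thr <- peak_frac * stats::median(h[h >= max(h) / 2])
  idx <- idx[h >= thr]
  idx <- thin_peaks(idx, omega[idx], min_sep = min_cycle_s * fs)
  make_events(trial_id, side, "MS", (idx - 1L) / fs, "kinematic",
              seq_along(idx))
}

# Greedy thinning: visit candidates tallest first (ties: earlier sample),
# keep those at least min_sep samples from every kept peak.
#' @noRd
thin_peaks <- function(idx, heights, min_sep) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-heights, idx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' @noRd
as_omega <- function(x, fs, side) {
  if (inherits(x, "shank_signal")) {
    list(omega = x$omega, fs = x$fs, side = x$side)
  } else {
    if (is.null(fs)) stop("fs is required when x is a plain series",
                          call. = FALSE)
    list(omega = as.numeric(x), fs = fs, side = side)
  }
}

#' Assign toe-off and heel-strike events around midswing peaks
#'
#' For each midswing (MS) event, the nearest negative-valued local minimum of
#' the velocity before the peak is marked toe-off (TO) and the nearest one
#' after it heel strike (HS). The search never crosses the adjacent MS
#' events. A boundary MS lacking a flanking negative minimum yields no event
#' for that flank (the cycle is incomplete, reported via a message). When one
#' single minimum sits between two consecutive MS peaks it serves as HS of
#' the earlier cycle and TO of the later one, with a warning.
#'
#' @param x a `shank_signal` or numeric filtered velocity series (the same
#'   series the MS events were detected on).
#' @param ms_events MS events from [detect_midswing()].
#' @inheritParams detect_midswing
#' @return gait-event data frame of TO and HS events (`source =
#'   "kinematic"`), sharing `cycle_index` with their MS event.
#' @export
detect_to_hs <- function(x, ms_events, fs = NULL, side = "left",
                         trial_id = "trial") {
  sig <- as_omega(x, fs, side)
  omega <- sig$omega; fs <- sig$fs; side <- sig$side
  if (anyNA(omega)) stop("omega contains NA/NaN", call. = FALSE)
  if (nrow(ms_events) == 0L) return(empty_events())
  if (is.unsorted(ms_events$time_s, strictly = TRUE)) {
    stop("ms_events must be strictly sorted by time", call. = FALSE)
  }
  ms_idx <- as.integer(round(ms_events$time_s * fs)) + 1L
  mins <- local_minima(omega)
  mins <- mins[omega[mins] < 0]
  n_ms <- length(ms_idx)
  out <- list()
  hs_prev <- NA_integer_
  shared <- FALSE
  incomplete <- 0L
  for (k in seq_len(n_ms)) {
    lo <- if (k > 1L) ms_idx[k - 1L] else 0L
    hi <- if (k < n_ms) ms_idx[k + 1L] else length(omega) + 1L
    before <- mins[mins > lo & mins < ms_idx[k]]
    after <- mins[mins > ms_idx[k] & mins < hi]
    ci <- ms_events$cycle_index[k]
    if (length(before) > 0L) {
      to_i <- max(before)
      if (!is.na(hs_prev) && to_i == hs_prev) shared <- TRUE
      out[[length(out) + 1L]] <-
        make_events(trial_id, side, "TO", (to_i - 1L) / fs, "kinematic", ci)
    } else incomplete <- incomplete + 1L
    if (length(after) > 0L) {
      hs_i <- min(after)
      hs_prev <- hs_i
      out[[length(out) + 1L]] <-
        make_events(trial_id, side, "HS", (hs_i - 1L) / fs, "kinematic", ci)
    } else {
      incomplete <- incomplete + 1L
      hs_prev <- NA_integer_
    }
  }
  if (shared) {
    warning("a single negative minimum between two midswing peaks was ",
            "assigned as both HS of the earlier cycle and TO of the later one",
            call. = FALSE)
  }
  if (incomplete > 0L) {
    message("detect_to_hs: ", incomplete,
            " boundary flank(s) without a negative minimum; ",
            "those cycles are incomplete")
  }
  if (length(out) == 0L) return(empty_events())
  sort_events(do.call(rbind, out))
}

#' Zero-crossing toe-off estimate
#'
#' The first negative-to-positive zero crossing of the shank velocity after a
#' detected TO, located by linear interpolation between the bracketing
#' samples. The interval between the TO minimum and this crossing is the
#' zone postulated to contain the true toe-off.
#'
#' @param x a `shank_signal` or numeric filtered velocity series.
#' @param to_event single-row TO event (kinematic source).
#' @inheritParams detect_midswing
#' @param next_ms_time search limit in seconds (the following MS event);
#'   `NULL` searches to the end of the series.
#' @return one-row gait-event data frame (`kind = "ZC"`), or an empty one
#'   (with a message) when the velocity does not cross zero before the limit.
#' @export
zero_crossing_to <- function(x, to_event, fs = NULL, next_ms_time = NULL,
                             side = "left", trial_id = "trial") {
  sig <- as_omega(x, fs, side)
  omega <- sig$omega; fs <- sig$fs; side <- sig$side
  stopifnot(is.data.frame(to_event), nrow(to_event) == 1L,
            to_event$kind == "TO")
  i0 <- as.integer(round(to_event$time_s * fs)) + 1L
  i1 <- length(omega) - 1L
  if (!is.null(next_ms_time)) {
    i1 <- min(i1, as.integer(round(next_ms_time * fs)))
  }
  if (i0 > i1) i0 <- i1
  for (i in i0:i1) {
    if (omega[i] < 0 && omega[i + 1L] >= 0) {
      t <- (i - 1L) / fs + (-omega[i]) / (omega[i + 1L] - omega[i]) / fs
      return(make_events(to_event$trial_id %||% trial_id, side, "ZC", t,
                         "kinematic", to_event$cycle_index))
    }
  }
  message("zero_crossing_to: no negative-to-positive crossing after TO at ",
          sprintf("%.3f s", to_event$time_s))
  empty_events()
}

#' Reference gait events from vertical ground reaction force
#'
#' Threshold detector on the vertical force of one belt/leg: an upward
#' crossing of `threshold_n` marks heel strike (event time at the first
#' sample at or above the threshold), a downward crossing marks toe-off (first
#' sample below). Spurious stance or swing episodes shorter than `debounce_s`
#' are merged away, and strict HS/TO alternation is enforced.
#'
#' @param force a [force_trial()].
#' @param side which force series to use (`"left"` or `"right"`).
#' @param threshold_n force threshold in newtons (default 20, a common
#'   treadmill convention).
#' @param debounce_s minimum duration of a stance/swing episode in seconds
#'   (default 0.05).
#' @return gait-event data frame of HS/TO events with `source = "force"`.
#' @export
grf_reference_events <- function(force, side, threshold_n = 20,
                                 debounce_s = 0.05) {
  stopifnot(inherits(force, "force_trial"))
  if (!side %in% names(force$fz)) {
    stop(sprintf("no force series for side '%s' (available: %s)", side,
                 paste(names(force$fz), collapse = ", ")), call. = FALSE)
  }
  fz <- force$fz[[side]]
  fs <- force$fs
  n <- length(fz)
  if (n < 2L) return(empty_events())
  above <- fz >= threshold_n
  if (!any(above) || all(above)) return(empty_events())
  d <- diff(above)
  up <- which(d == 1L) + 1L    # first sample at/above threshold
  down <- which(d == -1L) + 1L # first sample below threshold
  ev <- rbind(data.frame(i = up, kind = "HS", stringsAsFactors = FALSE),
              data.frame(i = down, kind = "TO", stringsAsFactors = FALSE))
  ev <- ev[order(ev$i), , drop = FALSE]
  # merge episodes shorter than the debounce window
  repeat {
    if (nrow(ev) < 2L) break
    dt <- diff(ev$i) / fs
    short <- which(dt < debounce_s)
    if (length(short) == 0L) break
    ev <- ev[-c(short[1L], short[1L] + 1L), , drop = FALSE]
  }
  if (nrow(ev) == 0L) return(empty_events())
  # enforce alternation, keeping the first of any same-kind run
  keep <- c(TRUE, ev$kind[-1L] != ev$kind[-nrow(ev)])
  if (!all(keep)) {
    warning("non-alternating force threshold crossings; duplicates dropped",
            call. = FALSE)
    ev <- ev[keep, , drop = FALSE]
  }
  make_events(force$trial_id, side, ev$kind, (ev$i - 1L) / fs, "force")
}

#' Run the full kinematic detection pipeline on a marker trial
#'
#' Convenience wrapper: for each requested side, build the shank velocity
#' signal, detect midswing peaks, and assign the flanking TO/HS events.
#'
#' @param trial a [marker_trial()].
#' @param sides character vector of sides to process.
#' @param zc also compute zero-crossing TO estimates (default `FALSE`).
#' @inheritParams detect_midswing
#' @inheritParams shank_signal_from_markers
#' @return gait-event data frame (kinds MS, TO, HS and optionally ZC) for all
#'   requested sides, sorted by time.
#' @export
detect_gait_events <- function(trial, sides = c("left", "right"),
                               fc = 4, order = 4L, auto_orient = TRUE,
                               peak_frac = 0.5, min_cycle_s = 0.4,
                               zc = FALSE) {
  out <- list()
  for (side in sides) {
    sig <- shank_signal_from_markers(trial, side, fc = fc, order = order,
                                     auto_orient = auto_orient)
    ms <- detect_midswing(sig, peak_frac = peak_frac,
                          min_cycle_s = min_cycle_s, trial_id = trial$trial_id)
    tohs <- detect_to_hs(sig, ms, trial_id = trial$trial_id)
    out[[length(out) + 1L]] <- ms
    out[[length(out) + 1L]] <- tohs
    if (isTRUE(zc) && nrow(tohs) > 0L) {
      tos <- tohs[tohs$kind == "TO", , drop = FALSE]
      for (j in seq_len(nrow(tos))) {
        nxt <- ms$time_s[ms$cycle_index == tos$cycle_index[j]]
        out[[length(out) + 1L]] <-
          zero_crossing_to(sig, tos[j, , drop = FALSE],
                           next_ms_time = if (length(nxt)) nxt else NULL,
                           trial_id = trial$trial_id)
      }
    }
  }
  sort_events(do.call(rbind, c(out, list(empty_events()))))
}
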