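# Trial containers and the CSV interchange dialect.
#
# Marker CSV dialect: optional first column "time_s", then one column per
# marker coordinate named <LABEL>_X / <LABEL>_Y / <LABEL>_Z; comma separated,
# decimal point, UTF-8. Force CSV: optional "time_s" plus Fz_<side> columns.

#' Construct a marker trial
#'
#' A `marker_trial` holds labelled 3D marker trajectories sampled at a common
#' rate, in metres. The lab-frame convention is carried in `axis_map`: which
#' coordinate axis is vertical and which points along the direction of
#' progression (the two axes spanning the sagittal plane).
#'
#' @param markers named list of numeric matrices, one per marker label, each
#'   `n_samples x 3` with columns `X`, `Y`, `Z` (metres).
#' @param fs sampling rate in Hz (> 0).
#' @param trial_id character identifier.
#' @param axis_map list with elements `vertical` and `forward`, each one of
#'   `"X"`, `"Y"`, `"Z"`. Default: vertical = Z, forward = Y, a common
#'   optical-mocap lab frame; confirm it against your lab's convention.
#' @return object of class `marker_trial` with fields `trial_id`, `fs`,
#'   `markers`, `n_samples`, `axis_map`, `gaps`.
#' @export
marker_trial <- function(markers, fs, trial_id = "trial",
                         axis_map = list(vertical = "Z", forward = "Y")) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.list(markers) || length(markers) == 0L ||
      is.null(names(markers)) || anyDuplicated(names(markers))) {
    stop("markers must be a non-empty named list with unique labels",
         call. = FALSE)
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker needs 3 columns (X, Y, Z)",
                            call. = FALSE)
    colnames(m) <- c("X", "Y", "Z")
    storage.mode(m) <- "double"
    m
  })
  ns <- unique(vapply(markers, nrow, integer(1)))
  if (length(ns) != 1L) {
    stop("all marker series must have the same number of samples",
         call. = FALSE)
  }
  stopifnot(all(c("vertical", "forward") %in% names(axis_map)),
            all(unlist(axis_map[c("vertical", "forward")]) %in%
                  c("X", "Y", "Z")))
  structure(list(trial_id = as.character(trial_id), fs = fs,
                 markers = markers, n_samples = ns,
                 axis_map = axis_map[c("vertical", "forward")],
                 gaps = NULL),
            class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial '%s'> %d markers x %d samples @ %g Hz (%.2f s)\n",
              x$trial_id, length(x$markers), x$n_samples, x$fs,
              x$n_samples / x$fs))
  cat("  labels:", paste(names(x$markers), collapse = ", "), "\n")
  cat(sprintf("  axes: vertical = %s, forward = %s\n",
              x$axis_map$vertical, x$axis_map$forward))
  invisible(x)
}

#' Construct a force trial
#'
#' Vertical ground-reaction-force series per side (newtons), typically from a
#' split-belt instrumented treadmill, sampled at `fs` Hz.
#'
#' @param fz named list (`left`, `right`, or a subset) of numeric vectors.
#' @param fs sampling rate in Hz (> 0).
#' @param trial_id character identifier.
#' @return object of class `force_trial`.
#' @export
force_trial <- function(fz, fs, trial_id = "trial") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.list(fz) || length(fz) == 0L || is.null(names(fz))) {
    stop("fz must be a named list of force series", call. = FALSE)
  }
  fz <- lapply(fz, as.numeric)
  if (!all(vapply(fz, function(v) all(is.finite(v)), logical(1)))) {
    stop("force series must be finite", call. = FALSE)
  }
  structure(list(trial_id = as.character(trial_id), fs = fs, fz = fz),
            class = "force_trial")
}

#' @export
print.force_trial <- function(x, ...) {
  n <- length(x$fz[[1L]])
  cat(sprintf("<force_trial '%s'> sides: %s; %d samples @ %g Hz (%.2f s)\n",
              x$trial_id, paste(names(x$fz), collapse = ", "), n, x$fs,
              n / x$fs))
  invisible(x)
}

#' Read labelled marker trajectories from CSV
#'
#' Expects columns `<LABEL>_X`, `<LABEL>_Y`, `<LABEL>_Z` and optionally a
#' leading `time_s` column. Missing samples (empty cells / NA) are treated as
#' gaps: runs of up to `max_gap_samples` are linearly interpolated with a
#' warning; longer runs are kept as NA and invalidate downstream cycles.
#'
#' @param path file path.
#' @param fs sampling rate in Hz; if `NULL`, inferred from the `time_s`
#'   column (required in that case).
#' @param axis_map lab-frame convention, see [marker_trial()].
#' @param trial_id identifier; defaults to the file name.
#' @param max_gap_samples longest gap that is interpolated (default 10).
#' @return a [marker_trial()].
#' @export
read_marker_csv <- function(path, fs = NULL,
                            axis_map = list(vertical = "Z", forward = "Y"),
                            trial_id = NULL, max_gap_samples = 10L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: no data rows in ", path,
                           call. = FALSE)
  cols <- names(df)
  has_time <- length(cols) > 0L && cols[1L] == "time_s"
  marker_cols <- if (has_time) cols[-1L] else cols
  bad <- marker_cols[!grepl("^.+_[XYZ]$", marker_cols)]
  if (length(bad) > 0L) {
    stop("malformed header: column(s) not of the form <LABEL>_X|_Y|_Z: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels <- unique(sub("_[XYZ]$", "", marker_cols))
  missing_axes <- unlist(lapply(labels, function(lab) {
    need <- paste0(lab, "_", c("X", "Y", "Z"))
    need[!need %in% marker_cols]
  }))
  if (length(missing_axes) > 0L) {
    stop("malformed header: missing coordinate column(s): ",
         paste(missing_axes, collapse = ", "), call. = FALSE)
  }
  if (is.null(fs)) {
    if (!has_time) {
      stop("fs not given and no 'time_s' column to infer it from",
           call. = FALSE)
    }
    dt <- diff(df$time_s)
    fs <- 1 / stats::median(dt)
  }
  markers <- lapply(labels, function(lab) {
    as.matrix(df[paste0(lab, "_", c("X", "Y", "Z"))])
  })
  names(markers) <- labels
  trial <- marker_trial(markers, fs = fs,
                        trial_id = trial_id %||% basename(path),
                        axis_map = axis_map)
  fill_marker_gaps(trial, max_gap_samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Interpolate short gaps (<= max_gap samples) per coordinate; keep long ones
# as NA and record all gap runs in trial$gaps.
#' @noRd
fill_marker_gaps <- function(trial, max_gap) {
  gaps <- list()
  for (lab in names(trial$markers)) {
    m <- trial$markers[[lab]]
    for (j in 1:3) {
      v <- m[, j]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        len <- r$lengths[k]
        interior <- starts[k] > 1L && ends[k] < length(v)
        filled <- interior && len <= max_gap
        gaps[[length(gaps) + 1L]] <- data.frame(
          label = lab, start = starts[k], end = ends[k],
          filled = filled, stringsAsFactors = FALSE)
        if (filled) {
          i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
          v[starts[k]:ends[k]] <-
            v[i0] + (v[i1] - v[i0]) * (seq_len(len)) / (len + 1L)
        }
      }
      m[, j] <- v
    }
    trial$markers[[lab]] <- m
  }
  if (length(gaps) > 0L) {
    gdf <- unique(do.call(rbind, gaps))
    trial$gaps <- gdf
    n_fill <- sum(gdf$filled)
    warning(sprintf(
      "%d gap run(s) in marker data; %d interpolated (<= %d samples), %d left as NA",
      nrow(gdf), n_fill, as.integer(max_gap), nrow(gdf) - n_fill),
      call. = FALSE)
  }
  trial
}

#' Write a marker trial to CSV
#'
#' Inverse of [read_marker_csv()]; writes a `time_s` column followed by the
#' `<LABEL>_X/_Y/_Z` coordinate columns at full double precision.
#'
#' @param trial a [marker_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  out <- data.frame(time_s = (seq_len(trial$n_samples) - 1L) / trial$fs)
  for (lab in names(trial$markers)) {
    m <- trial$markers[[lab]]
    out[[paste0(lab, "_X")]] <- m[, 1L]
    out[[paste0(lab, "_Y")]] <- m[, 2L]
    out[[paste0(lab, "_Z")]] <- m[, 3L]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read per-side vertical force from CSV
#'
#' Expects `Fz_<side>` columns (e.g. `Fz_left`, `Fz_right`) and optionally a
#' leading `time_s` column.
#'
#' @inheritParams read_marker_csv
#' @return a [force_trial()].
#' @export
read_force_csv <- function(path, fs = NULL, trial_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: no data rows in ", path,
                           call. = FALSE)
  cols <- names(df)
  fz_cols <- grep("^Fz_", cols, value = TRUE)
  if (length(fz_cols) == 0L) {
    stop("malformed header: no Fz_<side> column found", call. = FALSE)
  }
  if (is.null(fs)) {
    if (!"time_s" %in% cols) {
      stop("fs not given and no 'time_s' column to infer it from",
           call. = FALSE)
    }
    fs <- 1 / stats::median(diff(df$time_s))
  }
  fz <- lapply(fz_cols, function(cc) df[[cc]])
  names(fz) <- sub("^Fz_", "", fz_cols)
  force_trial(fz, fs = fs, trial_id = trial_id %||% basename(path))
}

#' Write a force trial to CSV
#' @param trial a [force_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(trial, path) {
  stopifnot(inherits(trial, "force_trial"))
  out <- data.frame(time_s = (seq_along(trial$fz[[1L]]) - 1L) / trial$fs)
  for (side in names(trial$fz)) out[[paste0("Fz_", side)]] <- trial$fz[[side]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write gait events to CSV
#'
#' One row per event with columns `trial_id, side, kind, time_s, source,
#' cycle_index`; times printed at millisecond precision. Events must be
#' sortable by time (no NA/NaN).
#'
#' @param events gait-event data frame (see [detect_gait_events()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- check_events(events)
  events <- sort_events(events)
  events$time_s <- sprintf("%.3f", events$time_s)
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read gait events written by [write_events()]
#' @param path file path.
#' @return gait-event data frame sorted by time.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "side", "kind", "time_s", "source", "cycle_index")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("malformed events file, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(empty_events())
  df$trial_id <- as.character(df$trial_id)
  df$side <- as.character(df$side)
  df$kind <- as.character(df$kind)
  df$source <- as.character(df$source)
  df$cycle_index <- as.integer(df$cycle_index)
  sort_events(df[need])
}

#' @noRd
check_events <- function(events) {
  need <- c("trial_id", "side", "kind", "time_s", "source", "cycle_index")
  if (!is.data.frame(events)) stop("events must be a data frame",
                                   call. = FALSE)
  missing <- setdiff(need, names(events))
  if (length(missing) > 0L) {
    stop("events missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) > 0L && anyNA(events$time_s)) {
    stop("event times contain NA/NaN", call. = FALSE)
  }
  events[need]
}

#' Write temporal gait parameters to CSV
#'
#' One row per complete gait cycle with columns `trial_id, side, cycle_index,
#' step_s, stride_s, stance_s, swing_s`.
#'
#' @param params parameter data frame from [compute_params()].
#' @param path output file path.
#' @param trial_id identifier written when `params` lacks the column.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, trial_id = "trial") {
  need <- c("side", "cycle_index", "step_s", "stride_s", "stance_s", "swing_s")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L) {
    stop("params missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"trial_id" %in% names(params)) params$trial_id <- trial_id
  utils::write.csv(params[c("trial_id", need)], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read temporal gait parameters written by [write_params()]
#' @param path file path.
#' @return parameter data frame.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
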