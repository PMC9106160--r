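# Internal helpers shared across modules.

#' Indices of strict interior local maxima
#'
#' A plateau of equal samples counts once, at its first index.
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] >= x[i + 1L]) + 1L
}

#' @noRd
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(x[i] < x[i - 1L] & x[i] <= x[i + 1L]) + 1L
}

#' Remove +/- 2*pi discontinuities from a wrapped angle series
#' @noRd
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jump <- round(d / (2 * pi))
  theta - c(0, cumsum(jump)) * 2 * pi
}

#' Expand a scalar or named per-side value to c(left = , right = )
#' @noRd
per_side <- function(x, name) {
  sides <- c("left", "right")
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), 2L), sides))
  }
  if (!all(sides %in% names(x))) {
    stop(sprintf("'%s' must be a scalar or named with both 'left' and 'right'",
                 name), call. = FALSE)
  }
  stats::setNames(as.numeric(x[sides]), sides)
}

#' @noRd
other_side <- function(side) {
  switch(side, left = "right", right = "left",
         stop("side must be 'left' or 'right'", call. = FALSE))
}

#' Empty gait-event data frame with the canonical columns
#' @noRd
empty_events <- function() {
  data.frame(trial_id = character(0), side = character(0),
             kind = character(0), time_s = numeric(0),
             source = character(0), cycle_index = integer(0),
             stringsAsFactors = FALSE)
}

#' Assemble a gait-event data frame, recycling scalar metadata
#' @noRd
make_events <- function(trial_id, side, kind, time_s, source,
                        cycle_index = NA_integer_) {
  if (length(time_s) == 0L) return(empty_events())
  data.frame(trial_id = trial_id, side = side, kind = kind,
             time_s = as.numeric(time_s), source = source,
             cycle_index = as.integer(cycle_index),
             stringsAsFactors = FALSE)
}

#' Sort events by time and check sanity
#' @noRd
sort_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  if (anyNA(events$time_s)) {
    stop("event times contain NA/NaN", call. = FALSE)
  }
  events[order(events$time_s), , drop = FALSE]
}
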