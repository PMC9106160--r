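# Gait-cycle segmentation (HS-to-HS per leg) and the four temporal
# parameters: step, stride, stance and swing time.

#' Segment events into complete gait cycles
#'
#' A complete cycle runs from one heel strike to the next of the same leg
#' (HS-HS) and must contain exactly one toe-off strictly between them; the
#' partial half-cycles at the start and end of a trial are discarded, and an
#' HS pair holding zero or more than one TO (a missed or spurious event) is
#' rejected with a warning. The contralateral heel strike attributed to a
#' cycle is the first opposite-side HS in `(hs_start, hs_end]`.
#'
#' Do not mix kinematic and force events in one call: build cycles per
#' source so every parameter is derived from a single method.
#'
#' @param events gait-event data frame containing HS and TO events for one or
#'   both sides (one source).
#' @param sides sides to segment (default both).
#' @return data frame with one row per complete cycle: `side, cycle_index,
#'   hs_start, to, hs_end, contralateral_hs` (NA when no opposite-side HS
#'   falls inside the cycle).
#' @export
build_cycles <- function(events, sides = c("left", "right")) {
  events <- check_events(events)
  events <- sort_events(events)
  if (length(unique(events$source)) > 1L) {
    stop("events from multiple sources; build cycles per source",
         call. = FALSE)
  }
  out <- list()
  rejected <- 0L
  for (side in sides) {
    hs <- events$time_s[events$side == side & events$kind == "HS"]
    to <- events$time_s[events$side == side & events$kind == "TO"]
    hs_opp <- events$time_s[events$side == other_side(side) &
                              events$kind == "HS"]
    if (length(hs) < 2L) next
    ci <- 0L
    for (j in seq_len(length(hs) - 1L)) {
      tos <- to[to > hs[j] & to < hs[j + 1L]]
      if (length(tos) != 1L) {
        rejected <- rejected + 1L
        next
      }
      contra <- hs_opp[hs_opp > hs[j] & hs_opp <= hs[j + 1L]]
      ci <- ci + 1L
      out[[length(out) + 1L]] <- data.frame(
        side = side, cycle_index = ci, hs_start = hs[j], to = tos,
        hs_end = hs[j + 1L],
        contralateral_hs = if (length(contra)) contra[1L] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (rejected > 0L) {
    warning(rejected, " HS-HS interval(s) without exactly one TO rejected",
            call. = FALSE)
  }
  if (length(out) == 0L) {
    warning("no complete gait cycles found", call. = FALSE)
    return(data.frame(side = character(0), cycle_index = integer(0),
                      hs_start = numeric(0), to = numeric(0),
                      hs_end = numeric(0), contralateral_hs = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Temporal gait parameters per cycle
#'
#' For each complete cycle: stance time = TO - HS_start, swing time =
#' HS_end - TO, stride time = stance + swing (algebraically HS_end -
#' HS_start; computed as the sum so that stance + swing equals stride
#' exactly, also in floating point), and step time = contralateral HS -
#' HS_start (NA when the cycle has no contralateral heel strike).
#'
#' @param cycles data frame from [build_cycles()] (one or more rows).
#' @return data frame `side, cycle_index, step_s, stride_s, stance_s,
#'   swing_s`, one row per cycle.
#' @export
compute_params <- function(cycles) {
  need <- c("side", "cycle_index", "hs_start", "to", "hs_end",
            "contralateral_hs")
  missing <- setdiff(need, names(cycles))
  if (length(missing) > 0L) {
    stop("cycles missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cycles) > 0L &&
      any(!(cycles$hs_start < cycles$to & cycles$to < cycles$hs_end))) {
    stop("invariant violated: need hs_start < to < hs_end in every cycle",
         call. = FALSE)
  }
  stance <- cycles$to - cycles$hs_start
  swing <- cycles$hs_end - cycles$to
  data.frame(side = cycles$side, cycle_index = cycles$cycle_index,
             step_s = cycles$contralateral_hs - cycles$hs_start,
             stride_s = stance + swing, stance_s = stance, swing_s = swing,
             stringsAsFactors = FALSE)
}

#' Events to temporal parameters in one step
#'
#' @inheritParams build_cycles
#' @return parameter data frame, see [compute_params()].
#' @export
temporal_params <- function(events, sides = c("left", "right")) {
  compute_params(build_cycles(events, sides = sides))
}
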