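# Shared helpers: run the kinematic pipeline on a synthetic trial and pull
# out truth landmarks, with messages silenced.

kin_events <- function(trial, side, ...) {
  sig <- shank_signal_from_markers(trial$markers, side)
  ms <- detect_midswing(sig, side = side, ...)
  tohs <- suppressWarnings(suppressMessages(
    detect_to_hs(sig, ms, side = side)))
  rbind(ms, tohs)
}

truth_landmark <- function(trial, side, kind) {
  lm <- trial$landmarks
  lm$time_s[lm$side == side & lm$kind == kind]
}

# Errors of detected kinematic events vs force-plate truth for both sides.
pipeline_errors <- function(trial) {
  pred <- rbind(kin_events(trial, "left"), kin_events(trial, "right"))
  pairs <- match_events(pred, trial$truth_events)
  event_errors(pairs)
}

quiet_trial <- function(...) {
  generate_trial(synthetic_config(...))
}

local_max_idx <- function(x) {
  i <- 2:(length(x) - 1)
  which(x[i] > x[i - 1] & x[i] >= x[i + 1]) + 1L
}

local_min_idx <- function(x) {
  i <- 2:(length(x) - 1)
  which(x[i] < x[i - 1] & x[i] <= x[i + 1]) + 1L
}

force_source <- function(ev) {
  ev$source <- "force"
  ev
}

make_to_event <- function(time_s) {
  data.frame(trial_id = "t", side = "left", kind = "TO", time_s = time_s,
             source = "kinematic", cycle_index = 1L,
             stringsAsFactors = FALSE)
}
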