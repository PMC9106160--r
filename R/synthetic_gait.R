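# Synthetic bilateral gait trials with ground truth: a smooth shank
# angular-velocity waveform per leg (one dominant midswing bump flanked by
# two negative minima per cycle, plus a small stance oscillation), tibia
# markers riding on the integrated orientation, and a vertical GRF trapezoid
# whose threshold crossings sit exactly at the true events.
#
# The timing offsets of the velocity minima relative to the true events are
# injectable per side: to_min_lead_ms places the first minimum BEFORE true
# toe-off (the early-TO phenomenon of the dual-minima rule), hs_min_lag_ms
# places the second minimum after true heel strike.

#' Configuration of a synthetic gait trial
#'
#' Defaults emulate slow amputee treadmill walking recorded by optical
#' motion capture at 200 Hz with belt-wise vertical force at 1000 Hz:
#' stride time 1.2 s (cadence 50 strides/min), stance fraction 0.62, a
#' midswing angular-velocity peak of 5 rad/s, and 2 mm marker noise. The
#' default minimum leads (left 80 ms, right 35 ms) reproduce the typical
#' side-asymmetric early toe-off of the dual-minima rule, with the left leg
#' playing the sound limb and the right the prosthetic one; the heel-strike
#' minima lag the true event slightly (left 5 ms, right 13 ms).
#'
#' @param n_cycles complete gait cycles per side (>= 1; default 25, about a
#'   30 s trial at the default cadence).
#' @param cadence_spm cadence in strides per minute (> 0; default 50).
#' @param stance_fraction fraction of the stride spent in stance, scalar or
#'   `c(left = , right = )`, each in (0, 1) (default 0.62).
#' @param ms_peak_amp amplitude of the midswing velocity peak in rad/s
#'   (default 5).
#' @param to_min_lead_ms time by which the pre-midswing velocity minimum
#'   precedes true toe-off, per side, in ms (>= 0; default left 80,
#'   right 35).
#' @param hs_min_lag_ms signed lag of the post-midswing minimum after true
#'   heel strike, per side, in ms (default left 5, right 13).
#' @param marker_noise_std_m i.i.d. Gaussian noise SD on each marker
#'   coordinate in metres (default 0.002, a soft-tissue-artifact stand-in).
#' @param fs_markers marker sampling rate in Hz (default 200).
#' @param fs_force force sampling rate in Hz (default 1000).
#' @param body_weight_n stance plateau force in newtons (default 700).
#' @param grf_threshold_n force threshold the synthetic GRF crosses exactly
#'   at the true events (default 20).
#' @param seed integer seed driving all randomness (default 1).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cycles = 25L, cadence_spm = 50,
                             stance_fraction = 0.62, ms_peak_amp = 5,
                             to_min_lead_ms = c(left = 80, right = 35),
                             hs_min_lag_ms = c(left = 5, right = 13),
                             marker_noise_std_m = 0.002,
                             fs_markers = 200, fs_force = 1000,
                             body_weight_n = 700, grf_threshold_n = 20,
                             seed = 1L) {
  stopifnot(n_cycles >= 1L, cadence_spm > 0, ms_peak_amp > 0,
            marker_noise_std_m >= 0, fs_markers > 0, fs_force > 0,
            body_weight_n > grf_threshold_n, grf_threshold_n > 0)
  cfg <- list(n_cycles = as.integer(n_cycles), cadence_spm = cadence_spm,
              stance_fraction = per_side(stance_fraction, "stance_fraction"),
              ms_peak_amp = ms_peak_amp,
              to_min_lead_ms = per_side(to_min_lead_ms, "to_min_lead_ms"),
              hs_min_lag_ms = per_side(hs_min_lag_ms, "hs_min_lag_ms"),
              marker_noise_std_m = marker_noise_std_m,
              fs_markers = fs_markers, fs_force = fs_force,
              body_weight_n = body_weight_n,
              grf_threshold_n = grf_threshold_n, seed = as.integer(seed))
  if (any(cfg$stance_fraction <= 0 | cfg$stance_fraction >= 1)) {
    stop("stance_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (any(cfg$to_min_lead_ms < 0)) {
    stop("to_min_lead_ms must be >= 0", call. = FALSE)
  }
  stride_s <- 60 / cadence_spm
  for (side in c("left", "right")) {
    g <- waveform_geometry(cfg, side)
    # landmarks must keep their order with clearance for the bump widths
    if (g$t_tomin <= g$t_sb + 2 * g$sigma_min ||
        g$t_ms - g$t_tomin < 2 * g$sigma_min ||
        g$t_hsmin - g$t_ms < 2 * g$sigma_min) {
      stop(sprintf(
        "config error: velocity landmarks out of order on side '%s' (lead/lag too large for the phase durations at stride %.3g s)",
        side, stride_s), call. = FALSE)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d cycles @ %g strides/min (stride %.3g s), seed %d\n",
    x$n_cycles, x$cadence_spm, 60 / x$cadence_spm, x$seed))
  cat(sprintf("  stance fraction L/R: %.2f/%.2f; TO-min lead %g/%g ms; HS-min lag %g/%g ms\n",
              x$stance_fraction["left"], x$stance_fraction["right"],
              x$to_min_lead_ms["left"], x$to_min_lead_ms["right"],
              x$hs_min_lag_ms["left"], x$hs_min_lag_ms["right"]))
  cat(sprintf("  marker noise %g mm; fs %g/%g Hz\n",
              1000 * x$marker_noise_std_m, x$fs_markers, x$fs_force))
  invisible(x)
}

# Within-cycle geometry (times relative to the cycle's heel strike) and bump
# widths/amplitudes. Widths scale with the stride so the waveform keeps its
# shape across cadences; the minima amplitude balances the positive bump
# areas so the orientation does not drift cycle over cycle.
#' @noRd
waveform_geometry <- function(cfg, side) {
  T <- 60 / cfg$cadence_spm
  s <- cfg$stance_fraction[[side]]
  lead <- cfg$to_min_lead_ms[[side]] / 1000
  lag <- cfg$hs_min_lag_ms[[side]] / 1000
  sigma_ms <- 0.05 * T
  sigma_min <- 0.04 * T
  sigma_sb <- 0.08 * T
  amp_sb <- 0.1 * cfg$ms_peak_amp
  amp_min <- (cfg$ms_peak_amp * sigma_ms + amp_sb * sigma_sb) /
    (2 * sigma_min)
  list(T = T, s = s,
       t_to = s * T,                 # true toe-off after the cycle HS
       t_hs_next = T,                # next true heel strike
       t_sb = 0.3 * s * T,          # stance bump centre
       t_tomin = s * T - lead,       # first (toe-off) minimum
       t_ms = (s * T + T) / 2,       # midswing peak
       t_hsmin = T + lag,            # second (heel-strike) minimum
       sigma_ms = sigma_ms, sigma_min = sigma_min, sigma_sb = sigma_sb,
       amp_ms = cfg$ms_peak_amp, amp_min = amp_min, amp_sb = amp_sb)
}

#' @noRd
gauss_bump <- function(t, centre, sigma, amp) {
  amp * exp(-((t - centre)^2) / (2 * sigma^2))
}

# Start time of the first heel strike for a side (right leg offset by half a
# stride) and the trial duration.
#' @noRd
trial_timing <- function(cfg) {
  T <- 60 / cfg$cadence_spm
  margin <- 0.75 * T
  duration <- 2 * margin + (cfg$n_cycles + 0.5) * T
  n_m <- as.integer(ceiling(duration * cfg$fs_markers))
  ratio <- cfg$fs_force / cfg$fs_markers
  n_f <- if (abs(ratio - round(ratio)) < 1e-9) {
    n_m * as.integer(round(ratio))
  } else {
    as.integer(ceiling(duration * cfg$fs_force))
  }
  list(T = T, margin = margin,
       t0 = c(left = margin, right = margin + T / 2),
       duration = duration, n_markers = n_m, n_force = n_f)
}

#' Generate the shank angular-velocity waveform for one side
#'
#' Builds the continuous-time waveform on the marker clock: per cycle a small
#' positive Gaussian bump during stance, a negative minimum at
#' `true TO - to_min_lead`, the dominant positive midswing peak centred in
#' swing, and a negative minimum at `true HS + hs_min_lag`. At zero noise the
#' waveform has exactly one qualifying positive peak and two negative minima
#' per cycle.
#'
#' @param config a [synthetic_config()].
#' @param side `"left"` or `"right"`.
#' @return list with `time`, `omega` (rad/s), and `landmarks`, a data frame
#'   of the constructed landmark times (`kind` in `MS`, `TO_MIN`, `HS_MIN`)
#'   together with the true events (`TO`, `HS`).
#' @export
generate_velocity_waveform <- function(config, side) {
  stopifnot(inherits(config, "synthetic_config"))
  side <- match.arg(side, c("left", "right"))
  tm <- trial_timing(config)
  g <- waveform_geometry(config, side)
  t <- (seq_len(tm$n_markers) - 1L) / config$fs_markers
  omega <- numeric(length(t))
  n <- config$n_cycles
  hs_times <- tm$t0[[side]] + (0:n) * g$T
  lm <- list()
  add <- function(kind, time, amp = NULL, sigma = NULL) {
    if (!is.null(amp)) omega <<- omega + gauss_bump(t, time, sigma, amp)
    lm[[length(lm) + 1L]] <<- data.frame(side = side, kind = kind,
                                         time_s = time,
                                         stringsAsFactors = FALSE)
  }
  for (k in 0:(n - 1L)) {
    hs_k <- hs_times[k + 1L]
    add("HS", hs_k)
    add("TO", hs_k + g$t_to)
    omega <- omega + gauss_bump(t, hs_k + g$t_sb, g$sigma_sb, g$amp_sb)
    add("TO_MIN", hs_k + g$t_tomin, -g$amp_min, g$sigma_min)
    add("MS", hs_k + g$t_ms, g$amp_ms, g$sigma_ms)
    add("HS_MIN", hs_k + g$t_hsmin, -g$amp_min, g$sigma_min)
  }
  add("HS", hs_times[n + 1L])
  # terminal minimum of the swing that ended at the very first heel strike
  omega <- omega + gauss_bump(t, hs_times[1L] - g$T + g$t_hsmin,
                              g$sigma_min, -g$amp_min)
  landmarks <- do.call(rbind, lm)
  landmarks <- landmarks[order(landmarks$time_s), , drop = FALSE]
  rownames(landmarks) <- NULL
  list(time = t, omega = omega, landmarks = landmarks)
}

#' Generate a complete synthetic gait trial
#'
#' Integrates the per-side velocity waveform to a shank orientation, places
#' proximal and distal tibia markers on a 0.40 m segment rotating about a
#' gently translating ankle point, adds i.i.d. Gaussian marker noise, and
#' builds the per-belt vertical GRF as a smoothed trapezoid spanning each
#' true stance whose `grf_threshold_n` crossings fall exactly on the true
#' heel-strike and toe-off times. All randomness derives from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_trial`: fields `config`, `markers`
#'   (a [marker_trial()] with LTIB/LTIBI/RTIB/RTIBI), `force`
#'   (a [force_trial()]), `truth_events` (gait-event data frame, `source =
#'   "force"`), `truth_params` (from [compute_params()]), and `landmarks`
#'   (the constructed velocity landmark times per side).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tm <- trial_timing(config)
  markers <- list()
  landmarks <- list()
  truth <- list()
  for (side in c("left", "right")) {
    wf <- generate_velocity_waveform(config, side)
    g <- waveform_geometry(config, side)
    t <- wf$time
    dt <- 1 / config$fs_markers
    # trapezoidal integration of the angular velocity
    incr <- c(0, cumsum((wf$omega[-1L] + wf$omega[-length(wf$omega)]) / 2 * dt))
    theta <- pi / 2 + incr - mean(incr)
    # ankle point translating smoothly at the stride period
    phase <- 2 * pi * (t - tm$t0[[side]]) / g$T
    ankle_fwd <- 0.03 * sin(phase)
    ankle_vert <- 0.09 + 0.015 * (0.5 - 0.5 * cos(phase))
    lat <- if (side == "left") 0.10 else -0.10
    u_fwd <- cos(theta); u_vert <- sin(theta)
    pre <- if (side == "left") "L" else "R"
    for (m in list(list(lab = paste0(pre, "TIB"), r = 0.45),
                   list(lab = paste0(pre, "TIBI"), r = 0.05))) {
      xyz <- cbind(X = rep(lat, length(t)),
                   Y = ankle_fwd + m$r * u_fwd,
                   Z = ankle_vert + m$r * u_vert)
      if (config$marker_noise_std_m > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0,
                                         config$marker_noise_std_m),
                            ncol = 3L)
      }
      markers[[m$lab]] <- xyz
    }
    landmarks[[side]] <-
      wf$landmarks[wf$landmarks$kind %in% c("MS", "TO_MIN", "HS_MIN"), ,
                   drop = FALSE]
    tru <- wf$landmarks[wf$landmarks$kind %in% c("HS", "TO"), , drop = FALSE]
    truth[[side]] <- make_events("synthetic", side, tru$kind, tru$time_s,
                                 "force")
  }
  truth_events <- sort_events(do.call(rbind, truth))
  fz <- lapply(c(left = "left", right = "right"), function(side) {
    synthetic_fz(config, truth_events[truth_events$side == side, ,
                                      drop = FALSE], tm)
  })
  trial_id <- sprintf("synthetic-seed%d", config$seed)
  mk <- marker_trial(markers, fs = config$fs_markers, trial_id = trial_id)
  fo <- force_trial(fz, fs = config$fs_force, trial_id = trial_id)
  truth_events$trial_id <- trial_id
  structure(list(config = config, markers = mk, force = fo,
                 truth_events = truth_events,
                 truth_params = temporal_params(truth_events),
                 landmarks = do.call(rbind, landmarks)),
            class = "synthetic_trial")
}

# Smoothed trapezoid per stance: smoothstep edges positioned so the force
# crosses grf_threshold_n exactly at the true HS (rising) and TO (falling).
# The final heel strike opens a stance that runs to the end of the trial.
#' @noRd
synthetic_fz <- function(cfg, events, tm) {
  t <- (seq_len(tm$n_force) - 1L) / cfg$fs_force
  fz <- numeric(length(t))
  W <- cfg$body_weight_n
  thr <- cfg$grf_threshold_n
  rise <- 0.08
  fall <- 0.10
  sstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    3 * u^2 - 2 * u^3
  }
  # fraction of the edge at which the smoothstep passes the threshold
  a <- stats::uniroot(function(u) sstep(u) - thr / W, c(1e-9, 0.5),
                      tol = 1e-12)$root
  hs <- events$time_s[events$kind == "HS"]
  to <- events$time_s[events$kind == "TO"]
  for (h in hs) {
    nxt <- to[to > h]
    up <- sstep((t - (h - a * rise)) / rise)
    if (length(nxt) > 0L) {
      dn <- sstep(((nxt[1L] + a * fall) - t) / fall)
      seg <- W * pmin(up, dn)
    } else {
      seg <- W * up  # trial ends mid-stance
    }
    fz <- pmax(fz, seg)
  }
  fz
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial '%s'> %d cycles/side, %.1f s\n",
              x$markers$trial_id, x$config$n_cycles,
              x$markers$n_samples / x$markers$fs))
  cat(sprintf("  %d truth events, %d truth cycles\n",
              nrow(x$truth_events), nrow(x$truth_params)))
  invisible(x)
}

#' Export a synthetic trial to CSV files
#'
#' Writes `<prefix>markers.csv`, `<prefix>force.csv` and
#' `<prefix>truth_events.csv` in the package's CSV dialect.
#'
#' @param trial a `synthetic_trial`.
#' @param prefix path prefix for the three output files.
#' @return named character vector of the written paths, invisibly.
#' @export
export_trial_csv <- function(trial, prefix) {
  stopifnot(inherits(trial, "synthetic_trial"))
  paths <- c(markers = paste0(prefix, "markers.csv"),
             force = paste0(prefix, "force.csv"),
             truth = paste0(prefix, "truth_events.csv"))
  write_marker_csv(trial$markers, paths["markers"])
  write_force_csv(trial$force, paths["force"])
  write_events(trial$truth_events, paths["truth"])
  invisible(paths)
}
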