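# Shank kinematics: sagittal orientation from a tibia marker pair, numerical
# differentiation to angular velocity, and zero-phase low-pass filtering.

#' Sagittal segment orientation from two markers
#'
#' Four-quadrant angle of the vector from the distal point `p2` to the
#' proximal point `p1` in the sagittal plane: `atan2(y1 - y2, x1 - x2)`, with
#' `x` the direction of progression and `y` vertical. A vertical shank
#' (proximal marker straight above the distal one) therefore reads pi/2 rad.
#'
#' @param p1 proximal point(s): length-2 vector `(x, y)` or an `n x 2` matrix.
#' @param p2 distal point(s), same shape as `p1`.
#' @return angle(s) in radians in (-pi, pi].
#' @export
segment_orientation <- function(p1, p2) {
  p1 <- rbind2cols(p1); p2 <- rbind2cols(p2)
  dx <- p1[, 1L] - p2[, 1L]
  dy <- p1[, 2L] - p2[, 2L]
  degen <- which(dx == 0 & dy == 0)
  if (length(degen) > 0L) {
    stop("degenerate geometry: coincident marker points at sample(s) ",
         paste(utils::head(degen, 5L), collapse = ", "), call. = FALSE)
  }
  unname(atan2(dy, dx))
}

#' @noRd
rbind2cols <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("points must have 2 sagittal coordinates",
                              call. = FALSE)
    matrix(as.numeric(p), ncol = 2L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("points must have 2 sagittal coordinates",
                            call. = FALSE)
    p
  }
}

#' Angular velocity by finite differences
#'
#' Central differences at interior samples, one-sided differences at the two
#' endpoints, so the output has the same length as the input. The input is
#' expected to be unwrapped (no artificial +/- pi jumps).
#'
#' @param theta orientation series in radians.
#' @param fs sampling rate in Hz.
#' @return angular velocity series in rad/s, same length as `theta`.
#' @export
angular_velocity <- function(theta, fs) {
  n <- length(theta)
  if (n < 3L) stop("insufficient data: need at least 3 samples", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  omega <- numeric(n)
  omega[2:(n - 1L)] <- (theta[3:n] - theta[1:(n - 2L)]) * fs / 2
  omega[1L] <- (theta[2L] - theta[1L]) * fs
  omega[n] <- (theta[n] - theta[n - 1L]) * fs
  omega
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (zero phase lag), with
#' odd-reflection padding at both ends to suppress edge transients. `order`
#' is the effective order of the combined forward-backward pass, the usual
#' convention in gait analysis; the underlying one-pass design has order
#' `order / 2`.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param fc cutoff frequency in Hz (default 4, suited to walking kinematics).
#' @param order effective zero-phase filter order; even, >= 2 (default 4).
#' @return filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, fc = 4, order = 4L) {
  if (!is.numeric(fc) || fc <= 0 || fc >= fs / 2) {
    stop("invalid cutoff: need 0 < fc < fs/2", call. = FALSE)
  }
  if (order %% 2L != 0L || order < 2L) {
    stop("order must be an even integer >= 2", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) return(x)
  if (anyNA(x)) stop("cannot filter a series containing NA/NaN",
                     call. = FALSE)
  bf <- signal::butter(order / 2L, fc / (fs / 2), type = "low")
  np <- min(n - 1L, as.integer(ceiling(3 * fs / fc)))
  # odd (point-symmetric) reflection; the pivot is a median of the few
  # outermost samples so a single noisy endpoint cannot seed an edge
  # transient
  k <- min(5L, n)
  piv_f <- stats::median(x[seq_len(k)])
  piv_b <- stats::median(x[(n - k + 1L):n])
  front <- 2 * piv_f - x[(np + 1L):2L]
  back <- 2 * piv_b - x[(n - 1L):(n - np)]
  xp <- c(front, x, back)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Shank angular-velocity signal from a marker trial
#'
#' Composes the kinematic chain for one leg: project the two tibia markers of
#' that side onto the sagittal plane (forward, vertical), compute the
#' four-quadrant segment orientation, unwrap it, differentiate to angular
#' velocity and low-pass filter. The sign convention makes forward shank
#' rotation during swing positive, so midswing appears as the dominant
#' positive peak; with `auto_orient = TRUE` the signal is negated (with a
#' message) if its dominant peaks come out negative, which absorbs lab-frame
#' axis flips and marker mislabelling.
#'
#' @param trial a [marker_trial()].
#' @param side `"left"` or `"right"`.
#' @param proximal,distal marker labels; defaults are the conventional tibia
#'   labels for the side (`LTIB`/`LTIBI` or `RTIB`/`RTIBI`).
#' @param fc,order low-pass settings, see [lowpass_filter()].
#' @param auto_orient logical; negate the velocity if its dominant peaks are
#'   negative (default `TRUE`).
#' @return object of class `shank_signal`: fields `side`, `fs`, `time`,
#'   `theta` (unwrapped rad), `omega_raw`, `omega` (filtered rad/s),
#'   `proximal`, `distal`, `flipped`.
#' @export
shank_signal_from_markers <- function(trial, side, proximal = NULL,
                                      distal = NULL, fc = 4, order = 4L,
                                      auto_orient = TRUE) {
  stopifnot(inherits(trial, "marker_trial"))
  side <- match.arg(side, c("left", "right"))
  prefix <- if (side == "left") "L" else "R"
  proximal <- proximal %||% paste0(prefix, "TIB")
  distal <- distal %||% paste0(prefix, "TIBI")
  for (lab in c(proximal, distal)) {
    if (!lab %in% names(trial$markers)) {
      stop(sprintf("marker '%s' not present in trial (available: %s)", lab,
                   paste(names(trial$markers), collapse = ", ")),
           call. = FALSE)
    }
  }
  fwd <- trial$axis_map$forward
  vert <- trial$axis_map$vertical
  p1 <- trial$markers[[proximal]][, c(fwd, vert)]
  p2 <- trial$markers[[distal]][, c(fwd, vert)]
  if (anyNA(p1) || anyNA(p2)) {
    stop(sprintf(
      "tibia markers for side '%s' contain unfilled gaps; cannot compute kinematics",
      side), call. = FALSE)
  }
  theta <- unwrap_angle(segment_orientation(p1, p2))
  omega_raw <- angular_velocity(theta, trial$fs)
  omega <- lowpass_filter(omega_raw, trial$fs, fc = fc, order = order)
  flipped <- FALSE
  # orientation decision on robust quantiles, not raw extremes
  q <- stats::quantile(omega, c(0.01, 0.99), names = FALSE)
  if (isTRUE(auto_orient) && q[2L] < -q[1L]) {
    omega <- -omega
    omega_raw <- -omega_raw
    flipped <- TRUE
    message("shank_signal_from_markers: dominant velocity peaks were ",
            "negative; signal negated (side ", side, ")")
  }
  structure(list(side = side, fs = trial$fs,
                 time = (seq_along(theta) - 1L) / trial$fs,
                 theta = theta, omega_raw = omega_raw, omega = omega,
                 proximal = proximal, distal = distal, flipped = flipped),
            class = "shank_signal")
}

#' @export
print.shank_signal <- function(x, ...) {
  cat(sprintf(
    "<shank_signal %s> %d samples @ %g Hz; omega range [%.2f, %.2f] rad/s%s\n",
    x$side, length(x$omega), x$fs, min(x$omega), max(x$omega),
    if (x$flipped) " (auto-negated)" else ""))
  invisible(x)
}
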