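# Shank orientation, differentiation and zero-phase filtering.

test_that("segment orientation gives four-quadrant angles", {
  # vertical segment, the x1 - x2 = 0 limit of the arctangent
  expect_equal(segment_orientation(c(0, 1.0), c(0, 0.6)), pi / 2)
  # 45-degree diagonal
  expect_equal(segment_orientation(c(1, 1), c(0, 0)), pi / 4)
  # generic point pair, oracle value from a four-quadrant arctangent
  expect_equal(segment_orientation(c(0.3, 1.2), c(0.1, 0.4)),
               1.3258176636680326, tolerance = 1e-12)
  expect_error(segment_orientation(c(1, 1), c(1, 1)), "degenerate")
})

test_that("segment orientation matches the complex-argument oracle", {
  set.seed(11)
  p1 <- matrix(runif(2000, -2, 2), ncol = 2)
  p2 <- matrix(runif(2000, -2, 2), ncol = 2)
  got <- segment_orientation(p1, p2)
  oracle <- Arg(complex(real = p1[, 1] - p2[, 1],
                        imaginary = p1[, 2] - p2[, 2]))
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("segment orientation is translation invariant", {
  set.seed(12)
  for (k in 1:20) {
    p1 <- runif(2, -1, 1); p2 <- runif(2, -1, 1)
    off <- runif(2, -10, 10)
    expect_equal(segment_orientation(p1 + off, p2 + off),
                 segment_orientation(p1, p2), tolerance = 1e-9)
  }
})

test_that("angular velocity recovers constant, ramp and sinusoid rates", {
  expect_equal(angular_velocity(rep(0.5, 10), 200), rep(0, 10))
  t <- (0:99) / 200
  expect_equal(angular_velocity(2 * t, 200)[2:99], rep(2, 98))
  theta <- 0.3 * sin(2 * pi * 1 * t)
  omega <- angular_velocity(theta, 200)
  truth <- 0.3 * 2 * pi * cos(2 * pi * t)
  rel_rms <- sqrt(mean((omega[2:99] - truth[2:99])^2)) / (0.3 * 2 * pi)
  expect_lt(rel_rms, 0.001)
  expect_equal(omega[1], 0.3 * 2 * pi, tolerance = 1e-3)
  expect_error(angular_velocity(c(1, 2), 200), "insufficient")
})

test_that("low-pass filter passes DC and the walking band, kills 40 Hz", {
  fs <- 200
  expect_equal(lowpass_filter(rep(5, 400), fs), rep(5, 400), tolerance = 1e-6)
  t <- (0:1999) / fs
  s1 <- sin(2 * pi * 1 * t)
  y <- lowpass_filter(s1, fs)
  # lock-in amplitude estimate over whole cycles away from the edges
  win <- 201:1800
  amp <- function(x, f) {
    2 * sqrt(mean(x[win] * sin(2 * pi * f * t[win]))^2 +
               mean(x[win] * cos(2 * pi * f * t[win]))^2)
  }
  expect_gt(amp(y, 1), 0.99)
  # peak-time shift of the 1 Hz component, within one cycle (peak at 2.25 s)
  one <- 401:500
  expect_lte(abs(one[which.max(s1[one])] - one[which.max(y[one])]), 1)
  mix <- s1 + sin(2 * pi * 40 * t)
  expect_lt(amp(lowpass_filter(mix, fs), 40), 0.01)
  expect_error(lowpass_filter(s1, fs, fc = 120), "cutoff")
})

test_that("filter is zero-phase on band-limited input", {
  fs <- 200
  t <- (0:1999) / fs
  x <- sin(2 * pi * 1.5 * t) + 0.5 * cos(2 * pi * 0.7 * t)
  y <- lowpass_filter(x, fs)
  cc <- stats::ccf(y, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("differentiate-then-filter commutes with filter-then-differentiate", {
  fs <- 200
  t <- (0:1999) / fs
  theta <- 0.4 * sin(2 * pi * 1.2 * t) + 0.1 * sin(2 * pi * 1.9 * t + 1)
  a <- lowpass_filter(angular_velocity(theta, fs), fs)
  b <- angular_velocity(lowpass_filter(theta, fs), fs)
  win <- 101:1900
  rel_rms <- sqrt(mean((a[win] - b[win])^2)) / sqrt(mean(b[win]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("shank signal recovers the generator's velocity and is invariant", {
  tr <- quiet_trial(n_cycles = 6, to_min_lead_ms = 0, hs_min_lag_ms = 0,
                    marker_noise_std_m = 0, seed = 3)
  sig <- shank_signal_from_markers(tr$markers, "left")
  wf <- generate_velocity_waveform(tr$config, "left")
  win <- 50:(length(wf$omega) - 50)
  # the raw differentiated signal reproduces the analytic velocity; the
  # filtered one reproduces the analytic velocity seen through the same
  # 4 Hz low-pass
  rel_rms <- function(a, b) sqrt(mean((a[win] - b[win])^2)) /
    sqrt(mean(b[win]^2))
  expect_lt(rel_rms(sig$omega_raw, wf$omega), 0.02)
  expect_lt(rel_rms(sig$omega, lowpass_filter(wf$omega, sig$fs)), 0.02)

  # whole-body translation leaves the orientation untouched
  tr2 <- tr$markers
  tr2$markers <- lapply(tr2$markers, function(m)
    sweep(m, 2, c(1.5, -2.0, 0.7), "+"))
  sig2 <- shank_signal_from_markers(tr2, "left")
  expect_equal(sig2$theta, sig$theta, tolerance = 1e-9)

  # swapping proximal/distal flips theta by pi but not omega
  sig3 <- shank_signal_from_markers(tr$markers, "left",
                                    proximal = "LTIBI", distal = "LTIB")
  dtheta <- (sig3$theta - sig$theta) %% (2 * pi)
  expect_true(all(abs(dtheta - pi) < 1e-6))
  expect_equal(sig3$omega, sig$omega, tolerance = 1e-9)
})

test_that("missing tibia marker is reported by name", {
  tr <- quiet_trial(n_cycles = 2, marker_noise_std_m = 0, seed = 1)
  tr$markers$markers$LTIB <- NULL
  expect_error(shank_signal_from_markers(tr$markers, "left"), "LTIB")
})
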