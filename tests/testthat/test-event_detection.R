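# The dual-minima detector and the GRF reference detector.

test_that("midswing detection finds every cycle's dominant peak", {
  tr <- quiet_trial(n_cycles = 10, to_min_lead_ms = 0, hs_min_lag_ms = 0,
                    marker_noise_std_m = 0, seed = 21)
  for (side in c("left", "right")) {
    sig <- shank_signal_from_markers(tr$markers, side)
    ms <- detect_midswing(sig, side = side)
    truth <- truth_landmark(tr, side, "MS")
    expect_equal(nrow(ms), 10)
    expect_true(all(abs(ms$time_s - truth) <= 1 / tr$markers$fs + 1e-9))
    expect_true(all(diff(ms$time_s) > 0))
  }
})

test_that("midswing detection handles degenerate signals", {
  expect_equal(nrow(detect_midswing(rep(0, 1000), fs = 200)), 0)
  # one synthetic swing hump
  t <- (0:399) / 200
  hump <- 3 * exp(-((t - 1)^2) / (2 * 0.05^2))
  ms <- detect_midswing(hump, fs = 200)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$time_s, 1, tolerance = 1 / 200)
  expect_error(detect_midswing(c(1, NaN, 2), fs = 200), "NaN")
})

test_that("midswing detection is invariant to positive rescaling", {
  tr <- quiet_trial(n_cycles = 8, marker_noise_std_m = 0.002, seed = 22)
  sig <- shank_signal_from_markers(tr$markers, "left")
  base <- detect_midswing(sig$omega, fs = sig$fs)
  for (k in c(0.01, 3.7, 250)) {
    expect_equal(detect_midswing(k * sig$omega, fs = sig$fs)$time_s,
                 base$time_s)
  }
})

test_that("TO precedes and HS follows each midswing within a sample", {
  tr <- quiet_trial(n_cycles = 10, to_min_lead_ms = 0, hs_min_lag_ms = 0,
                    marker_noise_std_m = 0, seed = 23)
  for (side in c("left", "right")) {
    ev <- kin_events(tr, side)
    tol <- 1 / tr$markers$fs + 1e-9
    for (ci in unique(ev$cycle_index)) {
      cyc <- ev[ev$cycle_index == ci, ]
      if (all(c("TO", "MS", "HS") %in% cyc$kind)) {
        expect_lt(cyc$time_s[cyc$kind == "TO"], cyc$time_s[cyc$kind == "MS"])
        expect_lt(cyc$time_s[cyc$kind == "MS"], cyc$time_s[cyc$kind == "HS"])
      }
    }
    to <- ev$time_s[ev$kind == "TO"]
    hs <- ev$time_s[ev$kind == "HS"]
    expect_true(all(abs(to - truth_landmark(tr, side, "TO_MIN")) <= tol))
    expect_true(all(abs(hs - truth_landmark(tr, side, "HS_MIN")) <= tol))
  }
})

test_that("a midswing without a preceding minimum yields no TO", {
  fs <- 200
  t <- (0:599) / fs
  # single MS bump at the very start, then a negative minimum after it
  omega <- 4 * exp(-((t - 0.05)^2) / (2 * 0.05^2)) -
    2 * exp(-((t - 0.8)^2) / (2 * 0.05^2))
  ms <- detect_midswing(omega, fs = fs)
  expect_equal(nrow(ms), 1)
  expect_message(tohs <- detect_to_hs(omega, ms, fs = fs), "incomplete")
  expect_equal(tohs$kind, "HS")
})

test_that("a single minimum between two peaks serves both cycles, with warning", {
  fs <- 200
  t <- (0:799) / fs
  omega <- 4 * exp(-((t - 1)^2) / (2 * 0.06^2)) +
    4 * exp(-((t - 3)^2) / (2 * 0.06^2)) -
    2 * exp(-((t - 2)^2) / (2 * 0.06^2)) -
    2 * exp(-((t - 0.3)^2) / (2 * 0.06^2)) -
    2 * exp(-((t - 3.7)^2) / (2 * 0.06^2))
  ms <- detect_midswing(omega, fs = fs, min_cycle_s = 0.4)
  expect_equal(nrow(ms), 2)
  expect_warning(tohs <- detect_to_hs(omega, ms, fs = fs), "both HS")
  # the shared minimum is HS of cycle 1 AND TO of cycle 2: never skipped,
  # never silently double-counted
  hs1 <- tohs$time_s[tohs$kind == "HS" & tohs$cycle_index == 1]
  to2 <- tohs$time_s[tohs$kind == "TO" & tohs$cycle_index == 2]
  expect_equal(hs1, to2)
  expect_equal(hs1, 2, tolerance = 1 / fs)
})

test_that("unsorted midswing events are rejected", {
  tr <- quiet_trial(n_cycles = 4, marker_noise_std_m = 0, seed = 2)
  sig <- shank_signal_from_markers(tr$markers, "left")
  ms <- detect_midswing(sig)
  expect_error(detect_to_hs(sig, ms[rev(seq_len(nrow(ms))), ]), "sorted")
})

test_that("zero crossing is linearly interpolated after TO", {
  fs <- 200
  omega <- rep(-1, 40)
  omega[22:40] <- 1  # -1 at sample 21 (t = 0.100), +1 at t = 0.105
  to <- make_to_event(0.100)
  zc <- zero_crossing_to(omega, to, fs = fs)
  expect_equal(zc$time_s, 0.1025, tolerance = 1e-12)
  expect_equal(zc$kind, "ZC")
})

test_that("zero crossing lies between TO and MS on synthetic cycles", {
  tr <- quiet_trial(n_cycles = 6, marker_noise_std_m = 0, seed = 31)
  sig <- shank_signal_from_markers(tr$markers, "left")
  ms <- detect_midswing(sig)
  tohs <- suppressMessages(detect_to_hs(sig, ms))
  tos <- tohs[tohs$kind == "TO", ]
  for (j in seq_len(nrow(tos))) {
    ms_t <- ms$time_s[ms$cycle_index == tos$cycle_index[j]]
    zc <- zero_crossing_to(sig, tos[j, ], next_ms_time = ms_t)
    expect_gt(zc$time_s, tos$time_s[j])
    expect_lt(zc$time_s, ms_t)
  }
})

test_that("zero crossing is absent when velocity stays negative", {
  fs <- 200
  omega <- seq(-2, -0.5, length.out = 100)
  expect_message(zc <- zero_crossing_to(omega, make_to_event(0.1), fs = fs),
                 "no negative-to-positive")
  expect_equal(nrow(zc), 0)
})

test_that("GRF threshold detector marks crossings and enforces alternation", {
  fs <- 1000
  t <- (0:2999) / fs
  # trapezoid rising through 20 N at 1.002 s, falling at 1.702 s
  fz <- 700 * pmin(pmax((t - 1.0) / 0.07, 0), 1) *
    pmin(pmax((1.704 - t) / 0.07, 0), 1)
  i_up <- which(fz >= 20)[1]
  i_dn <- which(t > 1.5 & fz < 20)[1]
  ft <- force_trial(list(left = fz), fs = fs)
  ev <- grf_reference_events(ft, "left", threshold_n = 20)
  expect_equal(ev$kind, c("HS", "TO"))
  expect_equal(ev$time_s, c(t[i_up], t[i_dn]))
  expect_equal(ev$time_s, c(1.002, 1.702), tolerance = 2 / fs)

  expect_equal(nrow(grf_reference_events(
    force_trial(list(left = rep(0, 100)), fs), "left")), 0)
})

test_that("GRF reference events hit the synthetic truth within one sample", {
  tr <- quiet_trial(n_cycles = 8, marker_noise_std_m = 0, seed = 33)
  for (side in c("left", "right")) {
    ev <- grf_reference_events(tr$force, side)
    tru <- tr$truth_events[tr$truth_events$side == side, ]
    expect_equal(nrow(ev), nrow(tru))
    m <- match_events(ev, tru)
    expect_true(all(abs(m$t_ref - m$t_pred) <= 1 / tr$force$fs + 1e-9))
  }
})

test_that("debounce merges spurious threshold spikes", {
  fs <- 1000
  fz <- rep(0, 3000)
  fz[1001:2000] <- 700
  fz[2500:2520] <- 30  # 21 ms spike during swing, below debounce window
  ft <- force_trial(list(left = fz), fs = fs)
  ev <- grf_reference_events(ft, "left", threshold_n = 20, debounce_s = 0.05)
  expect_equal(ev$kind, c("HS", "TO"))
})
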