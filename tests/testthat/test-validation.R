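# Event matching, signed errors, summaries and Bland-Altman agreement.

sev <- function(kind, times, side = "left", source = "force") {
  if (length(times) == 0) {
    return(data.frame(trial_id = character(0), side = character(0),
                      kind = character(0), time_s = numeric(0),
                      source = character(0), cycle_index = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(trial_id = "t", side = side, kind = kind, time_s = times,
             source = source, cycle_index = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("matching pairs nearest events one-to-one within half a stride", {
  m <- match_events(sev("HS", c(1.00, 2.00), source = "kinematic"),
                    sev("HS", c(1.05, 2.02)))
  expect_equal(m$t_pred, c(1.00, 2.00))
  expect_equal(m$t_ref, c(1.05, 2.02))

  m2 <- match_events(sev("HS", numeric(0), source = "kinematic"),
                     sev("HS", c(1.0, 2.0)))
  expect_equal(nrow(m2), 0)
  expect_equal(nrow(attr(m2, "unmatched_ref")), 2)

  # an extra spurious mid-cycle prediction stays unmatched
  m3 <- match_events(sev("HS", c(1.01, 1.52, 2.03), source = "kinematic"),
                     sev("HS", c(1.00, 2.00, 3.00)))
  expect_equal(m3$t_pred, c(1.01, 2.03))
  expect_equal(attr(m3, "unmatched_pred")$time_s, 1.52)
})

# Exhaustive optimal one-to-one assignment (max pairs, then min total |dt|)
# for small instances; the greedy matcher must agree when jitter is small
# relative to event spacing.
oracle_match <- function(tp, tr, window) {
  best <- NULL
  n <- length(tp)
  idx_sets <- function(k, from) {
    if (k == 0) return(list(integer(0)))
    if (from > length(tr)) return(list())
    out <- list()
    for (i in from:length(tr)) {
      for (rest in idx_sets(k - 1, i + 1)) {
        out[[length(out) + 1]] <- c(i, rest)
      }
    }
    out
  }
  for (k in n:0) {
    preds <- if (k == 0) list(integer(0)) else
      utils::combn(n, k, simplify = FALSE)
    for (ip in preds) {
      for (ir in idx_sets(k, 1)) {
        for (perm in if (k > 0) combinat_perms(ir) else list(integer(0))) {
          dt <- abs(tp[ip] - tr[perm])
          if (all(dt <= window)) {
            cost <- sum(dt)
            if (is.null(best) || k > best$k ||
                (k == best$k && cost < best$cost - 1e-12)) {
              best <- list(k = k, cost = cost, ip = ip, ir = perm)
            }
          }
        }
      }
    }
    if (!is.null(best) && best$k == k) break
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

test_that("greedy matching agrees with the optimal-assignment oracle", {
  set.seed(51)
  for (rep in 1:20) {
    tr_times <- sort(runif(4, 0, 10))
    while (min(diff(tr_times)) < 1) tr_times <- sort(runif(4, 0, 10))
    keep <- runif(4) > 0.2
    tp_times <- sort(tr_times[keep] + runif(sum(keep), -0.1, 0.1))
    m <- match_events(sev("HS", tp_times, source = "kinematic"),
                      sev("HS", tr_times))
    best <- oracle_match(tp_times, tr_times, window = 0.5)
    expect_equal(nrow(m), best$k)
    expect_equal(sort(m$t_pred), sort(tp_times[best$ip]))
    expect_equal(sort(m$t_ref), sort(tr_times[best$ir]))
  }
})

test_that("error sign convention: early prediction is positive", {
  pairs <- data.frame(side = "left", kind = "TO",
                      t_pred = c(1.000, 1.500, 2.100),
                      t_ref = c(1.050, 1.500, 2.080),
                      stride_s = 1, stringsAsFactors = FALSE)
  e <- event_errors(pairs)
  expect_equal(e$e_ms, c(50, 0, -20))
})

test_that("swapping predicted and reference negates errors and bias", {
  tr <- quiet_trial(n_cycles = 6, marker_noise_std_m = 0, seed = 52)
  pred <- kin_events(tr, "left")
  ref <- tr$truth_events[tr$truth_events$side == "left", ]
  e1 <- event_errors(match_events(pred, ref))
  e2 <- event_errors(match_events(ref, pred))
  expect_equal(sort(e2$e_ms), sort(-e1$e_ms))
  expect_equal(mean(e2$e_ms), -mean(e1$e_ms))
})

test_that("summaries: ME, MAE, SD with sample denominator", {
  e <- data.frame(kind = "TO", side = "left", e_ms = c(10, -10),
                  stride_s = 1, e_pct = NA_real_, stringsAsFactors = FALSE)
  s <- summarize_errors(e)
  expect_equal(s$me_ms, 0)
  expect_equal(s$mae_ms, 10)
  expect_equal(s$sd_ms, sqrt(200), tolerance = 1e-12)

  s1 <- summarize_errors(e[1, ])
  expect_equal(s1$me_ms, 10)
  expect_true(is.na(s1$sd_ms))
})

test_that("summaries match a brute-force recomputation", {
  set.seed(53)
  e <- data.frame(kind = sample(c("HS", "TO"), 1000, TRUE),
                  side = sample(c("left", "right"), 1000, TRUE),
                  e_ms = rnorm(1000, 10, 40), stride_s = 1,
                  e_pct = NA_real_, stringsAsFactors = FALSE)
  s <- summarize_errors(e)
  for (r in seq_len(nrow(s))) {
    g <- e$e_ms[e$kind == s$kind[r] & e$side == s$side[r]]
    me <- sum(g) / length(g)
    mae <- sum(abs(g)) / length(g)
    sdv <- sqrt(sum((g - me)^2) / (length(g) - 1))
    expect_equal(s$n[r], length(g))
    expect_lt(abs(s$me_ms[r] - me), 1e-12)
    expect_lt(abs(s$mae_ms[r] - mae), 1e-12)
    expect_lt(abs(s$sd_ms[r] - sdv), 1e-11)
  }
  # MAE >= |ME| in every group
  expect_true(all(s$mae_ms >= abs(s$me_ms)))
})

test_that("stride normalisation matches the element-wise formula", {
  e <- data.frame(kind = "TO", side = "left", e_ms = c(40, 0, -25),
                  stride_s = c(1.0, 1.2, 0.8), e_pct = NA_real_,
                  stringsAsFactors = FALSE)
  out <- normalize_errors(e)
  expect_equal(out$e_pct, c(4.0, 0, 100 * 25 / 800))
  e$stride_s[2] <- NA
  expect_warning(out2 <- normalize_errors(e), "unnormalised")
  expect_true(is.na(out2$e_pct[2]))
})

test_that("Bland-Altman statistics match the direct formulas", {
  x <- c(1.01, 1.02, 0.99, 1.00, 1.03)
  expect_error(bland_altman(x[1], x[1]), "insufficient")

  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$rpc, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba_off <- bland_altman(x + 0.070, x)
  expect_equal(ba_off$bias, 0.070, tolerance = 1e-12)
  expect_equal(ba_off$rpc, 0, tolerance = 1e-12)

  set.seed(54)
  m <- rnorm(1000, 1.2, 0.05)
  r <- m + rnorm(1000, -0.01, 0.02)
  ba <- bland_altman(m, r)
  d <- m - r
  bias <- sum(d) / length(d)
  sdd <- sqrt(sum((d - bias)^2) / (length(d) - 1))
  expect_lt(abs(ba$bias - bias), 1e-12)
  expect_lt(abs(ba$rpc - 1.96 * sdd), 1e-12)
  expect_lt(abs(ba$loa_low - (bias - 1.96 * sdd)), 1e-12)
  expect_lt(abs(ba$loa_high - (bias + 1.96 * sdd)), 1e-12)
  expect_lt(abs(ba$cv - 100 * sdd / mean((m + r) / 2)), 1e-10)
  expect_equal(ba$loa_high - ba$loa_low, 2 * ba$rpc)
})

test_that("TO mostly early makes its MAE approach its ME", {
  tr <- quiet_trial(n_cycles = 15, to_min_lead_ms = 60, hs_min_lag_ms = 0,
                    marker_noise_std_m = 0.002, seed = 55)
  err <- pipeline_errors(tr)
  s <- summarize_errors(err, group_by = "kind")
  to_row <- s[s$kind == "TO", ]
  expect_gt(to_row$me_ms, 0)
  expect_lt(abs(to_row$mae_ms - to_row$me_ms), 1e-9)
})
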