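# Validation of kinematic events against force-platform references: event
# matching, signed timing errors, ME/MAE/SD summaries, stride-normalised
# errors and Bland-Altman agreement statistics.

#' Match predicted events to reference events
#'
#' Pairs each predicted event with the nearest reference event of the same
#' side and kind, one-to-one and greedily by smallest time difference, and
#' only within half the local reference stride (the spacing of neighbouring
#' reference events of that kind), so a prediction can never be matched
#' across cycles. Leftover events on either list are reported unmatched.
#'
#' @param predicted,reference gait-event data frames; matching is done within
#'   each (side, kind) stratum present in the reference.
#' @param kinds event kinds to match (default HS and TO).
#' @return data frame of matched pairs: `side, kind, t_pred, t_ref, stride_s`
#'   (local reference stride). Unmatched events are attached as attributes
#'   `unmatched_pred` and `unmatched_ref`.
#' @export
match_events <- function(predicted, reference, kinds = c("HS", "TO")) {
  predicted <- sort_events(check_events(predicted))
  reference <- sort_events(check_events(reference))
  pairs <- list()
  un_pred <- list()
  un_ref <- list()
  for (side in unique(reference$side)) {
    for (kind in kinds) {
      tp <- predicted$time_s[predicted$side == side &
                               predicted$kind == kind]
      tr <- reference$time_s[reference$side == side &
                               reference$kind == kind]
      m <- match_times(tp, tr)
      if (nrow(m$pairs) > 0L) {
        pairs[[length(pairs) + 1L]] <-
          cbind(data.frame(side = side, kind = kind,
                           stringsAsFactors = FALSE), m$pairs)
      }
      if (length(m$unmatched_pred) > 0L) {
        un_pred[[length(un_pred) + 1L]] <-
          data.frame(side = side, kind = kind, time_s = m$unmatched_pred,
                     stringsAsFactors = FALSE)
      }
      if (length(m$unmatched_ref) > 0L) {
        un_ref[[length(un_ref) + 1L]] <-
          data.frame(side = side, kind = kind, time_s = m$unmatched_ref,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(side = character(0), kind = character(0),
               t_pred = numeric(0), t_ref = numeric(0),
               stride_s = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$side, res$kind, res$t_ref), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unmatched_pred") <- if (length(un_pred))
    do.call(rbind, un_pred) else NULL
  attr(res, "unmatched_ref") <- if (length(un_ref))
    do.call(rbind, un_ref) else NULL
  res
}

# Local reference stride at each reference event: mean spacing to its
# neighbours (single-sided at the ends, Inf when only one reference exists).
#' @noRd
local_ref_stride <- function(tr) {
  n <- length(tr)
  if (n < 2L) return(rep(Inf, n))
  d <- diff(tr)
  c(d[1L], if (n > 2L) (d[-length(d)] + d[-1L]) / 2 else NULL, d[n - 1L])
}

#' @noRd
match_times <- function(tp, tr) {
  stride <- local_ref_stride(tr)
  cand <- expand.grid(i = seq_along(tp), j = seq_along(tr))
  if (nrow(cand) > 0L) {
    cand$dt <- abs(tp[cand$i] - tr[cand$j])
    cand <- cand[cand$dt <= stride[cand$j] / 2, , drop = FALSE]
    cand <- cand[order(cand$dt, cand$i), , drop = FALSE]
  }
  used_p <- logical(length(tp))
  used_r <- logical(length(tr))
  keep_i <- integer(0)
  keep_j <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_p[i] && !used_r[j]) {
      used_p[i] <- TRUE; used_r[j] <- TRUE
      keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
    }
  }
  ord <- order(tr[keep_j])
  list(pairs = data.frame(t_pred = tp[keep_i][ord], t_ref = tr[keep_j][ord],
                          stride_s = stride[keep_j][ord],
                          stringsAsFactors = FALSE),
       unmatched_pred = tp[!used_p], unmatched_ref = tr[!used_r])
}

#' Signed event-timing errors
#'
#' The error of a matched pair is `e_ms = (t_ref - t_pred) * 1000`:
#' positive when the predicted event precedes the actual (reference) event,
#' negative when it lags it.
#'
#' @param pairs matched pairs from [match_events()].
#' @return data frame `side, kind, e_ms, stride_s, e_pct` (`e_pct` is NA
#'   until filled by [normalize_errors()]).
#' @export
event_errors <- function(pairs) {
  stopifnot(all(c("side", "kind", "t_pred", "t_ref") %in% names(pairs)))
  data.frame(side = pairs$side, kind = pairs$kind,
             e_ms = (pairs$t_ref - pairs$t_pred) * 1000,
             stride_s = if ("stride_s" %in% names(pairs)) pairs$stride_s
                        else NA_real_,
             e_pct = NA_real_, stringsAsFactors = FALSE)
}

#' Stride-normalised errors
#'
#' Fills `e_pct = 100 * |e_ms| / (1000 * stride_s)`, the absolute error as a
#' percentage of the enclosing reference stride, for comparison across
#' walking speeds. Errors without a finite positive stride are left
#' unnormalised with a warning.
#'
#' @param errors data frame from [event_errors()].
#' @return the same data frame with `e_pct` filled.
#' @export
normalize_errors <- function(errors) {
  stopifnot(all(c("e_ms", "stride_s") %in% names(errors)))
  ok <- is.finite(errors$stride_s) & errors$stride_s > 0
  errors$e_pct[ok] <- 100 * abs(errors$e_ms[ok]) / (1000 * errors$stride_s[ok])
  if (any(!ok)) {
    warning(sum(!ok), " error(s) without a valid stride left unnormalised",
            call. = FALSE)
  }
  errors
}

#' Summarise errors: ME, MAE and SD by group
#'
#' Mean signed error (ME), mean absolute error (MAE) and sample standard
#' deviation (n - 1 denominator; NA when a group has a single error), per
#' combination of the grouping columns.
#'
#' @param errors data frame with an `e_ms` column (see [event_errors()]).
#' @param group_by character vector of grouping columns present in `errors`
#'   (default `c("kind", "side")`).
#' @return data frame with the group columns plus `n, me_ms, mae_ms, sd_ms`.
#' @export
summarize_errors <- function(errors, group_by = c("kind", "side")) {
  stopifnot("e_ms" %in% names(errors),
            all(group_by %in% names(errors)))
  if (nrow(errors) == 0L) {
    warning("no errors to summarise", call. = FALSE)
    return(data.frame())
  }
  f <- interaction(lapply(group_by, function(g) errors[[g]]),
                   sep = "\r", drop = TRUE)
  groups <- split(errors$e_ms, f)
  keys <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- group_by
  out$n <- vapply(groups, length, integer(1))
  out$me_ms <- vapply(groups, mean, numeric(1))
  out$mae_ms <- vapply(groups, function(e) mean(abs(e)), numeric(1))
  out$sd_ms <- vapply(groups, function(e)
    if (length(e) > 1L) stats::sd(e) else NA_real_, numeric(1))
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement statistics
#'
#' For paired per-cycle parameter values, computes the differences
#' `method - reference` and reports the bias (mean difference), the
#' reproducibility coefficient `rpc = 1.96 * SD(differences)`, the limits of
#' agreement `bias -/+ rpc`, and the coefficient of variation
#' `cv = 100 * SD(differences) / mean of the pair means` (percent).
#'
#' @param method numeric vector of method values (e.g. kinematic stride
#'   times).
#' @param reference paired reference values, same length, n >= 2.
#' @param parameter label for printing.
#' @return object of class `bland_altman`: fields `parameter, n, bias,
#'   sd_diff, rpc, loa_low, loa_high, cv`.
#' @export
bland_altman <- function(method, reference, parameter = "parameter") {
  if (length(method) != length(reference)) {
    stop("method and reference must be paired (equal length)", call. = FALSE)
  }
  ok <- is.finite(method) & is.finite(reference)
  method <- method[ok]; reference <- reference[ok]
  if (length(method) < 2L) {
    stop("insufficient data: Bland-Altman needs at least 2 pairs",
         call. = FALSE)
  }
  d <- method - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  rpc <- 1.96 * sd_diff
  structure(list(parameter = parameter, n = length(d), bias = bias,
                 sd_diff = sd_diff, rpc = rpc,
                 loa_low = bias - rpc, loa_high = bias + rpc,
                 cv = 100 * sd_diff / mean((method + reference) / 2)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman '%s'> n = %d\n", x$parameter, x$n))
  cat(sprintf("  bias %.4g, LoA [%.4g, %.4g], RPC %.4g, CV %.3g%%\n",
              x$bias, x$loa_low, x$loa_high, x$rpc, x$cv))
  invisible(x)
}

#' @export
as.data.frame.bland_altman <- function(x, ...) {
  data.frame(parameter = x$parameter, n = x$n, bias = x$bias,
             sd_diff = x$sd_diff, rpc = x$rpc, loa_low = x$loa_low,
             loa_high = x$loa_high, cv = x$cv, stringsAsFactors = FALSE)
}
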