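#' Detect foot-strike and toe-off events from a COP trajectory
#'
#' During treadmill gait the ML component of the COP alternates between two
#' plateaus (single support under the left or right foot) joined by rapid
#' transfers (double support), the classic butterfly. Events are extracted
#' by hysteresis segmentation of the ML signal around its midline: samples
#' beyond half the butterfly amplitude belong to a side plateau, and each
#' plateau-to-plateau transfer is fit with a least-squares line whose
#' crossings of the two plateau levels give, respectively, the foot strike
#' of the destination side (onset of weight transfer) and the toe-off of
#' the source side (completion of transfer).
#'
#' @param cop data.frame with columns `time`, `ap`, `ml` (seconds, meters);
#'   ML positive toward the walker's right.
#' @param min_amplitude smallest acceptable butterfly half-amplitude (m);
#'   below this the signal is declared non-alternating.
#' @return an object of class `gait_events`: data.frame with columns `time`,
#'   `event` (`"strike"` or `"toe_off"`) and `foot`, ordered in time.
#' @export
detect_events <- function(cop, min_amplitude = 0.02) {
  if (!all(c("time", "ap", "ml") %in% names(cop))) {
    stopf("cop must have columns time, ap, ml")
  }
  ml <- cop$ml
  tm <- cop$time
  hi <- stats::quantile(ml, 0.9, names = FALSE)
  lo <- stats::quantile(ml, 0.1, names = FALSE)
  amp <- (hi - lo) / 2
  if (!is.finite(amp) || amp < min_amplitude) {
    stopf(paste0("no alternating ML COP pattern: butterfly half-amplitude ",
                 "%.4f m is below %.4f m (monotone or too-short signal?)"),
          amp, min_amplitude)
  }
  mid <- (hi + lo) / 2
  s <- ml - mid
  thr <- 0.5 * amp

  state <- ifelse(s > thr, 1L, ifelse(s < -thr, -1L, 0L))
  # carry the last plateau side through the transfer samples
  filled <- state
  last <- 0L
  for (i in seq_along(filled)) {
    if (filled[i] == 0L) filled[i] <- last else last <- filled[i]
  }
  r <- rle(filled)
  keep <- r$values != 0L
  if (sum(keep) < 3) {
    stopf("signal too short: fewer than two complete single-support plateaus")
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  plats <- data.frame(side = r$values[keep],
                      start = starts[keep], end = ends[keep])
  # drop truncated edge segments (ramps cut by the recording boundary)
  # whose level estimate would be biased
  len <- plats$end - plats$start + 1
  ok_len <- len >= 0.5 * stats::median(len)
  first_bad <- !ok_len[1]
  last_bad <- !ok_len[nrow(plats)]
  if (first_bad) plats <- plats[-1, , drop = FALSE]
  if (last_bad && nrow(plats)) plats <- plats[-nrow(plats), , drop = FALSE]
  if (nrow(plats) < 3) {
    stopf("signal too short: fewer than two complete single-support plateaus")
  }
  if (any(diff(plats$side) == 0)) {
    stopf("non-alternating ML plateau pattern: consecutive same-side plateaus")
  }

  foot_of <- function(side) ifelse(side > 0, "right", "left")
  ev <- list()
  for (i in seq_len(nrow(plats) - 1)) {
    p1 <- plats[i, ]; p2 <- plats[i + 1, ]
    core1 <- s[p1$start:p1$end]; core2 <- s[p2$start:p2$end]
    A1 <- stats::median(core1); A2 <- stats::median(core2)
    # transfer window: contiguous samples around the side flip with
    # |s| within 75% of the butterfly amplitude (the ramp, plateaus excluded)
    band <- 0.75 * amp
    lo_i <- p2$start
    while (lo_i > p1$start && abs(s[lo_i - 1]) <= band) lo_i <- lo_i - 1
    hi_i <- p2$start
    while (hi_i < p2$end && abs(s[hi_i + 1]) <= band) hi_i <- hi_i + 1
    gi <- lo_i:hi_i
    if (length(gi) < 2) next
    fit <- stats::lm.fit(cbind(1, tm[gi]), s[gi])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (!is.finite(b) || b == 0) next
    t_strike <- (A1 - a) / b     # leaving plateau 1: destination-foot strike
    t_toeoff <- (A2 - a) / b     # reaching plateau 2: source-foot toe-off
    ev[[length(ev) + 1]] <- data.frame(
      time = c(t_strike, t_toeoff),
      event = c("strike", "toe_off"),
      foot = c(foot_of(p2$side), foot_of(p1$side)),
      stringsAsFactors = FALSE
    )
  }
  if (length(ev) == 0) stopf("signal too short: no complete weight transfer found")
  out <- do.call(rbind, ev)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  bad <- out$time < tm[1] - 0.2 | out$time > tm[length(tm)] + 0.2
  out <- out[!bad, , drop = FALSE]
  class(out) <- c("gait_events", "data.frame")
  out
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events: %d strikes, %d toe-offs, %.2f-%.2f s>\n",
              sum(x$event == "strike"), sum(x$event == "toe_off"),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Stance table: pair each foot strike with its own toe-off
#' @param events a `gait_events` object.
#' @return data.frame `foot`, `strike`, `toe_off` (NA when the recording
#'   ends mid-stance), ordered by strike time.
#' @export
stance_table <- function(events) {
  st <- events[events$event == "strike", ]
  to <- events[events$event == "toe_off", ]
  res <- st[, c("foot", "time")]
  names(res)[2] <- "strike"
  res$toe_off <- vapply(seq_len(nrow(res)), function(i) {
    cand <- to$time[to$foot == res$foot[i] & to$time > res$strike[i]]
    if (length(cand)) min(cand) else NA_real_
  }, numeric(1))
  res <- res[order(res$strike), ]
  rownames(res) <- NULL
  res
}

#' Midstance times
#'
#' Midstance of a stance phase is the midpoint of the ipsilateral
#' single-support window, i.e. 50% between the contralateral foot's toe-off
#' and its subsequent heel strike.
#'
#' @param events a `gait_events` object.
#' @return data.frame with one row per stance for which both contralateral
#'   events exist: `foot`, `strike`, `contra_toe_off`, `contra_strike`,
#'   `midstance`. Stances truncated by the recording edges are dropped;
#'   an interior stance with a missing contralateral event is an error.
#' @export
midstance_times <- function(events) {
  stances <- stance_table(events)
  n <- nrow(stances)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- stances$strike[i]
    e <- stances$toe_off[i]
    contra <- events[events$foot != stances$foot[i], ]
    ct_off <- contra$time[contra$event == "toe_off" & contra$time >= s &
                            (is.na(e) | contra$time <= e)]
    ct_str <- contra$time[contra$event == "strike" & contra$time > s &
                            (is.na(e) | contra$time <= e)]
    if (length(ct_off) == 0 || length(ct_str) == 0) {
      # edge stances lack bracketing events; interior ones must not
      if (i > 1 && i < n) {
        stopf("unpaired events: stance of the %s foot striking at %.3f s has no bracketing contralateral toe-off/strike",
              stances$foot[i], s)
      }
      next
    }
    rows[[i]] <- data.frame(
      foot = stances$foot[i], strike = s,
      contra_toe_off = ct_off[1], contra_strike = ct_str[1],
      midstance = (ct_off[1] + ct_str[1]) / 2,
      degenerate = ct_str[1] <= ct_off[1],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no stance with complete contralateral events")
  rownames(out) <- NULL
  out
}

#' Preferred step length from COP and events
#'
#' Mean AP distance between the COP positions at successive foot strikes,
#' compensated for belt motion (`+ belt_speed * dt`), over the first
#' `n_strides` strides (two steps per stride).
#'
#' @param cop data.frame `time`, `ap`, `ml`.
#' @param events a `gait_events` object for `cop`.
#' @param n_strides number of strides to average over (default 20).
#' @param belt_speed belt speed (m/s).
#' @return step length in meters.
#' @export
preferred_step_length <- function(cop, events, n_strides = 20,
                                  belt_speed = 3 / 3.6) {
  strikes <- sort(events$time[events$event == "strike"])
  n_steps <- 2 * n_strides
  if (length(strikes) < n_steps + 1) {
    stopf("need %d strides (%d foot strikes) but only %d strikes detected",
          n_strides, n_steps + 1, length(strikes))
  }
  strikes <- strikes[seq_len(n_steps + 1)]
  ap <- interp_at(cop$time, cop$ap, strikes)
  steps <- diff(ap) + belt_speed * diff(strikes)
  mean(steps)
}
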