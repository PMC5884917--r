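#' Simulate one precision-stepping trial
#'
#' Synthesizes marker trajectories (150 samples/s, three markers per foot:
#' third metatarsal head, lateral malleolus, heel), a center-of-pressure
#' (COP) trajectory (1000 samples/s, AP/ML), and a complete ground-truth
#' record for a walker performing one block of the protocol.
#'
#' The model walks at a cadence locked to the belt (step period
#' `L / belt_speed` unless the subject specifies `step_time`), with a duty
#' factor of 60%: each stance lasts 1.2 step periods, overlapping the
#' contralateral stance in 20% double-support phases. During stance the foot
#' rides the belt (lab-frame AP velocity `-belt_speed`); during swing the
#' foot follows a minimum-jerk AP profile to its next landing with a
#' half-sine vertical clearance. Landing centers equal the (displaced, for
#' shifted targets) target center at foot strike plus a signed error drawn
#' from the subject's landing distribution, inflated by [kappa_ard()] on
#' shifted targets. The COP progresses linearly heel-to-toe under the
#' single-support foot and transfers linearly between feet during double
#' support, reproducing the butterfly pattern used for event detection.
#'
#' Target shifts are realized at the first (noiseless) COP sample at which
#' the target's lab-frame AP distance from the COP drops to `ard * L`; onset
#' times are recorded in the trial's target log, emulating the projector
#' software log from which target positions are recovered at scoring time.
#'
#' @param subject one row of a [make_cohort()] table (or a list with
#'   `sigma`, `error_bias`, `kappa_gain`, `kappa_knee`, `marker_noise_sd`,
#'   `cop_noise_sd`, optional `step_time`).
#' @param block a `step_block` from the protocol module.
#' @param params the [protocol_params()] the block was generated with; its
#'   preferred step length must match the block's.
#' @param seed integer seed.
#' @param n_lead number of lead-in steps before the first target (>= 2).
#' @param n_trail trailing steps after the last target (>= 2), so that the
#'   last target's midstance is bracketed by events.
#' @param marker_rate,cop_rate sampling rates (samples/s).
#' @param duty_factor stance duration as a fraction of the stride (0.5-0.75).
#' @return an object of class `stepping_trial`: list with `markers` (time +
#'   18 channels), `cop` (time, ap, ml), `block`, `params`, `target_log`
#'   (appearance and realized shift-onset times), `truth` (per-step ground
#'   truth) and `subject`.
#' @export
simulate_trial <- function(subject, block, params, seed,
                           n_lead = 4L, n_trail = 2L,
                           marker_rate = 150, cop_rate = 1000,
                           duty_factor = 0.6) {
  bp <- attr(block, "params")
  if (!is.null(bp) &&
      abs(bp$preferred_step_length - params$preferred_step_length) > 1e-9) {
    stopf("block was generated for L = %g m but params give L = %g m",
          bp$preferred_step_length, params$preferred_step_length)
  }
  if (n_lead < 2 || n_trail < 2) stopf("n_lead and n_trail must be >= 2")
  L <- params$preferred_step_length
  v <- params$belt_speed
  Tstep <- subject$step_time
  if (is.null(Tstep) || is.na(Tstep)) Tstep <- L / v
  stance_dur <- 2 * duty_factor * Tstep        # 1.2 T at duty 0.6
  ds <- stance_dur - Tstep                     # double-support duration
  if (ds <= 0 || ds >= Tstep) stopf("duty_factor must give 0 < double support < step time")

  N <- nrow(block)
  M <- n_lead + N + n_trail
  t1 <- 0.5
  t_strike <- t1 + (seq_len(M) - 1) * Tstep

  # feet: strict alternation continuous with the block's own sequence
  first_target_foot <- block$foot[1]
  other <- function(f) ifelse(f == "right", "left", "right")
  foot <- character(M)
  foot[n_lead + seq_len(N)] <- block$foot
  for (j in rev(seq_len(n_lead))) foot[j] <- other(foot[j + 1])
  for (j in n_lead + N + seq_len(n_trail)) foot[j] <- other(foot[j - 1])
  ml_side <- ifelse(foot == "right", 1, -1) * params$ml_center_distance / 2

  target_step <- n_lead + seq_len(N)
  appearance <- t_strike[target_step] - params$appearance_distance / v

  shifted <- !is.na(block$shift_direction)
  delta <- ifelse(shifted, block$displaced_ap_center - block$nominal_ap_center, 0)

  seeds <- derive_seeds(seed, 2L)
  err <- with_seed(seeds[1], {
    kap <- rep(1, M)
    kap[target_step][shifted] <- kappa_ard(block$shift_ard[shifted], subject)
    stats::rnorm(M, subject$error_bias * L, subject$sigma * kap * L)
  })
  # lab-frame AP landing center of each step; targets cross the origin at
  # their step's strike time, so the landing equals shift offset + error
  land <- err
  land[target_step] <- delta + err[target_step]

  rec_start <- t_strike[2]
  rec_end <- t_strike[M] + Tstep

  ## ---- COP (noiseless core) -------------------------------------------
  tt <- seq(rec_start, rec_end, by = 1 / cop_rate)
  tau <- (tt - t1) / Tstep
  j <- pmin(floor(tau) + 1, M)
  frac <- tau - (j - 1)
  # COP heel-to-toe half-excursion: at push-off the COP reaches the toe
  # region, close to the front of the shoe
  h <- 0.45 * params$shoe_length
  ds_frac <- ds / Tstep
  in_ds <- frac < ds_frac & j >= 2
  cop_ap <- numeric(length(tt))
  cop_ml <- numeric(length(tt))
  ss <- !in_ds
  u <- (frac[ss] - ds_frac) / (1 - ds_frac)
  cop_ap[ss] <- land[j[ss]] - v * (tt[ss] - t_strike[j[ss]]) + h * (2 * u - 1)
  cop_ml[ss] <- ml_side[j[ss]]
  jd <- j[in_ds]
  w <- frac[in_ds] / ds_frac
  A <- land[jd - 1] + h - v * (tt[in_ds] - t_strike[jd - 1])
  B <- land[jd] - h - v * (tt[in_ds] - t_strike[jd])
  cop_ap[in_ds] <- (1 - w) * A + w * B
  cop_ml[in_ds] <- (1 - w) * ml_side[jd - 1] + w * ml_side[jd]

  ## ---- realized shift onsets (from the noiseless COP) -----------------
  shift_onset <- rep(NA_real_, N)
  for (i in which(shifted)) {
    lab_ap <- params$appearance_distance - v * (tt - appearance[i])
    ok <- tt >= appearance[i] &
      (lab_ap - cop_ap) <= block$shift_ard[i] * L
    hit <- which(ok)[1]
    t_land_i <- t_strike[target_step[i]]
    if (is.na(hit) || tt[hit] >= t_land_i) {
      # gait variability can keep the COP just outside the criterion until
      # the last moment; the projector then shifts as late as it can
      hit <- max(which(tt < t_land_i))
    }
    shift_onset[i] <- tt[hit]
  }

  ## ---- markers --------------------------------------------------------
  mt <- seq(rec_start, rec_end, by = 1 / marker_rate)
  clearance <- 0.05
  foot_xyz <- function(f) {
    J <- which(foot == f)
    x <- numeric(length(mt)); z <- numeric(length(mt)); ml <- numeric(length(mt))
    for (ii in seq_along(J)) {
      jj <- J[ii]
      seg_end <- if (ii < length(J)) t_strike[J[ii + 1]] else rec_end + 1
      sel <- mt >= t_strike[jj] - 1e-12 & mt < seg_end
      if (ii == 1) sel <- mt < seg_end       # extend first stance backwards
      ts <- mt[sel]
      st_end <- t_strike[jj] + stance_dur
      stance <- ts < st_end | ii == length(J)
      x[sel][stance] <- land[jj] - v * (ts[stance] - t_strike[jj])
      z[sel][stance] <- 0
      ml[sel][stance] <- ml_side[jj]
      if (any(!stance)) {
        jn <- J[ii + 1]
        tau_s <- (ts[!stance] - st_end) / (t_strike[jn] - st_end)
        s <- 10 * tau_s^3 - 15 * tau_s^4 + 6 * tau_s^5
        p0 <- land[jj] - v * stance_dur
        x[sel][!stance] <- p0 + (land[jn] - p0) * s
        z[sel][!stance] <- clearance * sin(pi * tau_s)
        ml[sel][!stance] <- ml_side[jj] + (ml_side[jn] - ml_side[jj]) * s
      }
    }
    list(x = x, z = z, ml = ml)
  }

  len <- params$shoe_length
  # rigid marker offsets from the foot center (sum to zero on every axis,
  # so the marker centroid coincides with the foot center in AP and ML)
  offsets <- list(
    toe  = c(ap = 0.40 * len, ml = -0.025, z = 0.02),
    mall = c(ap = 0.05 * len, ml =  0.050, z = 0.08),
    heel = c(ap = -0.45 * len, ml = -0.025, z = 0.03)
  )
  markers <- data.frame(time = mt)
  n_mark <- with_seed(seeds[2], {
    for (f in c("left", "right")) {
      ctr <- foot_xyz(f)
      sgn <- if (f == "right") 1 else -1
      for (m in names(offsets)) {
        o <- offsets[[m]]
        markers[[paste(f, m, "ap", sep = "_")]] <-
          ctr$x + o[["ap"]] + stats::rnorm(length(mt), 0, subject$marker_noise_sd)
        markers[[paste(f, m, "ml", sep = "_")]] <-
          ctr$ml + sgn * o[["ml"]] + stats::rnorm(length(mt), 0, subject$marker_noise_sd)
        markers[[paste(f, m, "z", sep = "_")]] <-
          ctr$z + o[["z"]] + stats::rnorm(length(mt), 0, subject$marker_noise_sd)
      }
    }
    cop_ap <- cop_ap + stats::rnorm(length(tt), 0, subject$cop_noise_sd)
    cop_ml <- cop_ml + stats::rnorm(length(tt), 0, subject$cop_noise_sd)
    list(markers = markers, cop_ap = cop_ap, cop_ml = cop_ml)
  })
  markers <- n_mark$markers
  cop_ap <- n_mark$cop_ap
  cop_ml <- n_mark$cop_ml

  target_log <- data.frame(
    index = block$index,
    appearance_time = appearance,
    shift_onset = shift_onset,
    stringsAsFactors = FALSE
  )

  truth_steps <- data.frame(
    step = seq_len(M),
    target_index = {
      ti <- rep(NA_integer_, M); ti[target_step] <- block$index; ti
    },
    foot = foot,
    strike = t_strike,
    toe_off = t_strike + stance_dur,
    ss_start = t_strike + ds,
    ss_end = t_strike + Tstep,
    midstance = t_strike + (ds + Tstep) / 2,
    landing_ap = land,
    true_error = err,
    stringsAsFactors = FALSE
  )

  structure(list(
    markers = markers, marker_rate = marker_rate,
    cop = data.frame(time = tt, ap = cop_ap, ml = cop_ml),
    cop_rate = cop_rate,
    block = block, params = params,
    target_log = target_log,
    truth = list(steps = truth_steps, step_time = Tstep,
                 stance_duration = stance_dur),
    subject = subject
  ), class = "stepping_trial")
}

#' @export
print.stepping_trial <- function(x, ...) {
  cat(sprintf(
    "<stepping_trial: %s block, %d targets, %.1f s, %d COP / %d marker samples>\n",
    attr(x$block, "kind"), nrow(x$block),
    diff(range(x$cop$time)), nrow(x$cop), nrow(x$markers)))
  invisible(x)
}
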