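#' Foot center from the marker triangle at a time point
#'
#' The foot is represented by the triangle of its three markers (toe =
#' third metatarsal head, lateral malleolus, heel); its center is the center
#' of the three connecting-segment midpoints, which equals the centroid of
#' the three markers.
#'
#' @param markers marker data.frame from a trial (`time` + 18 channels named
#'   `<foot>_<marker>_<axis>`).
#' @param t time (s), inside the recording; marker samples are linearly
#'   interpolated within a 33 ms window.
#' @param foot `"left"` or `"right"`.
#' @return named numeric `c(ap = , ml = , z = )` in meters.
#' @export
foot_center_at <- function(markers, t, foot = c("left", "right")) {
  foot <- match.arg(foot)
  out <- vapply(c("ap", "ml", "z"), function(axis) {
    cols <- paste(foot, c("toe", "mall", "heel"), axis, sep = "_")
    missing <- setdiff(cols, names(markers))
    if (length(missing)) stopf("marker channel %s not found", missing[1])
    vals <- vapply(cols, function(cl) {
      interp_at(markers$time, markers[[cl]], t, max_gap = 0.033)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  names(out) <- c("ap", "ml", "z")
  out
}

#' Lab-frame target center at midstance
#'
#' Recomputes the target's lab-frame center at the moment of midstance from
#' the protocol geometry, belt kinematics and the trial's target log (the
#' projector's record of appearance and realized shift-onset times). Once a
#' shift has been realized, the displaced AP center is used.
#'
#' @param target one-row slice of a `step_block`.
#' @param t_mid midstance time (s).
#' @param params a [protocol_params()] object.
#' @param appearance_time the target's appearance time (s).
#' @param shift_onset realized shift-onset time (s) or `NA` if unshifted.
#' @return named numeric `c(ap = , ml = )` in meters.
#' @export
target_center_at_midstance <- function(target, t_mid, params,
                                       appearance_time, shift_onset = NA) {
  pos <- target_lab_position(target, t_mid, appearance_time, params)
  if (!is.na(shift_onset) && t_mid >= shift_onset) {
    pos["ap"] <- pos[["ap"]] +
      (target$displaced_ap_center - target$nominal_ap_center)
  }
  pos
}

#' Signed anteroposterior step error
#'
#' AP distance between the centers of the targeting foot and the step
#' target at midstance. Positive errors are overshoots (foot center
#' anterior to the target center), negative errors undershoots.
#'
#' @param foot_center,target_center positions with an `ap` component, in the
#'   lab frame at the same instant.
#' @return signed error in meters.
#' @export
step_error <- function(foot_center, target_center) {
  as.numeric(foot_center[["ap"]] - target_center[["ap"]])
}

#' Mean error and variability of a condition
#'
#' The constant error is the mean raw error, normalized to the preferred
#' step length; the variability is the population (divide-by-k) standard
#' deviation of the raw errors,
#' \deqn{\sqrt{(\Sigma e^2 - (\Sigma e)^2/k)/k},}
#' expressed as a percentage of the preferred step length.
#'
#' @param errors raw signed step errors (m).
#' @param L preferred step length (m, > 0).
#' @return named numeric: `mean_error` and `variability` (both % of L) and
#'   `k` (number of steps).
#' @export
condition_summary <- function(errors, L) {
  k <- length(errors)
  if (k < 1) stopf("condition_summary needs at least one step error")
  if (!is_number(L) || L <= 0) stopf("L must be a positive step length")
  ss <- sum(errors^2) - sum(errors)^2 / k
  c(mean_error = 100 * mean(errors) / L,
    variability = 100 / L * sqrt(max(ss, 0) / k),
    k = k)
}

#' Pool condition summaries over the forward ARDs
#'
#' Unweighted mean of the four forward-ARD condition values, per measure.
#'
#' @param per_ard data.frame with columns `ard`, `mean_error`,
#'   `variability` (one row per forward ARD condition).
#' @param ard_conditions the forward ARDs that must be present.
#' @return named numeric `c(mean_error = , variability = )` (% of L).
#' @export
pool_over_ard <- function(per_ard, ard_conditions = c(0.8, 1.0, 1.3, 2.0)) {
  missing <- setdiff(ard_conditions, per_ard$ard)
  if (length(missing)) {
    stopf("missing ARD condition(s): %s",
          paste(format(missing), collapse = ", "))
  }
  sel <- per_ard[per_ard$ard %in% ard_conditions, ]
  c(mean_error = mean(sel$mean_error), variability = mean(sel$variability))
}

#' Score every target of a simulated or imported trial
#'
#' Detects gait events (unless supplied), derives midstance times, matches
#' each target to the stance landing on it (nearest foot strike to the
#' target's expected arrival at the walker, same foot), and computes the
#' signed AP step error at midstance from the marker-based foot center and
#' the log-reconstructed target center. Targets without a matching stance
#' or midstance are dropped with a message.
#'
#' @param trial a `stepping_trial` (or a compatible list with `markers`,
#'   `cop`, `block`, `params`, `target_log`).
#' @param events optional precomputed [detect_events()] result.
#' @return a `step_scores` data.frame: `index`, `foot`, `condition`,
#'   `direction`, `ard`, `midstance`, `raw_error` (m), `normalized_error`
#'   (% of L); attribute `L`.
#' @export
score_trial <- function(trial, events = NULL) {
  if (is.null(events)) events <- detect_events(trial$cop)
  mid <- midstance_times(events)
  block <- trial$block
  params <- trial$params
  L <- params$preferred_step_length
  v <- params$belt_speed
  log <- trial$target_log
  t_expect <- log$appearance_time + params$appearance_distance / v
  step_t <- L / v

  rows <- vector("list", nrow(block))
  dropped <- 0L
  for (i in seq_len(nrow(block))) {
    cand <- which(mid$foot == block$foot[i])
    if (length(cand) == 0) { dropped <- dropped + 1L; next }
    d <- abs(mid$strike[cand] - t_expect[i])
    jbest <- cand[which.min(d)]
    if (min(d) > 0.5 * step_t) { dropped <- dropped + 1L; next }
    t_mid <- mid$midstance[jbest]
    fc <- foot_center_at(trial$markers, t_mid, block$foot[i])
    tc <- target_center_at_midstance(block[i, ], t_mid, params,
                                     log$appearance_time[i],
                                     log$shift_onset[i])
    e <- step_error(fc, tc)
    shifted <- !is.na(block$shift_direction[i])
    rows[[i]] <- data.frame(
      index = block$index[i],
      foot = block$foot[i],
      condition = if (shifted) {
        paste0(block$shift_direction[i], "_", format(block$shift_ard[i]))
      } else "unperturbed",
      direction = block$shift_direction[i],
      ard = block$shift_ard[i],
      midstance = t_mid,
      raw_error = e,
      normalized_error = 100 * e / L,
      stringsAsFactors = FALSE
    )
  }
  if (dropped > 0) {
    message(sprintf("score_trial: dropped %d of %d targets without a matched stance",
                    dropped, nrow(block)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no target could be matched to a stance")
  out$block_kind <- attr(block, "kind")
  attr(out, "L") <- L
  class(out) <- c("step_scores", "data.frame")
  out
}

#' Per-subject summary of step scores
#'
#' Unperturbed measures come from unperturbed steps of unperturbed blocks;
#' perturbed measures from shifted forward steps of perturbed blocks,
#' summarized per ARD condition and then averaged (unweighted) over the
#' four forward ARDs. Backward (catch) shifts are scored but excluded from
#' all summaries.
#'
#' @param scores a `step_scores` data.frame (possibly row-bound over
#'   blocks, with a `block_kind` column).
#' @param L preferred step length (m); defaults to the scores' attribute.
#' @param ard_conditions forward ARD levels.
#' @return a one-row data.frame: `unperturbed_error`,
#'   `unperturbed_variability`, per-ARD `error_ard<ard>` /
#'   `variability_ard<ard>`, pooled `perturbed_error`,
#'   `perturbed_variability`, and per-condition counts `k_unperturbed`,
#'   `k_ard<ard>` (all errors in % of L).
#' @export
subject_summary <- function(scores, L = attr(scores, "L"),
                            ard_conditions = c(0.8, 1.0, 1.3, 2.0)) {
  if (is.null(L)) stopf("preferred step length L is required")
  unp <- scores$raw_error[scores$block_kind == "unperturbed" &
                            scores$condition == "unperturbed"]
  if (length(unp) == 0) stopf("no unperturbed steps to summarize")
  su <- condition_summary(unp, L)

  per_ard <- do.call(rbind, lapply(ard_conditions, function(a) {
    e <- scores$raw_error[!is.na(scores$direction) &
                            scores$direction == "forward" &
                            abs(scores$ard - a) < 1e-9]
    if (length(e) == 0) {
      stopf("missing ARD condition(s): %s", format(a))
    }
    cs <- condition_summary(e, L)
    data.frame(ard = a, mean_error = cs[["mean_error"]],
               variability = cs[["variability"]], k = cs[["k"]])
  }))
  pooled <- pool_over_ard(per_ard, ard_conditions)

  out <- data.frame(
    unperturbed_error = su[["mean_error"]],
    unperturbed_variability = su[["variability"]],
    perturbed_error = pooled[["mean_error"]],
    perturbed_variability = pooled[["variability"]],
    k_unperturbed = su[["k"]]
  )
  for (i in seq_len(nrow(per_ard))) {
    a <- per_ard$ard[i]
    tag <- sub("\\.", "", format(100 * a))
    out[[paste0("error_ard", tag)]] <- per_ard$mean_error[i]
    out[[paste0("variability_ard", tag)]] <- per_ard$variability[i]
    out[[paste0("k_ard", tag)]] <- per_ard$k[i]
  }
  out
}
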