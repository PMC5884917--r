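#' Subject model template
#'
#' Parameters of the generative model for one walker. Landing errors on a
#' target are drawn from a normal distribution whose mean (`error_bias`, an
#' age-invariant constant bias) and standard deviation are expressed as
#' fractions of the preferred step length L. The per-subject standard
#' deviation follows a linear age model
#' \deqn{\sigma(age) = \sigma_0 + b \cdot age,}
#' with `b <= 0`: stepping becomes more consistent with age. On shifted
#' targets the standard deviation is inflated by a factor
#' `kappa(ard) >= 1` that is non-increasing in the available response
#' distance: the less distance (time) available to correct the step, the
#' more variable the landing.
#'
#' Defaults are calibrated so that a cohort of 30 walkers aged 9-18.5 years
#' shows a population correlation of about -0.6 between age and unperturbed
#' step variability (see the methods vignette).
#'
#' @param error_bias mean signed landing error, fraction of L (+ overshoot).
#' @param sigma0 intercept of the variability model, fraction of L.
#' @param age_slope slope `b` of the variability model, fraction of L per
#'   year; must be `<= 0`.
#' @param sigma_between between-subject SD around the age model, fraction of
#'   L.
#' @param bias_between between-subject SD of the bias, fraction of L.
#' @param sigma_floor lower truncation for the per-subject SD, fraction of L.
#' @param kappa_gain,kappa_knee parameters of the ARD inflation factor
#'   `kappa(ard) = 1 + kappa_gain * max(0, kappa_knee - ard) / (kappa_knee - 0.8)`.
#' @param step_time step period in seconds; `NA` means lock the cadence to
#'   the belt (`L / belt_speed`) so the walker tracks the belt-fixed targets.
#' @param marker_noise_sd additive white noise on marker positions (m).
#' @param cop_noise_sd additive white noise on the COP signal (m).
#' @return an object of class `subject_model` (named list).
#' @export
subject_model <- function(error_bias = -0.01,
                          sigma0 = 0.060,
                          age_slope = -0.0020,
                          sigma_between = 0.0067,
                          bias_between = 0.010,
                          sigma_floor = 0.005,
                          kappa_gain = 0.5,
                          kappa_knee = 1.5,
                          step_time = NA_real_,
                          marker_noise_sd = 0.001,
                          cop_noise_sd = 0.002) {
  if (age_slope > 0) stopf("age_slope must be <= 0 (variability cannot grow with age)")
  if (sigma0 <= 0) stopf("sigma0 must be positive")
  if (kappa_gain < 0) stopf("kappa_gain must be >= 0 (kappa(ard) >= 1)")
  m <- list(
    error_bias = error_bias, sigma0 = sigma0, age_slope = age_slope,
    sigma_between = sigma_between, bias_between = bias_between,
    sigma_floor = sigma_floor,
    kappa_gain = kappa_gain, kappa_knee = kappa_knee,
    step_time = step_time,
    marker_noise_sd = marker_noise_sd, cop_noise_sd = cop_noise_sd
  )
  class(m) <- "subject_model"
  m
}

#' ARD inflation factor for landing variability
#'
#' Non-increasing in `ard`, equal to 1 for large ARDs: with two step lengths
#' of warning the response is as precise as an unperturbed step, while late
#' shifts (small ARD) force fast corrections and inflate variability.
#'
#' @param ard available response distance, fraction of L (> 0).
#' @param model a [subject_model()] (or list with `kappa_gain`, `kappa_knee`).
#' @return multiplicative SD factor `>= 1`.
#' @export
kappa_ard <- function(ard, model = subject_model()) {
  if (any(ard <= 0)) stopf("ard must be positive")
  1 + model$kappa_gain * pmax(0, model$kappa_knee - ard) / (model$kappa_knee - 0.8)
}

#' Landing distribution for a shifted target
#'
#' Returns the parameters of the landing distribution relative to the
#' displaced target center: the walker re-aims at the new center with its
#' habitual bias, and with variability inflated by [kappa_ard()].
#'
#' @param subject one row of a [make_cohort()] table (or list with
#'   `error_bias`, `sigma`, and kappa parameters), values as fractions of L.
#' @param ard available response distance, fraction of L.
#' @param L preferred step length (m), used to express the result in meters.
#' @return list with `mean_m` and `sd_m` (meters, relative to the displaced
#'   center) and the inflation `kappa`.
#' @export
respond_to_shift <- function(subject, ard, L = 1) {
  kap <- kappa_ard(ard, subject)
  list(mean_m = subject$error_bias * L,
       sd_m = subject$sigma * kap * L,
       kappa = kap)
}

#' Draw a cohort of subjects
#'
#' Ages are uniform on `age_range`; each subject's landing-error SD follows
#' the linear age model of the template plus between-subject noise
#' (truncated at `sigma_floor`), and its bias is the template bias plus
#' between-subject noise. Preferred step length grows mildly with age.
#'
#' @param n number of subjects (>= 2).
#' @param age_range numeric `c(min, max)` in years.
#' @param model a [subject_model()] template.
#' @param seed integer seed.
#' @return a data.frame of class `cohort_params`, one row per subject:
#'   `id`, `age`, `sex`, `error_bias`, `sigma` (fractions of L),
#'   `preferred_step_length` (m), plus noise settings; the template is kept
#'   as an attribute.
#' @export
#' @examples
#' co <- make_cohort(30, c(9, 18.5), seed = 1)
#' cor(co$age, co$sigma)  # negative: older walkers step more consistently
make_cohort <- function(n, age_range = c(9, 18.5), model = subject_model(),
                        seed) {
  if (!is_count(n) || n < 2) stopf("a cohort needs n >= 2 subjects")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stopf("age_range must be c(min, max) with min < max")
  }
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sigma <- model$sigma0 + model$age_slope * age +
      stats::rnorm(n, 0, model$sigma_between)
    sigma <- pmax(sigma, model$sigma_floor)
    bias <- model$error_bias + stats::rnorm(n, 0, model$bias_between)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    co <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      age = age, sex = sex,
      error_bias = bias, sigma = sigma,
      preferred_step_length = 0.40 + 0.008 * age,
      kappa_gain = model$kappa_gain, kappa_knee = model$kappa_knee,
      marker_noise_sd = model$marker_noise_sd,
      cop_noise_sd = model$cop_noise_sd,
      stringsAsFactors = FALSE
    )
    attr(co, "model") <- model
    attr(co, "age_range") <- age_range
    class(co) <- c("cohort_params", "data.frame")
    co
  })
}

#' Draw per-step landing errors for one subject (score level)
#'
#' Generates the true signed landing errors a subject would produce over a
#' full session (one unperturbed block and `n_perturbed_blocks` perturbed
#' blocks) without synthesizing marker/COP signals: errors are drawn
#' directly from the subject's landing distribution, with ARD-dependent
#' inflation on shifted targets. This is the fast path used for cohort-level
#' statistics; [simulate_trial()] is the signal-level path.
#'
#' @param subject one row of a [make_cohort()] table.
#' @param params a [protocol_params()] object; its `preferred_step_length`
#'   is overridden by the subject's.
#' @param seed integer seed.
#' @return a `step_scores` data.frame (see [score_trial()]) with columns
#'   `block`, `index`, `foot`, `condition`, `direction`, `ard`, `raw_error`
#'   (m) and `normalized_error` (% of L); attribute `L`.
#' @export
simulate_subject_scores <- function(subject, params = protocol_params(),
                                    seed) {
  L <- subject$preferred_step_length
  p <- params
  p$preferred_step_length <- L
  seeds <- derive_seeds(seed, 2L)
  session <- generate_session(p, seed = seeds[1])
  rows <- list()
  with_seed(seeds[2], {
    for (bi in seq_along(session)) {
      b <- session[[bi]]
      shifted <- !is.na(b$shift_direction)
      kap <- rep(1, nrow(b))
      kap[shifted] <- kappa_ard(b$shift_ard[shifted], subject)
      e <- stats::rnorm(nrow(b), subject$error_bias * L,
                        subject$sigma * kap * L)
      rows[[bi]] <- data.frame(
        block = bi,
        block_kind = attr(b, "kind"),
        index = b$index,
        foot = b$foot,
        condition = ifelse(shifted,
                           paste0(b$shift_direction, "_",
                                  format(b$shift_ard)),
                           "unperturbed"),
        direction = b$shift_direction,
        ard = b$shift_ard,
        raw_error = e,
        normalized_error = 100 * e / L,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "L") <- L
  class(out) <- c("step_scores", "data.frame")
  out
}
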