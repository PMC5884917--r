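test_that("foot center is the centroid of the marker triangle", {
  # three markers: center of the three segment midpoints = marker centroid
  mk <- data.frame(time = c(0, 0.01))
  pts <- list(toe = c(0, 0, 0), mall = c(0.2, 0, 0), heel = c(0.1, 0.05, 0))
  for (m in names(pts)) {
    mk[[paste0("left_", m, "_ap")]] <- pts[[m]][1]
    mk[[paste0("left_", m, "_ml")]] <- pts[[m]][2]
    mk[[paste0("left_", m, "_z")]] <- pts[[m]][3]
  }
  fc <- foot_center_at(mk, 0.005, "left")
  expect_equal(unname(fc), c(0.1, 0.05 / 3, 0), tolerance = 1e-9)

  # coincident markers collapse to the point
  mk2 <- mk
  for (cl in setdiff(names(mk2), "time")) {
    mk2[[cl]] <- if (grepl("_ap$", cl)) 0.3 else if (grepl("_ml$", cl)) -0.1 else 0.02
  }
  expect_equal(unname(foot_center_at(mk2, 0, "left")), c(0.3, -0.1, 0.02))

  # translation equivariance
  mk3 <- mk
  for (cl in grep("_ap$", names(mk3), value = TRUE)) mk3[[cl]] <- mk3[[cl]] + 1.5
  fc3 <- foot_center_at(mk3, 0.005, "left")
  expect_equal(fc3[["ap"]], fc[["ap"]] + 1.5)

  expect_error(foot_center_at(mk, 10, "left"), "outside the recording")
})

test_that("step error is the signed AP foot-target distance", {
  tc <- c(ap = 1.0, ml = 0.1)
  expect_equal(step_error(c(ap = 1.005), tc), 0.005)  # anterior = overshoot
  expect_equal(step_error(c(ap = 1.0), tc), 0)
  expect_equal(step_error(c(ap = 0.990), tc), -0.010) # posterior = undershoot
})

test_that("condition summaries implement the population-SD variability", {
  # {10, 20, 30} mm at L = 0.5 m: population SD = sqrt(200/3) mm
  cs <- condition_summary(c(0.010, 0.020, 0.030), 0.5)
  expect_equal(cs[["variability"]], 100 * sqrt(200 / 3) / 500,
               tolerance = 1e-9)
  expect_equal(cs[["mean_error"]], 100 * 0.020 / 0.5)
  expect_equal(cs[["k"]], 3)

  # zero spread and singleton
  expect_equal(condition_summary(rep(0.007, 5), 0.5)[["variability"]], 0)
  expect_equal(condition_summary(0.012, 0.5)[["variability"]], 0)
  expect_equal(condition_summary(rep(0.007, 5), 0.5)[["mean_error"]],
               100 * 0.007 / 0.5)

  expect_error(condition_summary(numeric(0), 0.5), "at least one")
  expect_error(condition_summary(c(0.01), -1), "positive")
})

test_that("variability is shift-invariant and the oracle agrees", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:40, 1)
    e <- rnorm(k, 0, 0.02)
    L <- runif(1, 0.3, 0.8)
    cs <- condition_summary(e, L)
    expect_equal(cs[["variability"]], oracle_variability(e, L),
                 tolerance = 1e-10)
    cs2 <- condition_summary(e + 0.013, L)
    expect_equal(cs2[["variability"]], cs[["variability"]], tolerance = 1e-9)
    expect_equal(cs2[["mean_error"]] - cs[["mean_error"]], 100 * 0.013 / L,
                 tolerance = 1e-9)
  }
})

test_that("pooling over ARD is the unweighted four-condition mean", {
  df <- data.frame(ard = c(0.8, 1.0, 1.3, 2.0),
                   mean_error = c(1, 2, 3, 4),
                   variability = c(4, 4, 4, 4))
  pooled <- pool_over_ard(df)
  expect_equal(pooled[["mean_error"]], 2.5)
  expect_equal(pooled[["variability"]], 4)
  expect_error(pool_over_ard(df[-2, ]), "missing ARD condition")

  set.seed(9)
  for (i in 1:20) {
    df$mean_error <- rnorm(4); df$variability <- abs(rnorm(4))
    pooled <- pool_over_ard(df)
    expect_equal(pooled[["mean_error"]], mean(df$mean_error))
    expect_equal(pooled[["variability"]], mean(df$variability))
  }
})

test_that("target centers at midstance match the simulator log exactly", {
  p <- default_params()
  b <- generate_perturbed_block(p, seed = 2)
  subj <- test_subject(sigma = 0.02)
  tr <- simulate_trial(subj, b, p, seed = 6)
  steps <- tr$truth$steps
  lg <- tr$target_log
  tgt <- steps[!is.na(steps$target_index), ]
  for (i in seq(1, nrow(tgt), by = 11)) {
    row <- tgt[i, ]
    ti <- row$target_index
    tc <- target_center_at_midstance(b[ti, ], row$midstance, p,
                                     lg$appearance_time[ti],
                                     lg$shift_onset[ti])
    # truth: landing minus error, advected to midstance by the belt
    want <- (row$landing_ap - row$true_error) -
      p$belt_speed * (row$midstance - row$strike)
    expect_equal(tc[["ap"]], want, tolerance = 1e-9)
  }
  # before the shift onset the nominal center is used
  si <- which(!is.na(lg$shift_onset))[1]
  before <- target_center_at_midstance(b[si, ], lg$shift_onset[si] - 1e-4, p,
                                       lg$appearance_time[si],
                                       lg$shift_onset[si])
  after <- target_center_at_midstance(b[si, ], lg$shift_onset[si], p,
                                      lg$appearance_time[si],
                                      lg$shift_onset[si])
  jump <- after[["ap"]] - before[["ap"]] +
    p$belt_speed * 1e-4
  expect_equal(jump, b$displaced_ap_center[si] - b$nominal_ap_center[si],
               tolerance = 1e-7)
})

test_that("noiseless end-to-end scoring reproduces true errors under 0.5 mm", {
  p <- default_params()
  for (blk in list(generate_unperturbed_block(p),
                   generate_perturbed_block(p, seed = 5))) {
    tr <- simulate_trial(test_subject(sigma = 0.03, bias = -0.01), blk, p,
                         seed = 4)
    sc <- quiet_score(tr)
    truth <- tr$truth$steps
    want <- truth$true_error[match(sc$index, truth$target_index)]
    expect_equal(nrow(sc), nrow(blk))
    expect_lt(max(abs(sc$raw_error - want)), 5e-4)
    expect_equal(sc$normalized_error, 100 * sc$raw_error / 0.5)
  }
})

test_that("subject summaries pool forward ARDs and exclude backward shifts", {
  p <- small_params()
  subj <- test_subject(sigma = 0.03, bias = 0.01)
  sc <- simulate_subject_scores(
    list(preferred_step_length = 0.5, error_bias = 0.01, sigma = 0.03,
         kappa_gain = 0.5, kappa_knee = 1.5),
    default_params(), seed = 31
  )
  ss <- subject_summary(sc)
  # pooled values are the unweighted means of the four forward ARD columns
  expect_equal(ss$perturbed_error,
               mean(c(ss$error_ard80, ss$error_ard100, ss$error_ard130,
                      ss$error_ard200)))
  expect_equal(ss$perturbed_variability,
               mean(c(ss$variability_ard80, ss$variability_ard100,
                      ss$variability_ard130, ss$variability_ard200)))
  # counts: 59 unperturbed-block steps; 8 x 3 blocks per forward ARD
  expect_equal(ss$k_unperturbed, 59)
  expect_equal(ss$k_ard80, 24)
  # backward steps exist in the scores but are in no summary count
  expect_equal(sum(sc$direction == "backward", na.rm = TRUE), 24)
  summed <- ss$k_unperturbed + ss$k_ard80 + ss$k_ard100 + ss$k_ard130 +
    ss$k_ard200
  expect_lt(summed, nrow(sc))

  # unperturbed summary uses only unperturbed blocks
  manual <- condition_summary(
    sc$raw_error[sc$block_kind == "unperturbed"], 0.5)
  expect_equal(ss$unperturbed_error, manual[["mean_error"]])
  expect_equal(ss$unperturbed_variability, manual[["variability"]])
})
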