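# Prediction errors, predictive checks, bootstrap and shrinkage.

test_that("prediction errors follow their defining formulas", {
  expect_equal(prediction_error(1.0, 1.0), 0)
  expect_equal(prediction_error(1.1, 1.0), 10)
  expect_equal(prediction_error(0.9, 1.0), -10)
  expect_error(prediction_error(1, 0), "DV > 0")
  # per-subject parameter version: (0.676 - 0.60)/0.60 * 100 = 12.67
  expect_equal(parameter_prediction_error(0.676, 0.60), 12.667,
               tolerance = 1e-4)
  expect_equal(parameter_prediction_error(2, 2), 0)
  expect_error(parameter_prediction_error(1, 0), "positive")
})

test_that("mean prediction error aggregates with bootstrap CIs", {
  expect_equal(mean_prediction_error(c(10, -10), seed = 1)$mpe, 0)
  z <- mean_prediction_error(rep(0, 20), seed = 1)
  expect_equal(z$ci, c(0, 0))
  expect_error(mean_prediction_error(numeric(0)), "no prediction errors")
  x <- rnorm(200, 1, 5)
  m <- mean_prediction_error(x, n_boot = 2000, seed = 2)
  expect_equal(m$mpe, mean(x))
  expect_lt(m$ci[1], m$mpe)
  expect_gt(m$ci[2], m$mpe)
})

test_that("self-prediction of a noise-free typical cohort has zero bias", {
  des <- trial_design(6, n_cycles = 2)
  dat <- simulate_trial(des, tab1_theta, omega_matrix(), sigma_model(1e-12),
                        seed = 31)
  dat <- dat[!(dat$EVID == 0 & dat$TIME == 0), ]
  subs <- tdm1popk:::.prep_subjects(dat)
  pred <- tdm1popk:::cpp_ipred(subs, as.numeric(tab1_theta),
                               matrix(0, length(subs), 4))
  pe <- unlist(lapply(seq_along(subs), function(i)
    prediction_error(drop(pred[[i]]), subs[[i]]$y)))
  expect_equal(max(abs(pe)), 0, tolerance = 1e-6)
})

test_that("external-validation machinery is unbiased on self-simulated data", {
  # a synthetic validation cohort simulated from the model itself plays
  # the role of an external study: MPE should be small with a CI
  # covering 0
  dat <- small_trial(60, 2, seed = 33)
  rep <- external_validation(tab1_theta, tab1_omega, tab1_sigma, dat,
                             n_boot = 500, seed = 34)
  # per-subject CL/Vc errors: small bias, CI covering 0 (the per-record
  # concentration MPE is right-skewed by construction - the reciprocal of
  # a 31.6%-CV observation - so only its median is near zero)
  expect_lt(abs(rep$cl$mpe), 10)
  expect_lt(abs(rep$vc$mpe), 10)
  expect_true(rep$cl$ci[1] < 0 && 0 < rep$cl$ci[2])
  expect_true(rep$vc$ci[1] < 0 && 0 < rep$vc$ci[2])
  expect_lt(abs(median(rep$conc$pe)), 10)
})

test_that("VPC is calibrated under the generating model", {
  dat <- small_trial(60, 2, seed = 35)
  vpc <- visual_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat,
                                 n_rep = 150, mqc = 0.05, seed = 36)
  # observed median inside the simulated median band in >= 90% of bins
  ok <- vpc$observed[, "p50"] >= vpc$sim_lower[, "p50"] &
        vpc$observed[, "p50"] <= vpc$sim_upper[, "p50"]
  expect_gte(mean(ok), 0.9)
  expect_true(all(vpc$sim_lower <= vpc$sim_upper))
  # a single replicate collapses the bands onto that replicate
  v1 <- visual_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat,
                                n_rep = 1, mqc = 0.05, seed = 37)
  expect_equal(v1$sim_lower, v1$sim_median)
  expect_equal(v1$sim_upper, v1$sim_median)
  # doubling all doses in the simulation shifts the bands up, making the
  # miscalibration visible while the observations stay put
  dat2 <- dat
  dat2$AMT <- dat2$AMT * 2
  v2 <- visual_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat2,
                                n_rep = 60, mqc = 0.05, seed = 38)
  expect_gt(median(v2$sim_median[, "p50"] / vpc$sim_median[, "p50"],
                   na.rm = TRUE), 1.8)
  expect_equal(v2$observed, vpc$observed)
})

test_that("NPC coverage matches nominal prediction intervals", {
  dat <- small_trial(80, 2, seed = 39)
  npc <- numerical_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat,
                                    n_rep = 300,
                                    pi_levels = c(0.5, 0.9),
                                    mqc = 0.05, seed = 40)
  out90 <- npc$observed_outside[npc$pi_level == 0.9]
  expect_lt(abs(out90 - 0.10), 0.03)
  out50 <- npc$observed_outside[npc$pi_level == 0.5]
  expect_lt(abs(out50 - 0.50), 0.06)
  # degenerate interval levels
  npc0 <- numerical_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat,
                                     n_rep = 40, pi_levels = 1e-9,
                                     mqc = 0.05, seed = 41)
  expect_gt(npc0$observed_outside, 0.97)
  npc1 <- numerical_predictive_check(tab1_theta, tab1_omega, tab1_sigma, dat,
                                     n_rep = 40, pi_levels = 1 - 1e-9,
                                     mqc = 0.05, seed = 42)
  expect_lt(npc1$observed_outside, 0.05)
})

test_that("shrinkage formulas behave at their limits and with design density", {
  # all EBEs at zero -> 100% eta-shrinkage
  fit0 <- structure(list(
    omega = omega_matrix(cl = 0.2, vc = 0.1),
    etas = matrix(0, 10, 4), sigma = sigma_model(0.3),
    theta = tab1_theta,
    subjects = tdm1popk:::.prep_subjects(small_trial(10, 1, seed = 43))),
    class = "popk_fit")
  s0 <- shrinkage(fit0)
  expect_equal(unname(s0$eta[1:2]), c(100, 100))
  expect_true(all(is.na(s0$eta[3:4])))
  # SD(eta-hat) equal to omega -> 0%
  set.seed(44)
  e <- rnorm(500, 0, 0.2); e <- (e - mean(e)) / sd(e) * 0.2
  fit1 <- fit0
  fit1$etas <- cbind(e, 0, 0, 0)
  fit1$omega <- omega_matrix(cl = 0.2)
  fit1$subjects <- tdm1popk:::.prep_subjects(small_trial(500, 1, seed = 45))
  expect_equal(unname(shrinkage(fit1)$eta[1]), 0, tolerance = 1e-9)
})

test_that("eta-shrinkage increases as the design gets sparser", {
  # same population, rich vs sparse sampling; EBEs from the known model
  shr_for <- function(schedule) {
    des <- trial_design(40, n_cycles = 2, schedule = schedule)
    dat <- simulate_trial(des, tab1_theta, tab1_omega, tab1_sigma, seed = 46)
    dat <- apply_mqc_censoring(dat, 0.05)
    subs <- tdm1popk:::.prep_subjects(dat)
    etas <- t(vapply(subs, function(s)
      drop(tdm1popk:::cpp_map_eta(s, as.numeric(tab1_theta),
                                  unclass(tab1_omega), 0.3156,
                                  rep(0, 4))$eta), numeric(4)))
    100 * (1 - apply(etas, 2, sd) / sqrt(diag(tab1_omega)))
  }
  rich <- shr_for("rich")
  sparse <- shr_for("sparse")
  expect_gt(sparse[1], rich[1])
  expect_gt(sparse[2], rich[2])
})

test_that("percent of IIV explained matches the published arithmetic", {
  expect_equal(percent_iiv_explained(25.6, 19.1), 44.33, tolerance = 0.01)
  expect_equal(percent_iiv_explained(17.5, 11.66), 55.61, tolerance = 0.01)
  expect_equal(percent_iiv_explained(20, 20), 0)
  expect_warning(out <- percent_iiv_explained(10, 12), "exceeds")
  expect_lt(out, 0)
})

test_that("the bootstrap recovers generating values and scales with n", {
  dat <- small_trial(24, 1, seed = 47)
  init <- list(theta = tab1_theta, omega = tab1_omega, sigma = tab1_sigma)
  bs <- bootstrap_fit(dat, init, n_boot = 30,
                      estimate = list(theta = 1:2, omega = FALSE,
                                      sigma = FALSE), seed = 48)
  expect_equal(bs$n_nonconverged, 0)
  cl <- bs$summary[bs$summary$parameter == "CL", ]
  vc <- bs$summary[bs$summary$parameter == "Vc", ]
  expect_lt(abs(cl$median / 0.676 - 1), 0.10)
  expect_lt(abs(vc$median / 3.127 - 1), 0.10)
  expect_true(cl$lower < cl$median && cl$median < cl$upper)
  # a single-subject dataset has only one possible resample: all
  # replicates coincide and the CI collapses
  one <- dat[dat$ID == 1, ]
  b1 <- bootstrap_fit(one, init, n_boot = 5,
                      estimate = list(theta = 1:2, omega = FALSE,
                                      sigma = FALSE), seed = 49)
  expect_equal(b1$summary$lower, b1$summary$upper, tolerance = 1e-6)
  # quadrupling the subject count shrinks the CI (root-n, directionally)
  big <- small_trial(96, 1, seed = 50)
  bs4 <- bootstrap_fit(big, init, n_boot = 30,
                       estimate = list(theta = 1:2, omega = FALSE,
                                       sigma = FALSE), seed = 51)
  cl4 <- bs4$summary[bs4$summary$parameter == "CL", ]
  expect_lt(cl4$upper - cl4$lower, cl$upper - cl$lower)
})
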