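# Conditional estimation: MAP individuals, the population objective,
# fitting, and stepwise covariate selection.

test_that("MAP individual estimation honors its limits", {
  # no observations: prior mode
  d0 <- one_subject_data(numeric(0), numeric(0))
  m0 <- suppressWarnings(map_individual(tab1_theta, tab1_omega, tab1_sigma, d0))
  expect_equal(unname(m0$eta), rep(0, 4))
  # noise-free rich data at a known eta is recovered almost exactly
  eta_true <- c(0.25, -0.15, 0.4, -0.3)
  ind <- individual_parameters(tab1_theta, reference_covariates(), eta_true)
  tt <- c(0.0208, 0.25, 1, 3, 7, 14, 21, 22, 24, 28, 35, 42)
  doses <- dose_events(c(0, 21), 252, 0.0208)
  y <- concentration(ind, doses, tt)
  dd <- one_subject_data(numeric(0), numeric(0))
  dd <- rbind(dd[0, ],
              data.frame(ID = 1L, TIME = c(0, 21), EVID = 1L, AMT = 252,
                         DUR = 0.0208, DV = NA, MDV = 1L, WT = 70, ECD = 25,
                         ALBU = 41, TMBD = 9, TBL = 0, AST = 27),
              data.frame(ID = 1L, TIME = tt, EVID = 0L, AMT = NA, DUR = NA,
                         DV = y, MDV = 0L, WT = 70, ECD = 25, ALBU = 41,
                         TMBD = 9, TBL = 0, AST = 27))
  dd <- dd[order(dd$TIME, -dd$EVID), ]
  m <- map_individual(tab1_theta, tab1_omega, sigma_model(1e-5), dd)
  expect_equal(unname(m$eta), eta_true, tolerance = 1e-3)
  # one observation under a nearly flat prior: IPRED approaches DV as the
  # residual CV shrinks (at finite CV the proportional-error mode sits a
  # factor ~(1 + cv^2) below the observation, because smaller predictions
  # buy a smaller residual variance)
  d1 <- one_subject_data(3, 25)
  big <- omega_matrix(cl = 5, vc = 5, q = 1e-6, vp = 1e-6)
  m1 <- map_individual(tab1_theta, big, sigma_model(0.05), d1)
  ind1 <- individual_parameters(tab1_theta, reference_covariates(), m1$eta)
  ipred <- concentration(ind1, dose_events(0, 252, 0.0208), 3)
  expect_equal(ipred, 25, tolerance = 0.01)
  m3 <- map_individual(tab1_theta, big, tab1_sigma, d1)
  ind3 <- individual_parameters(tab1_theta, reference_covariates(), m3$eta)
  ipred3 <- concentration(ind3, dose_events(0, 252, 0.0208), 3)
  expect_equal(ipred3, 25 / (1 + 0.3156^2), tolerance = 0.03)
  # singular active block errors
  sing <- omega_matrix(cl = 0.2, vc = 0.2, cov_cl_vc = 0.04)
  expect_error(map_individual(tab1_theta, sing, tab1_sigma, d1), "singular")
})

test_that("the conditional objective matches adaptive quadrature on 1-eta toys", {
  doses <- dose_events(0, 252, 0.0208)
  # toy noise levels are moderate by construction: the conditional
  # approximations carry a known O(cv^2) skew error, so the oracle check
  # verifies the implementation where the approximation itself is sound
  cases <- list(
    list(times = c(0.25, 2, 6, 14), om = 0.25, sig = 0.15, seed = 61),
    list(times = c(1, 4, 10), om = 0.4, sig = 0.10, seed = 62),
    # one-compartment degenerate model, single observation
    list(times = 5, om = 0.3, sig = 0.05, seed = 63, onecmt = TRUE))
  for (cs in cases) {
    set.seed(cs$seed)
    theta <- tab1_theta
    if (isTRUE(cs$onecmt)) theta[3] <- -30   # Q ~ 0
    ind <- individual_parameters(theta, eta = c(rnorm(1, 0, cs$om), 0, 0, 0))
    y <- concentration(ind, doses, cs$times) *
      (1 + rnorm(length(cs$times), 0, cs$sig))
    dat <- one_subject_data(cs$times, y)
    om <- omega_matrix(cl = cs$om)
    ofv <- as.numeric(foce_objective(theta, om, cs$sig, dat))
    oracle <- quadrature_m2ll(theta, cs$om, cs$sig, doses, cs$times, y)
    expect_lt(abs(ofv - oracle) / abs(oracle), 0.005)
    agq <- as.numeric(foce_objective(theta, om, cs$sig, dat, method = "agq"))
    expect_lt(abs(agq - oracle) / abs(oracle), 0.005)
  }
})

test_that("the objective is additive over subjects and rewards true covariates", {
  dat <- small_trial(12, 2, seed = 64)
  ofv1 <- as.numeric(foce_objective(tab1_theta, tab1_omega, tab1_sigma, dat))
  dup <- dat
  dup$ID <- dup$ID + 1000L
  both <- rbind(dat, dup)
  ofv2 <- as.numeric(foce_objective(tab1_theta, tab1_omega, tab1_sigma, both))
  expect_equal(ofv2, 2 * ofv1, tolerance = 1e-9)
  # removing the true weight effect from the model raises the OFV
  th_nowt <- tab1_theta
  th_nowt[5] <- th_nowt[6] <- 0
  ofv_nowt <- as.numeric(foce_objective(th_nowt, tab1_omega, tab1_sigma, dat))
  expect_gt(ofv_nowt, ofv1)
})

test_that("scaling concentrations and volumes leaves OFV differences unchanged", {
  dat <- small_trial(10, 2, seed = 65)
  csc <- 3.7
  dat_sc <- dat
  dat_sc$DV <- dat_sc$DV * csc
  shift <- function(th) {
    th[1:4] <- as.numeric(th)[1:4] - log(csc)
    th
  }
  thA <- tab1_theta
  thB <- tab1_theta; thB[1] <- thB[1] + 0.1
  d_orig <- as.numeric(foce_objective(thA, tab1_omega, tab1_sigma, dat)) -
    as.numeric(foce_objective(thB, tab1_omega, tab1_sigma, dat))
  d_sc <- as.numeric(foce_objective(shift(thA), tab1_omega, tab1_sigma, dat_sc)) -
    as.numeric(foce_objective(shift(thB), tab1_omega, tab1_sigma, dat_sc))
  expect_equal(d_sc, d_orig, tolerance = 1e-6)
})

test_that("population fitting recovers generating parameters at small scale", {
  dat <- small_trial(50, 2, seed = 66)
  th0 <- as.numeric(tab1_theta)
  th0[1] <- th0[1] + log(1.2)
  th0[2] <- th0[2] + log(0.85)
  fit <- fit_population(dat, list(theta = as_theta_vector(th0),
                                  omega = tab1_omega, sigma = tab1_sigma))
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$theta[1]) / 0.676 - 1), 0.05)
  expect_lt(abs(exp(fit$theta[2]) / 3.127 - 1), 0.05)
  expect_lt(abs(fit$sigma$cv / 0.3156 - 1), 0.10)
  # refitting from the optimum is a fixed point up to the conditional-mode
  # reproducibility floor (well under one OFV unit on ~19,000)
  fit2 <- fit_population(dat, list(theta = fit$theta, omega = fit$omega,
                                   sigma = fit$sigma))
  expect_lt(abs(fit2$ofv - fit$ofv), 0.5)
  expect_lt(max(abs(as.numeric(fit2$theta)[1:4] -
                    as.numeric(fit$theta)[1:4])), 0.01)
})

test_that("fixed-effect-only fits reach the optimizer tolerance noise-free", {
  des <- trial_design(8, n_cycles = 2)
  dat <- simulate_trial(des, tab1_theta, omega_matrix(), sigma_model(1e-12),
                        seed = 67)
  dat <- apply_mqc_censoring(dat, 0.05)
  th0 <- as.numeric(tab1_theta) + c(0.3, -0.2, 0.2, -0.2, rep(0, 7))
  # residual CV pinned small: the log-variance term otherwise shifts the
  # noise-free optimum by O(cv^2)
  fit <- fit_population(dat, list(theta = as_theta_vector(th0),
                                  omega = omega_matrix(),
                                  sigma = sigma_model(1e-4)),
                        estimate = list(theta = 1:4, sigma = FALSE),
                        control = list(rel_tol = 1e-10, grad_step = 1e-5))
  expect_equal(as.numeric(fit$theta)[1:4], as.numeric(tab1_theta)[1:4],
               tolerance = 2e-3)
})

test_that("likelihood-ratio significance uses the chi-square upper tail", {
  expect_equal(lrt_significance(6.635, 1), 0.01, tolerance = 1e-3)
  expect_equal(lrt_significance(10.828, 1), 0.001, tolerance = 1e-3)
  expect_equal(lrt_significance(0, 1), 1)
  expect_error(lrt_significance(-1, 1))
})

test_that("stepwise selection keeps the generating covariate and drops the rest", {
  th_gen <- as_theta_vector(c(as.numeric(tab1_theta)[1:4], 0, 0.49,
                              rep(0, 5)))
  des <- trial_design(80, n_cycles = 2)
  dat <- simulate_trial(des, th_gen, tab1_omega, tab1_sigma, seed = 68)
  dat <- apply_mqc_censoring(dat, 0.05)
  cands <- list(covariate_candidate("CL", "WT"),
                covariate_candidate("CL", "ALBU"))
  init <- list(theta = as_theta_vector(c(as.numeric(tab1_theta)[1:4],
                                         rep(0, 7))),
               omega = tab1_omega, sigma = tab1_sigma)
  sel <- stepwise_selection(dat, cands, init)
  kept <- vapply(sel$included, function(c) c$covariate, "")
  expect_true("WT" %in% kept)
  expect_false("ALBU" %in% kept)
  expect_equal(sel$fit$theta[["theta6"]], 0.49, tolerance = 0.35)
  expect_true(all(c("base", "forward") %in% sel$trace$phase))
  # empty candidate list returns the base model
  sel0 <- stepwise_selection(dat, list(), init)
  expect_equal(length(sel0$included), 0)
  expect_equal(sel0$trace$phase, "base")
  # a zero forward threshold admits every candidate
  sel_all <- stepwise_selection(dat, cands, init, forward_delta = 0,
                                backward_delta = -1)
  expect_equal(length(sel_all$included), 2)
})

test_that("covariate candidates map onto the model's functional forms", {
  expect_equal(covariate_candidate("CL", "WT")$theta_index, 6L)
  expect_equal(covariate_candidate("Vc", "WT")$theta_index, 5L)
  expect_equal(covariate_candidate("CL", "TBL")$form, "linear")
  expect_equal(covariate_candidate("CL", "AST")$form, "power")
  expect_error(covariate_candidate("Vc", "ALBU"), "body weight")
  expect_error(covariate_candidate("CL", "XYZ"), "unknown")
})
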