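# Structural model, covariate model and exposure metrics.

test_that("typical clearance reproduces the published covariate model", {
  expect_equal(typical_clearance(tab1_theta), 0.676, tolerance = 0.005)
  expect_equal(typical_clearance(tab1_theta, covariate_vector(WT = 49)),
               0.567, tolerance = 0.005)
  # covariate terms vanish when their coefficients are zero
  th0 <- as_theta_vector(c(as.numeric(tab1_theta)[1:5], rep(0, 6)))
  expect_equal(typical_clearance(th0, covariate_vector(WT = 55, ECD = 100,
                                                       ALBU = 35, TMBD = 2,
                                                       TBL = 30, AST = 60)),
               exp(tab1_theta[["theta1"]]))
  expect_error(typical_clearance(tab1_theta, covariate_vector(ALBU = -1)),
               "positive")
})

test_that("typical central volume reproduces the published weight model", {
  expect_equal(typical_central_volume(tab1_theta), 3.127, tolerance = 0.005)
  expect_equal(typical_central_volume(tab1_theta, covariate_vector(WT = 98)),
               3.821, tolerance = 0.005)
  th0 <- as_theta_vector(c(as.numeric(tab1_theta)[1:4], rep(0, 7)))
  expect_equal(typical_central_volume(th0, covariate_vector(WT = 123)),
               exp(tab1_theta[["theta2"]]))
})

test_that("individual parameters combine typical values and etas", {
  ind0 <- individual_parameters(tab1_theta)
  expect_equal(ind0$CL, typical_clearance(tab1_theta))
  expect_equal(ind0$Vc, typical_central_volume(tab1_theta))
  expect_equal(ind0$Q, 1.534, tolerance = 1e-12)
  expect_equal(ind0$Vp, 0.66, tolerance = 1e-12)
  # eta_CL = log 2 doubles clearance: 0.676 * 2 = 1.352
  ind2 <- individual_parameters(tab1_theta, eta = c(log(2), 0, 0, 0))
  expect_equal(ind2$CL, 1.352, tolerance = 1e-6)
})

test_that("micro constants follow the standard reparameterization", {
  k <- micro_constants(individual_parameters(tab1_theta))
  expect_equal(unname(k[["k10"]]), 0.676 / 3.127, tolerance = 1e-12)
  k1 <- micro_constants(list(CL = 2, Vc = 2, Q = 0.5, Vp = 0.25))
  expect_equal(unname(k1), c(1, 0.25, 2))
  k0 <- micro_constants(list(CL = 1, Vc = 1, Q = 0, Vp = 1))
  expect_equal(unname(k0[c("k12", "k21")]), c(0, 0))
})

test_that("terminal half-life matches the published value and a slope oracle", {
  ind <- individual_parameters(tab1_theta)
  expect_equal(terminal_half_life(ind), 3.94, tolerance = 0.01 / 3.94)
  # one-compartment limit
  ind1 <- list(CL = 0.7, Vc = 3, Q = 0, Vp = 1)
  expect_equal(terminal_half_life(ind1), log(2) * 3 / 0.7)
  # numeric slope of log-concentration long after a bolus
  set.seed(42)
  for (i in 1:5) {
    ind_r <- list(CL = runif(1, 0.3, 2), Vc = runif(1, 2, 6),
                  Q = runif(1, 0.5, 3), Vp = runif(1, 0.3, 3))
    t12 <- terminal_half_life(ind_r)
    tt <- c(20, 21) * t12
    cc <- concentration(ind_r, dose_events(0, 100, 0), tt)
    slope <- (log(cc[2]) - log(cc[1])) / (tt[2] - tt[1])
    expect_equal(log(2) / -slope, t12, tolerance = 1e-6)
  }
})

test_that("closed-form concentration has the right limits and superposes", {
  ind <- individual_parameters(tab1_theta)
  # bolus initial condition: dose / Vc
  c0 <- concentration(ind, dose_events(0, 252, 0), 1e-9)
  expect_equal(c0, 252 / 3.127, tolerance = 1e-6)
  # times before the first dose give zero
  expect_equal(concentration(ind, dose_events(2, 252, 0.02), c(0, 1, 1.99)),
               rep(0, 3))
  # superposition: two doses = sum of shifted single-dose curves
  tt <- seq(0, 42, by = 0.5)
  two <- concentration(ind, dose_events(c(0, 21), c(252, 252), 0.0208), tt)
  one <- concentration(ind, dose_events(0, 252, 0.0208), tt)
  one_shift <- concentration(ind, dose_events(21, 252, 0.0208), tt)
  expect_equal(two, one + one_shift, tolerance = 1e-12)
})

test_that("closed-form kinetics agree with an ODE oracle to <0.1%", {
  skip_if_not_installed("deSolve")
  # piecewise integration with a constant infusion rate per segment, so
  # the stiff solver never steps across a rate discontinuity
  two_cmt_ode <- function(ind, doses, times) {
    k <- micro_constants(ind)
    rhs <- function(t, A, p) {
      list(c(p - (k[["k10"]] + k[["k12"]]) * A[1] + k[["k21"]] * A[2],
             k[["k12"]] * A[1] - k[["k21"]] * A[2]))
    }
    bounds <- sort(unique(c(0, doses$time, doses$time + doses$dur,
                            times, max(times))))
    A <- c(0, 0)
    sol <- cbind(time = 0, c1 = 0)
    for (i in seq_len(length(bounds) - 1)) {
      t0 <- bounds[i]; t1 <- bounds[i + 1]
      mid <- (t0 + t1) / 2
      rate <- sum(doses$amt / doses$dur *
                    (mid > doses$time & mid < doses$time + doses$dur))
      out <- deSolve::lsoda(A, c(t0, t1), rhs, rate,
                            rtol = 1e-11, atol = 1e-13)
      A <- unname(out[nrow(out), 2:3])
      sol <- rbind(sol, c(t1, A[1]))
    }
    approx(sol[, 1], sol[, 2] / ind$Vc, xout = times)$y
  }
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    ind <- list(CL = rlnorm(1, log(0.7), 0.4), Vc = rlnorm(1, log(3), 0.3),
                Q = rlnorm(1, log(1.5), 0.5), Vp = rlnorm(1, log(0.7), 0.4))
    # zero-order infusions only: the bolus limit is checked analytically
    # above, and a Dirac input has no natural ODE representation
    doses <- dose_events(c(0, 21), rep(rlnorm(1, log(250), 0.2), 2),
                         dur = sample(c(0.0208, 0.125, 0.5), 1))
    tt <- sort(runif(8, 0.01, 42))
    a <- concentration(ind, doses, tt)
    b <- two_cmt_ode(ind, doses, tt)
    rel <- abs(a - b) / pmax(abs(b), 1e-3 * max(b))
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 0.001)
})

test_that("steady-state exposure metrics obey dose/CL and linearity", {
  ind <- individual_parameters(tab1_theta)
  ex <- steady_state_exposure(ind, 252, 21)
  expect_equal(ex$auc, 252 / 0.676, tolerance = 1e-6)
  expect_gte(ex$cmax, ex$ctrough)
  expect_gt(ex$ctrough, 0)
  # numeric AUC over one interval at steady state equals dose/CL
  tt <- seq(0, 21, length.out = 20001)
  css <- tdm1popk:::.conc_ss(ind, 252, 21, 0.0208, tt)
  auc_num <- sum((css[-1] + css[-length(css)]) / 2) * diff(tt[1:2])
  expect_equal(auc_num, ex$auc, tolerance = 1e-4)
  # doubling the dose doubles all three metrics
  ex2 <- steady_state_exposure(ind, 504, 21)
  expect_equal(c(ex2$auc, ex2$cmax, ex2$ctrough),
               2 * c(ex$auc, ex$cmax, ex$ctrough), tolerance = 1e-9)
  # tau -> infinity: trough vanishes, Cmax tends to the single-dose Cmax
  ex_inf <- steady_state_exposure(ind, 252, 2000)
  expect_lt(ex_inf$ctrough, 1e-10)
  single_cmax <- max(concentration(ind, dose_events(0, 252, 0.0208),
                                   seq(0, 2, length.out = 4001)))
  expect_equal(ex_inf$cmax, single_cmax, tolerance = 1e-3)
  # steady-state profile consistent with long-run superposition
  css20 <- concentration(ind, dose_events(21 * (0:19), 252, 0.0208),
                         21 * 19 + c(0.5, 3, 10, 21))
  css_exact <- tdm1popk:::.conc_ss(ind, 252, 21, 0.0208, c(0.5, 3, 10, 21))
  expect_equal(css20, css_exact, tolerance = 1e-6)
})

test_that("clearance is monotone in each covariate with published signs", {
  up <- c(WT = 1, ECD = 1, ALBU = -1, TMBD = 1, TBL = -1, AST = 1)
  ref <- reference_covariates()
  for (nm in names(up)) {
    lo <- as.list(unclass(ref)); hi <- lo
    lo[[nm]] <- if (nm == "TBL") 0 else ref[[nm]] * 0.8
    hi[[nm]] <- if (nm == "TBL") 20 else ref[[nm]] * 1.2
    cl_lo <- typical_clearance(tab1_theta, do.call(covariate_vector, lo))
    cl_hi <- typical_clearance(tab1_theta, do.call(covariate_vector, hi))
    expect_true(sign(cl_hi - cl_lo) == up[[nm]], label = nm)
  }
})
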