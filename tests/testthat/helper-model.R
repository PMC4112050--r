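# Shared fixtures: published parameter set and small simulated trials.

tab1_theta <- reference_theta()
tab1_omega <- reference_omega()
tab1_sigma <- reference_sigma()

# a small rich-design trial used by several estimation/diagnostic tests
small_trial <- function(n = 30, n_cycles = 2, seed = 101, mqc = 0.05, ...) {
  des <- trial_design(n, n_cycles = n_cycles, mqc = mqc, ...)
  dat <- simulate_trial(des, tab1_theta, tab1_omega, tab1_sigma, seed = seed)
  apply_mqc_censoring(dat, mqc)
}

# one-subject dataset with arbitrary observations (for toy likelihoods)
one_subject_data <- function(times, dv, dose = 252, dur = 0.0208,
                             cov = reference_covariates()) {
  data.frame(ID = 1L, TIME = c(0, times), EVID = c(1L, rep(0L, length(times))),
             AMT = c(dose, rep(NA, length(times))),
             DUR = c(dur, rep(NA, length(times))),
             DV = c(NA, dv), MDV = c(1L, rep(0L, length(times))),
             WT = cov[["WT"]], ECD = cov[["ECD"]], ALBU = cov[["ALBU"]],
             TMBD = cov[["TMBD"]], TBL = cov[["TBL"]], AST = cov[["AST"]])
}

# exact -2 log marginal likelihood of a one-random-effect toy model by
# adaptive quadrature (oracle for the conditional-estimation objective)
quadrature_m2ll <- function(theta, omega_sd, sigma_cv, doses, times, dv,
                            eta_dim = 1, cov = reference_covariates()) {
  integrand <- function(eta) {
    vapply(eta, function(e) {
      ev <- rep(0, 4); ev[eta_dim] <- e
      ind <- individual_parameters(theta, cov, ev)
      f <- concentration(ind, doses, times)
      exp(sum(dnorm(dv, f, sigma_cv * f, log = TRUE))) *
        dnorm(e, 0, omega_sd)
    }, 0)
  }
  L <- integrate(integrand, -8 * omega_sd, 8 * omega_sd,
                 rel.tol = 1e-10)$value
  -2 * log(L)
}
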