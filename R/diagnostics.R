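# Internal and external validation machinery: prediction errors,
# simulation-based predictive checks, bootstrap and shrinkage.

#' Per-record prediction error
#'
#' `Pe = (PRED - DV) / DV * 100`, in percent; positive values indicate
#' over-prediction.
#'
#' @param pred population predictions
#' @param dv observed concentrations (strictly positive)
#' @return prediction errors in percent
#' @export
prediction_error <- function(pred, dv) {
  if (any(dv <= 0)) stop("prediction error requires DV > 0")
  (pred - dv) / dv * 100
}

#' Mean prediction error with bootstrap confidence interval
#'
#' The arithmetic mean of the per-record (or per-subject) prediction
#' errors, with a nonparametric percentile-bootstrap 95% CI.
#'
#' @param pe prediction errors in percent (non-empty)
#' @param n_boot bootstrap resamples for the CI
#' @param conf confidence level
#' @param seed optional seed for the bootstrap resampling
#' @return list with `mpe`, `ci` (length 2) and `n`
#' @export
mean_prediction_error <- function(pe, n_boot = 1000, conf = 0.95,
                                  seed = NULL) {
  if (length(pe) == 0) stop("no prediction errors supplied")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(sample(pe, replace = TRUE)), 0)
  a <- (1 - conf) / 2
  list(mpe = mean(pe),
       ci = unname(quantile(boot, c(a, 1 - a))),
       n = length(pe))
}

#' Per-subject parameter prediction error
#'
#' `Pe_i = (pop_i - bayes_i) / bayes_i * 100`: the covariate-model
#' (population) parameter prediction for subject i relative to the
#' subject's empirical-Bayes estimate. Aggregate with
#' [mean_prediction_error()] over subjects.
#'
#' @param pop population (covariate-model) parameter values
#' @param bayes empirical-Bayes individual parameter values (> 0)
#' @return prediction errors in percent
#' @export
parameter_prediction_error <- function(pop, bayes) {
  if (any(bayes <= 0)) stop("Bayesian estimates must be strictly positive")
  (pop - bayes) / bayes * 100
}

#' External-validation statistics for a dataset
#'
#' Computes the concentration prediction errors (population predictions
#' at eta = 0 against the observations) and the per-subject CL and Vc
#' prediction errors (population vs empirical-Bayes estimates), each with
#' their mean and bootstrap 95% CI.
#'
#' @param theta,omega,sigma final model parameters (held fixed)
#' @param data validation PK dataset
#' @param n_boot bootstrap resamples for the CIs
#' @param seed optional seed
#' @return list of class `prediction_error_report` with elements `conc`,
#'   `cl`, `vc`, each a [mean_prediction_error()] result plus the raw
#'   errors
#' @export
external_validation <- function(theta, omega, sigma, data, n_boot = 1000,
                                seed = NULL) {
  subs <- .prep_subjects(data)
  th <- as.numeric(theta)
  om <- .as_omega(omega)
  cv <- .sigma_cv(sigma)
  pred <- cpp_ipred(subs, th, matrix(0, length(subs), 4))
  pe <- unlist(lapply(seq_along(subs), function(i)
    prediction_error(drop(pred[[i]]), subs[[i]]$y)))
  cl_pe <- vc_pe <- numeric(length(subs))
  for (i in seq_along(subs)) {
    eta <- drop(cpp_map_eta(subs[[i]], th, om, cv, rep(0, 4))$eta)
    logp_pop <- drop(subs[[i]]$D %*% th)
    cl_pe[i] <- parameter_prediction_error(exp(logp_pop[1]),
                                           exp(logp_pop[1] + eta[1]))
    vc_pe[i] <- parameter_prediction_error(exp(logp_pop[2]),
                                           exp(logp_pop[2] + eta[2]))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list(conc = c(mean_prediction_error(pe, n_boot), list(pe = pe)),
              cl = c(mean_prediction_error(cl_pe, n_boot), list(pe = cl_pe)),
              vc = c(mean_prediction_error(vc_pe, n_boot), list(pe = vc_pe)))
  structure(out, class = "prediction_error_report")
}

# simulate one replicate of the dataset design under the model (same
# doses, times and covariates), returning simulated DVs for observation
# rows; below-MQC simulated points are marked NA (omitted), mirroring the
# data-processing rule
.simulate_replicate <- function(subs, theta, omega, cv, mqc) {
  etas <- .rmvnorm0(length(subs), omega)
  f <- cpp_ipred(subs, as.numeric(theta), etas)
  lapply(seq_along(subs), function(i) {
    fi <- drop(f[[i]])
    dv <- fi * (1 + rnorm(length(fi), 0, cv))
    dv[dv <= 0] <- 1e-6
    if (!is.null(mqc)) dv[dv < mqc] <- NA_real_
    dv
  })
}

#' Visual predictive check
#'
#' Simulates the dataset's design (doses, sampling times, covariates)
#' `n_rep` times under the model, applies the same below-MQC omission rule
#' as the data, and compares observed percentiles per time bin with the
#' across-replicate distribution of the simulated percentiles.
#'
#' @param theta,omega,sigma model parameters
#' @param data PK dataset providing the design and the observations
#' @param n_rep number of simulation replicates (>= 100 recommended; 1 is
#'   allowed and collapses the bands onto that replicate)
#' @param bins breakpoints for time bins; defaults to the distinct nominal
#'   observation times (exact-design binning)
#' @param pi percentiles summarized within each bin
#' @param band across-replicate confidence level for the simulated bands
#' @param mqc below-quantification limit applied to simulated replicates;
#'   `NULL` disables
#' @param seed optional seed
#' @return list of class `vpc_result`: per-bin observed percentiles,
#'   simulated medians and bands, bin observation counts (bins with < 5
#'   observations are flagged)
#' @export
visual_predictive_check <- function(theta, omega, sigma, data, n_rep = 200,
                                    bins = NULL, pi = c(0.05, 0.5, 0.95),
                                    band = 0.95, mqc = NULL, seed = NULL) {
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  subs <- .prep_subjects(data)
  om <- .as_omega(omega)
  cv <- .sigma_cv(sigma)
  times <- unlist(lapply(subs, function(s) s$t))
  y <- unlist(lapply(subs, function(s) s$y))
  if (is.null(bins)) {
    bin_id <- match(round(times, 6), sort(unique(round(times, 6))))
    bin_time <- sort(unique(round(times, 6)))
  } else {
    bin_id <- findInterval(times, bins, all.inside = TRUE)
    bin_time <- vapply(split(times, bin_id), median, 0)
  }
  nbin <- max(bin_id)
  obs_q <- t(vapply(seq_len(nbin), function(b)
    quantile(y[bin_id == b], pi, names = FALSE), numeric(length(pi))))
  n_in_bin <- tabulate(bin_id, nbin)

  sim_q <- array(NA_real_, c(n_rep, nbin, length(pi)))
  for (r in seq_len(n_rep)) {
    dv <- unlist(.simulate_replicate(subs, theta, om, cv, mqc))
    for (b in seq_len(nbin)) {
      v <- dv[bin_id == b]
      v <- v[!is.na(v)]
      if (length(v)) sim_q[r, b, ] <- quantile(v, pi, names = FALSE)
    }
  }
  a <- (1 - band) / 2
  sim_med <- apply(sim_q, c(2, 3), median, na.rm = TRUE)
  sim_lo <- apply(sim_q, c(2, 3), quantile, probs = a, na.rm = TRUE)
  sim_hi <- apply(sim_q, c(2, 3), quantile, probs = 1 - a, na.rm = TRUE)
  dimnames(obs_q) <- dimnames(sim_med) <- dimnames(sim_lo) <-
    dimnames(sim_hi) <- list(NULL, paste0("p", pi * 100))
  flagged <- which(n_in_bin < 5)
  if (length(flagged))
    warning("bin(s) with fewer than 5 observations: ",
            paste(flagged, collapse = ", "))
  structure(list(bin_time = bin_time, n_in_bin = n_in_bin, pi = pi,
                 observed = obs_q, sim_median = sim_med,
                 sim_lower = sim_lo, sim_upper = sim_hi,
                 n_rep = n_rep, flagged_bins = flagged),
            class = "vpc_result")
}

#' Numerical predictive check
#'
#' For each prediction-interval level, the fraction of observations
#' falling outside the model-simulated interval for their own design
#' point, compared with the expected fraction.
#'
#' @inheritParams visual_predictive_check
#' @param pi_levels prediction-interval levels (e.g. 0.9 = the central
#'   90% interval)
#' @return data.frame with, per level: expected and observed fractions
#'   outside, split into below/above
#' @export
numerical_predictive_check <- function(theta, omega, sigma, data,
                                       n_rep = 200,
                                       pi_levels = c(0.2, 0.5, 0.8, 0.9),
                                       mqc = NULL, seed = NULL) {
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  subs <- .prep_subjects(data)
  om <- .as_omega(omega)
  cv <- .sigma_cv(sigma)
  y <- unlist(lapply(subs, function(s) s$y))
  sims <- matrix(NA_real_, n_rep, length(y))
  for (r in seq_len(n_rep))
    sims[r, ] <- unlist(.simulate_replicate(subs, theta, om, cv, mqc))
  out <- lapply(pi_levels, function(lv) {
    a <- (1 - lv) / 2
    lo <- apply(sims, 2, quantile, probs = a, na.rm = TRUE)
    hi <- apply(sims, 2, quantile, probs = 1 - a, na.rm = TRUE)
    data.frame(pi_level = lv,
               expected_outside = 1 - lv,
               observed_outside = mean(y < lo | y > hi),
               observed_below = mean(y < lo),
               observed_above = mean(y > hi))
  })
  do.call(rbind, out)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits the model on each
#' resampled dataset, and summarizes each reported parameter by its
#' median and percentile 95% CI. Non-converged replicates are counted and
#' excluded; a report with more than 20% non-convergence is flagged.
#'
#' @param data PK dataset
#' @param init,estimate,control passed to [fit_population()]
#' @param n_boot number of bootstrap datasets (>= 50; published analyses
#'   commonly use 1000)
#' @param seed optional seed
#' @return list of class `bootstrap_result`: `summary` data.frame
#'   (parameter, median, lower, upper), raw `estimates` matrix,
#'   `n_nonconverged`, `flagged`
#' @export
bootstrap_fit <- function(data, init, n_boot = 200, estimate = list(),
                          control = list(), seed = NULL) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  subs <- if (is.list(data) && !is.data.frame(data)) data else .prep_subjects(data)
  n <- length(subs)
  ests <- NULL
  nonconv <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n, n, replace = TRUE)
    fit <- try(fit_population(subs[pick], init, estimate, control),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) {
      nonconv <- nonconv + 1L
      next
    }
    row <- c(exp(fit$theta[1:4]), fit$theta[5:11],
             iiv = 100 * sqrt(diag(fit$omega)),
             omega_cl_vc = fit$omega[1, 2], sigma_cv = fit$sigma$cv)
    names(row)[1:4] <- c("CL", "Vc", "Q", "Vp")
    ests <- rbind(ests, row)
  }
  if (is.null(ests)) stop("no bootstrap replicate converged")
  qs <- apply(ests, 2, quantile, probs = c(0.5, 0.025, 0.975))
  summary <- data.frame(parameter = colnames(ests),
                        median = qs[1, ], lower = qs[2, ], upper = qs[3, ],
                        row.names = NULL)
  flagged <- nonconv > 0.2 * n_boot
  if (flagged)
    warning("more than 20% of bootstrap replicates failed to converge")
  structure(list(summary = summary, estimates = ests,
                 n_boot = n_boot, n_nonconverged = nonconv,
                 flagged = flagged),
            class = "bootstrap_result")
}

#' Eta- and epsilon-shrinkage of a fit
#'
#' `eta-shrinkage_k = 100 * (1 - SD(etahat_k) / omega_k)` per random
#' effect, and `eps-shrinkage = 100 * (1 - SD(IWRES))` with
#' `IWRES = (DV - IPRED) / (sigma * IPRED)`. Random effects with zero
#' population variance are reported as `NA`.
#'
#' @param fit a converged [fit_population()] result
#' @return list with `eta` (named percent vector) and `eps` (percent)
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "popk_fit"))
  om_sd <- sqrt(diag(fit$omega))
  eta_shr <- ifelse(om_sd > 0,
                    100 * (1 - apply(fit$etas, 2, sd) / om_sd),
                    NA_real_)
  names(eta_shr) <- c("CL", "Vc", "Q", "Vp")
  ipred <- cpp_ipred(fit$subjects, as.numeric(fit$theta), fit$etas)
  iwres <- unlist(lapply(seq_along(fit$subjects), function(i) {
    f <- drop(ipred[[i]])
    (fit$subjects[[i]]$y - f) / (fit$sigma$cv * f)
  }))
  list(eta = eta_shr, eps = 100 * (1 - sd(iwres)))
}

#' Fraction of base-model inter-individual variability explained
#'
#' `100 * (1 - (final/base)^2)` for IIV magnitudes reported in percent
#' (or any common scale). A final IIV above the base value yields a
#' negative fraction and a warning.
#'
#' @param iiv_base,iiv_final IIV of the base and final (covariate) model,
#'   both positive, on the same scale
#' @return percent of base-model variance explained by the covariates
#' @export
percent_iiv_explained <- function(iiv_base, iiv_final) {
  stopifnot(iiv_base > 0, iiv_final > 0)
  out <- 100 * (1 - (iiv_final / iiv_base)^2)
  if (out < 0)
    warning("final-model IIV exceeds base-model IIV")
  out
}
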