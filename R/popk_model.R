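#' Typical clearance under the covariate model
#'
#' Evaluates the clearance arm of the covariate model,
#' `CL = exp(theta1 + theta6*log(WT/70) + theta7*log(ECD/25) +
#' theta8*log(ALBU/41) + theta9*log(TMBD/9) + theta10*TBL +
#' theta11*log(AST/27))`, i.e. the population prediction for a subject with
#' the given baseline covariates and eta = 0.
#'
#' @param theta a [theta_vector()]
#' @param cov a [covariate_vector()]
#' @return typical clearance in L/day
#' @export
typical_clearance <- function(theta, cov = reference_covariates()) {
  D <- .design_matrix(cov)
  exp(drop(D %*% as.numeric(theta))[1])
}

#' Typical central volume under the covariate model
#'
#' `Vc = exp(theta2 + theta5*log(WT/70))`.
#'
#' @inheritParams typical_clearance
#' @return typical central volume in L
#' @export
typical_central_volume <- function(theta, cov = reference_covariates()) {
  D <- .design_matrix(cov)
  exp(drop(D %*% as.numeric(theta))[2])
}

#' Individual disposition parameters
#'
#' Combines the covariate model with a subject's log-scale random effects:
#' `CL = typical_clearance * exp(eta_CL)` and analogously for Vc; `Q` and
#' `Vp` carry no covariates, `Q = exp(theta3 + eta_Q)`,
#' `Vp = exp(theta4 + eta_Vp)`.
#'
#' @inheritParams typical_clearance
#' @param eta numeric length-4 vector of log-scale random effects in the
#'   order (CL, Vc, Q, Vp)
#' @return list of class `individual_parameters` with elements `CL`, `Vc`,
#'   `Q`, `Vp` (all strictly positive) and `eta`
#' @export
individual_parameters <- function(theta, cov = reference_covariates(),
                                  eta = rep(0, 4)) {
  stopifnot(length(eta) == 4L, all(is.finite(eta)))
  D <- .design_matrix(cov)
  p <- exp(drop(D %*% as.numeric(theta)) + as.numeric(eta))
  structure(list(CL = p[1], Vc = p[2], Q = p[3], Vp = p[4],
                 eta = setNames(as.numeric(eta), c("CL", "Vc", "Q", "Vp"))),
            class = "individual_parameters")
}

.as_ind <- function(ind) {
  if (inherits(ind, "individual_parameters")) return(ind)
  stopifnot(is.list(ind), all(c("CL", "Vc", "Q", "Vp") %in% names(ind)))
  ind
}

#' Micro rate constants of the two-compartment model
#'
#' @param ind an [individual_parameters()] list (or any list with `CL`,
#'   `Vc`, `Q`, `Vp`)
#' @return named vector `(k10, k12, k21)` in 1/day; `Q = 0` degenerates to
#'   a one-compartment model with `k12 = k21 = 0`
#' @export
micro_constants <- function(ind) {
  ind <- .as_ind(ind)
  stopifnot(ind$CL > 0, ind$Vc > 0, ind$Q >= 0, ind$Vp >= 0)
  k10 <- ind$CL / ind$Vc
  if (ind$Q <= 0 || ind$Vp <= 0) return(c(k10 = k10, k12 = 0, k21 = 0))
  c(k10 = k10, k12 = ind$Q / ind$Vc, k21 = ind$Q / ind$Vp)
}

# hybrid macro constants: exponents alpha >= beta and bolus coefficients
# A + B = 1 of the central-compartment unit impulse response
.macro_constants <- function(ind) {
  k <- micro_constants(ind)
  if (k[["k12"]] == 0 && k[["k21"]] == 0)
    return(list(alpha = k[["k10"]], beta = 0, A = 1, B = 0, onecmt = TRUE))
  s <- sum(k)
  p <- k[["k10"]] * k[["k21"]]
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta,
       A = (alpha - k[["k21"]]) / (alpha - beta),
       B = (k[["k21"]] - beta) / (alpha - beta), onecmt = FALSE)
}

#' Terminal elimination half-life
#'
#' `log(2) / beta` where `beta` is the smaller exponent of the
#' bi-exponential disposition, i.e. the smaller root of
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`. With `Q = 0` this
#' reduces to the one-compartment half-life `log(2) Vc / CL`.
#'
#' @inheritParams micro_constants
#' @return half-life in days
#' @export
terminal_half_life <- function(ind) {
  m <- .macro_constants(.as_ind(ind))
  if (m$onecmt) log(2) / m$alpha else log(2) / m$beta
}

#' Dose event table
#'
#' @param time dose start times (days)
#' @param amt dose amounts (mg)
#' @param dur infusion durations in days; 0 flags an instantaneous bolus.
#'   The default 0.0208 days is a 30-minute infusion.
#' @return data.frame of class `dose_events`
#' @export
dose_events <- function(time, amt, dur = 0.0208) {
  d <- data.frame(time = time, amt = amt, dur = dur)
  stopifnot(all(d$amt >= 0), all(d$dur >= 0), !is.unsorted(d$time))
  structure(d, class = c("dose_events", "data.frame"))
}

#' Closed-form concentration in the central compartment
#'
#' Bi-exponential solution for zero-order infusions (bolus as the
#' zero-duration limit), summed over dose events by superposition. Times
#' before the first dose return 0.
#'
#' @inheritParams micro_constants
#' @param doses a [dose_events()] data.frame (columns `time`, `amt`, `dur`)
#' @param t observation times in days (any order, each >= 0)
#' @return concentrations in mg/L (= ug/mL)
#' @export
concentration <- function(ind, doses, t) {
  ind <- .as_ind(ind)
  stopifnot(all(t >= 0))
  drop(cpp_conc_profile(ind$CL, ind$Vc, ind$Q, ind$Vp,
                        doses$time, doses$amt, doses$dur, t))
}

# steady-state concentration at time t (in [0, tau]) after repeated dosing,
# by geometric accumulation of the post-infusion exponentials
.conc_ss <- function(ind, dose, tau, dur, t) {
  m <- .macro_constants(ind)
  lam <- if (m$onecmt) m$alpha else c(m$alpha, m$beta)
  co <- if (m$onecmt) 1 else c(m$A, m$B)
  single <- concentration(ind, dose_events(0, dose, dur), t)
  tail <- rep(0, length(t))
  for (j in seq_along(lam)) {
    l <- lam[j]
    acc <- exp(-l * tau) / (1 - exp(-l * tau))
    post <- if (dur > 0) {
      (dose / dur) / ind$Vc * co[j] / l * (1 - exp(-l * dur)) *
        exp(-l * (t - dur))
    } else {
      dose / ind$Vc * co[j] * exp(-l * t)
    }
    tail <- tail + post * acc
  }
  single + tail
}

#' Steady-state exposure metrics for repeated dosing
#'
#' For a linear model the steady-state AUC over one dosing interval is
#' `dose / CL` exactly; Cmax and Ctrough are read off the closed-form
#' steady-state profile (geometric-series accumulation of the
#' exponential terms), with Ctrough evaluated at `t = tau` after the dose
#' start.
#'
#' @inheritParams micro_constants
#' @param dose dose amount per administration (mg)
#' @param tau dosing interval (days)
#' @param dur infusion duration (days); 0 = bolus
#' @param n_grid number of grid points used to locate Cmax on the
#'   steady-state profile
#' @return list of class `exposure_metrics` with `auc` (ug day/mL),
#'   `cmax` and `ctrough` (ug/mL)
#' @export
steady_state_exposure <- function(ind, dose, tau, dur = 0.0208,
                                  n_grid = 2001L) {
  ind <- .as_ind(ind)
  stopifnot(dose > 0, tau > 0, dur >= 0, dur < tau)
  tgrid <- sort(unique(c(seq(0, tau, length.out = n_grid), dur, tau)))
  css <- .conc_ss(ind, dose, tau, dur, tgrid)
  structure(list(auc = dose / ind$CL, cmax = max(css),
                 ctrough = css[length(css)]),
            class = "exposure_metrics")
}
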