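# Nonlinear mixed-effects estimation: FOCE with interaction.
#
# The marginal -2 log-likelihood is approximated per subject by
# linearizing the prediction around the subject's conditional mode
# (empirical-Bayes eta) with the residual variance evaluated at the
# individual prediction ("interaction"). The outer quasi-Newton problem
# works on the exact FOCE-I objective: every outer evaluation re-solves
# each subject's conditional mode, warm-started from the previous modes
# so inner solves cost one or two Gauss-Newton steps. Holding the modes
# fixed during outer steps is not an option here: a shift in a typical
# value is exactly compensated by the stored modes (theta1 and eta_CL
# enter the prediction only through their sum), which leaves a
# frozen-mode objective flat along the directions being estimated.

# split a PK dataset into the per-subject lists the C++ core consumes
.prep_subjects <- function(data) {
  need <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV",
            "WT", "ECD", "ALBU", "TMBD", "TBL", "AST")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  ids <- unique(data$ID)
  subs <- lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & !is.na(d$DV), , drop = FALSE]
    if (nrow(dose) == 0) stop("subject ", id, " has no dose events")
    cvec <- covariate_vector(WT = d$WT[1], ECD = d$ECD[1], ALBU = d$ALBU[1],
                             TMBD = d$TMBD[1], TBL = d$TBL[1], AST = d$AST[1])
    list(t = obs$TIME, y = obs$DV, dt = dose$TIME, da = dose$AMT,
         du = ifelse(is.na(dose$DUR), 0, dose$DUR),
         D = .design_matrix(cvec))
  })
  names(subs) <- as.character(ids)
  n_obs <- vapply(subs, function(s) length(s$y), 0L)
  if (any(n_obs == 0))
    warning("subject(s) ", paste(names(subs)[n_obs == 0], collapse = ", "),
            " have no quantifiable observations; they carry no information")
  subs
}

.as_omega <- function(omega) {
  om <- unclass(omega)
  stopifnot(is.matrix(om), nrow(om) == 4, ncol(om) == 4)
  om
}

#' Empirical-Bayes (MAP) estimation of a subject's random effects
#'
#' Minimizes the conditional objective
#' `sum_j [ (DV_j - f_j)^2 / (sigma^2 f_j^2) + log(sigma^2 f_j^2) ] +
#' eta' Omega^-1 eta` over the random effects with non-zero variance.
#' With no observations the prior mode `eta = 0` is returned.
#'
#' @param theta,omega,sigma population parameters
#' @param subject_data PK dataset rows for a single subject (dose and
#'   observation records plus covariate columns)
#' @param eta0 starting value
#' @return list with `eta` (length 4), `objective` and `converged`
#' @export
map_individual <- function(theta, omega, sigma, subject_data,
                           eta0 = rep(0, 4)) {
  om <- .as_omega(omega)
  if (length(unique(subject_data$ID)) > 1)
    stop("subject_data must contain a single subject")
  sub <- .prep_subjects(subject_data)[[1]]
  res <- cpp_map_eta(sub, as.numeric(theta), om, .sigma_cv(sigma),
                     as.numeric(eta0))
  res$eta <- setNames(drop(res$eta), c("CL", "Vc", "Q", "Vp"))
  if (!res$converged)
    warning("MAP optimization did not converge for this subject")
  res
}

#' FOCE-I objective function value
#'
#' Sum over subjects of the interaction-corrected first-order conditional
#' approximation to -2 log marginal likelihood (constants included), with
#' each subject's eta at its conditional mode. Deterministic given the
#' data.
#'
#' @param theta,omega,sigma population parameters
#' @param data PK dataset (every subject should retain at least one
#'   quantifiable observation)
#' @param method `"foce"` (linearized, the default), `"laplace"` (exact
#'   joint at the mode plus Gauss-Newton log-curvature) or `"agq"`
#'   (adaptive 3-node Gauss-Hermite around the mode, the least biased and
#'   most expensive)
#' @return objective value with attribute `etas` (conditional modes)
#' @export
foce_objective <- function(theta, omega, sigma, data,
                           method = c("foce", "laplace", "agq")) {
  method <- match.arg(method)
  subs <- if (is.list(data) && !is.data.frame(data)) data else .prep_subjects(data)
  om <- .as_omega(omega)
  res <- cpp_foce(subs, as.numeric(theta), om, .sigma_cv(sigma),
                  matrix(0, length(subs), 4), TRUE, .method_code(method))
  structure(res$ofv, etas = res$etas, ofv_i = drop(res$ofv_i))
}

.method_code <- function(method) {
  switch(method, foce = 0L, laplace = 1L, agq = 2L,
         stop("unknown method: ", method))
}

# ---- outer parameter packing -------------------------------------------

# free structure: theta indices; omega estimated as a block whose shape
# (which diagonals > 0, CL-Vc covariance != 0) is taken from init
.pack_pars <- function(theta, omega, sigma, est) {
  p <- as.numeric(theta)[est$theta]
  if (est$omega) {
    d <- sqrt(diag(omega))
    if (est$omega_shape[1] && est$omega_shape[2] && est$omega_cov) {
      c11 <- d[1]; c21 <- omega[1, 2] / c11
      c22 <- sqrt(max(omega[2, 2] - c21^2, 1e-12))
      p <- c(p, log(c11), c21, log(c22))
    } else {
      if (est$omega_shape[1]) p <- c(p, log(d[1]))
      if (est$omega_shape[2]) p <- c(p, log(d[2]))
    }
    if (est$omega_shape[3]) p <- c(p, log(d[3]))
    if (est$omega_shape[4]) p <- c(p, log(d[4]))
  }
  if (est$sigma) p <- c(p, log(.sigma_cv(sigma)))
  p
}

.unpack_pars <- function(p, init, est) {
  theta <- as.numeric(init$theta)
  k <- length(est$theta)
  theta[est$theta] <- p[seq_len(k)]
  i <- k
  omega <- .as_omega(init$omega)
  if (est$omega) {
    if (est$omega_shape[1] && est$omega_shape[2] && est$omega_cov) {
      c11 <- exp(p[i + 1]); c21 <- p[i + 2]; c22 <- exp(p[i + 3]); i <- i + 3
      omega[1, 1] <- c11^2
      omega[1, 2] <- omega[2, 1] <- c11 * c21
      omega[2, 2] <- c21^2 + c22^2
    } else {
      if (est$omega_shape[1]) { i <- i + 1; omega[1, 1] <- exp(2 * p[i]) }
      if (est$omega_shape[2]) { i <- i + 1; omega[2, 2] <- exp(2 * p[i]) }
    }
    if (est$omega_shape[3]) { i <- i + 1; omega[3, 3] <- exp(2 * p[i]) }
    if (est$omega_shape[4]) { i <- i + 1; omega[4, 4] <- exp(2 * p[i]) }
  }
  sigma <- .sigma_cv(init$sigma)
  if (est$sigma) sigma <- exp(p[i + 1])
  list(theta = theta, omega = omega, sigma = sigma)
}

.make_est <- function(init, estimate) {
  om <- .as_omega(init$omega)
  est <- list(theta = estimate$theta %||% 1:11,
              omega = isTRUE(estimate$omega %||% TRUE),
              sigma = isTRUE(estimate$sigma %||% TRUE))
  if (is.logical(est$theta)) est$theta <- which(est$theta)
  est$omega_shape <- diag(om) > 0
  est$omega_cov <- om[1, 2] != 0
  if (!any(est$omega_shape)) est$omega <- FALSE
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the population model by FOCE with interaction
#'
#' Minimizes [foce_objective()] over the fixed effects, the
#' inter-individual covariance (log-Cholesky parameterized, so positive
#' definiteness of the estimated block is structural) and the proportional
#' residual CV (log scale). Random-effect structure (which etas carry
#' variability, whether the CL-Vc covariance is present) is read off the
#' initial `omega`: zero diagonals stay zero.
#'
#' @param data PK dataset (see [simulate_trial()] / [read_pkdataset()])
#' @param init list with starting `theta`, `omega`, `sigma`
#' @param estimate list controlling what is estimated: `theta` (indices or
#'   logical mask over theta1..theta11), `omega` (TRUE/FALSE for the whole
#'   block), `sigma` (TRUE/FALSE). Defaults estimate everything present.
#' @param control list: `iter_max` outer quasi-Newton iterations,
#'   `rel_tol` relative OFV convergence tolerance, `grad_step` forward
#'   finite-difference step for the outer gradient
#' @param compute_se compute asymptotic standard errors / 95% CIs from a
#'   finite-difference information matrix
#' @return object of class `popk_fit`: estimates (`theta`, `omega`,
#'   `sigma`), `ofv`, per-subject conditional modes `etas`, `converged`,
#'   and (optionally) `se`/`ci` tables on the internal scale
#' @export
fit_population <- function(data, init, estimate = list(),
                           control = list(), compute_se = FALSE) {
  subs <- if (is.list(data) && !is.data.frame(data)) data else .prep_subjects(data)
  n_obs <- vapply(subs, function(s) length(s$y), 0L)
  keep <- n_obs > 0
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no quantifiable observations dropped")
    subs <- subs[keep]
  }
  init$omega <- .as_omega(init$omega)
  init$sigma <- .sigma_cv(init$sigma)
  est <- .make_est(init, estimate)
  n_iiv <- sum(est$omega_shape)
  if (any(n_obs[keep] < n_iiv))
    warning("some subjects have fewer observations than random effects; ",
            "individual estimates rely on prior shrinkage")
  ctl <- list(iter_max = 200L, rel_tol = 1e-6, grad_step = 1e-4,
              max_polish = 4L, method = "foce")
  ctl[names(control)] <- control
  mth <- .method_code(ctl$method)

  p <- .pack_pars(init$theta, init$omega, init$sigma, est)
  n_sub <- length(subs)
  # Every evaluation re-solves the conditional modes starting from a FIXED
  # cache (the modes at the current pass's reference point), so the
  # objective and gradient are deterministic functions of the parameters.
  # Carrying modes forward from whatever point was evaluated last makes
  # the surface path-dependent: subjects stranded in poor inner modes add
  # several OFV units of hysteresis noise, which is enough to drown the
  # curvature of the typical-value parameters at n ~ 300.
  env <- new.env()
  mm <- .unpack_pars(p, init, est)
  env$cache <- cpp_foce(subs, mm$theta, mm$omega, mm$sigma,
                        matrix(0, n_sub, 4), TRUE, mth)$etas
  ofv_at <- function(pp, warm) {
    m <- .unpack_pars(pp, init, est)
    cpp_foce(subs, m$theta, m$omega, m$sigma, warm, TRUE, mth)
  }
  obj <- function(pp) {
    v <- ofv_at(pp, env$cache)$ofv
    if (!is.finite(v)) 1e10 else v
  }
  grad <- function(pp) {
    base <- ofv_at(pp, env$cache)$ofv
    g <- vapply(seq_along(pp), function(k) {
      h <- ctl$grad_step * max(1, abs(pp[k]))
      pk <- pp; pk[k] <- pp[k] + h
      (ofv_at(pk, env$cache)$ofv - base) / h
    }, 0)
    ifelse(is.finite(g), g, 0)
  }
  run_nlminb <- function(p0) {
    opt <- nlminb(p0, obj, grad,
                  control = list(iter.max = ctl$iter_max,
                                 eval.max = 3L * ctl$iter_max,
                                 rel.tol = ctl$rel_tol))
    # a fresh quasi-Newton restart clears "false convergence" stops caused
    # by the finite-difference gradient near the optimum
    for (restart in 1:2) {
      if (opt$convergence == 0 ||
          !grepl("false convergence", opt$message)) break
      prev <- opt$objective
      opt2 <- nlminb(opt$par, obj, grad,
                     control = list(iter.max = ctl$iter_max,
                                    eval.max = 3L * ctl$iter_max,
                                    rel.tol = ctl$rel_tol))
      if (opt2$objective <= prev) opt <- opt2
      if (abs(prev - opt$objective) < ctl$rel_tol * (abs(prev) + 1)) {
        opt$message <- "relative convergence (restart)"
        break
      }
    }
    opt
  }
  # cache-refresh polish: re-solve the modes from the prior mean at each
  # pass's optimum and repeat while that still improves the objective
  opt <- run_nlminb(p)
  iters <- opt$iterations
  for (polish in seq_len(ctl$max_polish)) {
    m <- .unpack_pars(opt$par, init, est)
    clean <- cpp_foce(subs, m$theta, m$omega, m$sigma,
                      matrix(0, n_sub, 4), TRUE, mth)
    if (!is.finite(clean$ofv) ||
        clean$ofv >= opt$objective - ctl$rel_tol * (abs(clean$ofv) + 1)) break
    env$cache <- clean$etas
    opt <- run_nlminb(opt$par)
    iters <- iters + opt$iterations
  }
  p <- opt$par
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|both X|singular convergence", opt$message)
  m <- .unpack_pars(p, init, est)
  res <- cpp_foce(subs, m$theta, m$omega, m$sigma,
                  matrix(0, n_sub, 4), TRUE, mth)
  etas <- res$etas
  opt$iterations <- iters

  fit <- structure(list(
    theta = as_theta_vector(m$theta),
    omega = structure(m$omega, dimnames = list(c("CL", "Vc", "Q", "Vp"),
                                               c("CL", "Vc", "Q", "Vp")),
                      class = c("omega_matrix", "matrix")),
    sigma = sigma_model(m$sigma),
    ofv = res$ofv,
    etas = structure(etas, dimnames = list(names(subs),
                                           c("CL", "Vc", "Q", "Vp"))),
    converged = converged, iterations = opt$iterations,
    message = opt$message,
    n_subjects = n_sub, n_obs = sum(n_obs[keep]),
    estimate = est, init = init, par = p, subjects = subs),
    class = "popk_fit")
  if (!converged)
    warning("fit did not reach the OFV tolerance within max_cycles; ",
            "best-so-far estimates returned")
  if (compute_se) fit <- .add_se(fit, init, est)
  fit
}

# asymptotic covariance: 2 * inverse Hessian of the OFV (OFV = -2 logL),
# Hessian by central differences of the exact FOCE-I objective
.add_se <- function(fit, init, est) {
  p <- fit$par
  subs <- fit$subjects
  warm <- fit$etas
  f <- function(pp) {
    m <- .unpack_pars(pp, init, est)
    cpp_foce(subs, m$theta, m$omega, m$sigma, warm, TRUE)$ofv
  }
  np <- length(p)
  h <- pmax(5e-4, 5e-4 * abs(p))
  H <- matrix(NA_real_, np, np)
  f0 <- f(p)
  fp <- fm <- numeric(np)
  for (k in seq_len(np)) {
    pk <- p; pk[k] <- p[k] + h[k]; fp[k] <- f(pk)
    pk[k] <- p[k] - h[k]; fm[k] <- f(pk)
    H[k, k] <- (fp[k] - 2 * f0 + fm[k]) / h[k]^2
  }
  for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
    pij <- p; pij[i] <- p[i] + h[i]; pij[j] <- p[j] + h[j]
    H[i, j] <- H[j, i] <-
      (f(pij) - fp[i] - fp[j] + f0) / (h[i] * h[j])
  }
  cv <- try(2 * solve(H), silent = TRUE)
  if (inherits(cv, "try-error") || any(diag(cv) < 0)) {
    warning("information matrix not positive definite; no SEs reported")
    return(fit)
  }
  se <- sqrt(diag(cv))
  fit$se <- se
  fit$ci <- cbind(lower = p - qnorm(0.975) * se,
                  upper = p + qnorm(0.975) * se)
  fit
}

#' @export
print.popk_fit <- function(x, ...) {
  cat("Population PK fit (FOCE-I)\n")
  cat(sprintf("  subjects: %d, observations: %d\n", x$n_subjects, x$n_obs))
  cat(sprintf("  OFV: %.3f  (converged: %s, %d outer iterations)\n",
              x$ofv, x$converged, x$iterations))
  cat(sprintf("  typical CL %.4f L/day, Vc %.4f L, Q %.4f L/day, Vp %.4f L\n",
              exp(x$theta[1]), exp(x$theta[2]), exp(x$theta[3]),
              exp(x$theta[4])))
  iiv <- 100 * sqrt(diag(x$omega))
  cat(sprintf("  IIV %%: CL %.1f, Vc %.1f, Q %.1f, Vp %.1f; sigma CV %.3f\n",
              iiv[1], iiv[2], iiv[3], iiv[4], x$sigma$cv))
  invisible(x)
}

#' Likelihood-ratio test p-value for an OFV drop
#'
#' @param delta_ofv non-negative drop in objective function value
#' @param df degrees of freedom (number of added parameters)
#' @return upper-tail chi-square probability
#' @export
lrt_significance <- function(delta_ofv, df = 1) {
  stopifnot(delta_ofv >= 0, df >= 1)
  pchisq(delta_ofv, df = df, lower.tail = FALSE)
}

#' Covariate candidate for stepwise selection
#'
#' Candidates follow the final model's functional conventions:
#' log-normalized power terms for all covariate-parameter pairs except
#' TBL on CL, which is linear on the log scale.
#'
#' @param parameter `"CL"` or `"Vc"`
#' @param covariate one of `"WT"`, `"ECD"`, `"ALBU"`, `"TMBD"`, `"TBL"`,
#'   `"AST"` (on CL) or `"WT"` (on Vc)
#' @return list with the candidate's theta index and functional form
#' @export
covariate_candidate <- function(parameter = c("CL", "Vc"), covariate) {
  parameter <- match.arg(parameter)
  idx <- if (parameter == "Vc") {
    if (covariate != "WT") stop("only body weight is modeled on Vc")
    5L
  } else {
    switch(covariate, WT = 6L, ECD = 7L, ALBU = 8L, TMBD = 9L,
           TBL = 10L, AST = 11L,
           stop("unknown covariate: ", covariate))
  }
  structure(list(parameter = parameter, covariate = covariate,
                 theta_index = idx,
                 form = if (idx == 10L) "linear" else "power"),
            class = "covariate_candidate")
}

#' Stepwise forward-addition / backward-deletion covariate selection
#'
#' Forward step: among candidates not yet included, fit each extension of
#' the current model and add the one with the largest OFV drop, provided
#' the drop is significant at `forward_alpha` (chi-square, 1 df per
#' candidate). Repeat until no addition qualifies. Backward step: remove,
#' one at a time, the included covariate whose deletion raises the OFV
#' least, as long as that rise is not significant at `backward_alpha`.
#'
#' @param data PK dataset
#' @param candidates list of [covariate_candidate()]s
#' @param init starting parameters for the base model (covariate
#'   coefficients are initialized at 0 when first added)
#' @param forward_alpha,backward_alpha significance levels (defaults 0.01
#'   forward, 0.001 backward)
#' @param forward_delta,backward_delta optional explicit OFV thresholds
#'   overriding the chi-square quantiles
#' @param estimate,control passed to [fit_population()]
#' @return list with the final `fit`, `included` candidates and a `trace`
#'   data.frame recording every tested step
#' @export
stepwise_selection <- function(data, candidates, init,
                               forward_alpha = 0.01, backward_alpha = 0.001,
                               forward_delta = NULL, backward_delta = NULL,
                               estimate = list(), control = list()) {
  subs <- if (is.list(data) && !is.data.frame(data)) data else .prep_subjects(data)
  if (is.null(forward_delta)) forward_delta <- qchisq(1 - forward_alpha, 1)
  if (is.null(backward_delta)) backward_delta <- qchisq(1 - backward_alpha, 1)
  base_idx <- 1:4
  cand_idx <- vapply(candidates, function(c) c$theta_index, 0L)
  cand_lab <- vapply(candidates, function(c)
    paste0(c$covariate, "_", c$parameter), "")

  fit_with <- function(idx_set, theta_start) {
    est <- estimate
    est$theta <- sort(unique(c(base_idx, idx_set)))
    ini <- init
    th <- as.numeric(theta_start)
    th[setdiff(5:11, idx_set)] <- 0
    ini$theta <- as_theta_vector(th)
    fit_population(subs, ini, est, control)
  }

  included <- integer(0)
  cur <- fit_with(included, init$theta)
  trace <- data.frame(phase = "base", candidate = "(none)",
                      action = "fit", ofv = cur$ofv, delta = NA_real_,
                      p = NA_real_, accepted = NA)
  if (length(candidates)) {
    # forward addition
    repeat {
      open <- setdiff(seq_along(cand_idx), match(included, cand_idx))
      if (!length(open)) break
      fits <- lapply(open, function(j)
        fit_with(c(included, cand_idx[j]), cur$theta))
      deltas <- cur$ofv - vapply(fits, function(f) f$ofv, 0)
      best <- which.max(deltas)
      accept <- deltas[best] > forward_delta
      trace <- rbind(trace, data.frame(
        phase = "forward", candidate = cand_lab[open],
        action = "try-add", ofv = vapply(fits, function(f) f$ofv, 0),
        delta = deltas, p = lrt_significance(pmax(deltas, 0), 1),
        accepted = seq_along(open) == best & accept))
      if (!accept) break
      included <- c(included, cand_idx[open[best]])
      cur <- fits[[best]]
    }
    # backward deletion
    repeat {
      if (!length(included)) break
      fits <- lapply(seq_along(included), function(j)
        fit_with(included[-j], cur$theta))
      rises <- vapply(fits, function(f) f$ofv, 0) - cur$ofv
      worst <- which.min(rises)
      remove <- rises[worst] < backward_delta
      trace <- rbind(trace, data.frame(
        phase = "backward", candidate = cand_lab[match(included, cand_idx)],
        action = "try-drop", ofv = vapply(fits, function(f) f$ofv, 0),
        delta = rises, p = lrt_significance(pmax(rises, 0), 1),
        accepted = seq_along(included) == worst & remove))
      if (!remove) break
      cur <- fits[[worst]]
      included <- included[-worst]
    }
  }
  rownames(trace) <- NULL
  list(fit = cur,
       included = candidates[match(included, cand_idx)],
       trace = trace)
}
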