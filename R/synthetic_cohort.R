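#' Fit a log-normal distribution to percentile anchors
#'
#' Matches a log-normal to reported 5th/50th/95th percentiles: the log-mean
#' is `log(p50)` and the log-SD averages the two one-tail fits
#' `log(p95/p50)/z95` and `log(p50/p5)/z95` with `z95 = qnorm(0.95)`.
#' When the anchors are log-symmetric the two tail fits agree and the fit
#' is exact.
#'
#' @param p5,p50,p95 strictly ordered positive percentile anchors
#' @return list with `meanlog` and `sdlog`
#' @export
fit_lognormal_from_percentiles <- function(p5, p50, p95) {
  if (!(0 < p5 && p5 < p50 && p50 < p95))
    stop("percentile anchors must satisfy 0 < p5 < p50 < p95")
  z <- qnorm(0.95)
  list(meanlog = log(p50),
       sdlog = mean(c(log(p95 / p50), log(p50 / p5))) / z)
}

#' Baseline covariate distribution of the analysis population
#'
#' Percentile anchors (5th/50th/95th) per covariate, in the units of
#' [covariate_vector()]. Each positive covariate is sampled log-normally
#' via [fit_lognormal_from_percentiles()]; baseline trastuzumab (TBL) is a
#' mixture of a point mass at 0 (trastuzumab-naive washout) and a
#' log-normal for the positive part.
#'
#' The defaults are the published percentile anchors of the pooled
#' 671-patient population: weight 49/70/98 kg, ECD 8.5/25/332 ng/mL,
#' albumin 33/41/48 g/L, tumor burden 1.5/9/30.3 cm, AST 15.3/27/64 IU/L,
#' and TBL with 95th percentile 54 ug/mL. The TBL point-mass probability
#' and positive-part median are not published; half the population is
#' assumed residual-trastuzumab free and the positive part is anchored so
#' its upper tail reproduces the published 95th percentile.
#'
#' @param anchors named list of `c(p5, p50, p95)` vectors for `WT`, `ECD`,
#'   `ALBU`, `TMBD`, `AST`
#' @param tbl_p0 probability that TBL is exactly 0
#' @param tbl_p50_pos,tbl_p95 median of the positive part and overall 95th
#'   percentile of TBL
#' @param copula_corr optional 5x5 correlation matrix (WT, ECD, ALBU, TMBD,
#'   AST order) for a log-scale Gaussian copula; default independent
#' @return list of class `covariate_spec`
#' @export
covariate_spec <- function(anchors = list(WT = c(49, 70, 98),
                                          ECD = c(8.5, 25, 332),
                                          ALBU = c(33, 41, 48),
                                          TMBD = c(1.5, 9, 30.3),
                                          AST = c(15.3, 27, 64)),
                           tbl_p0 = 0.5, tbl_p50_pos = 13, tbl_p95 = 54,
                           copula_corr = NULL) {
  stopifnot(tbl_p0 >= 0, tbl_p0 <= 1, tbl_p50_pos > 0, tbl_p95 > tbl_p50_pos)
  fits <- lapply(anchors, function(a)
    fit_lognormal_from_percentiles(a[1], a[2], a[3]))
  # positive part of TBL: quantile level of the overall p95 within the
  # positive component, assuming p0 >= 0.5 puts the median at 0
  q <- if (tbl_p0 < 0.95) (0.95 - tbl_p0) / (1 - tbl_p0) else 0.90
  tbl_sdlog <- log(tbl_p95 / tbl_p50_pos) / qnorm(q)
  if (!is.null(copula_corr))
    stopifnot(is.matrix(copula_corr), nrow(copula_corr) == 5,
              isTRUE(all.equal(copula_corr, t(copula_corr))))
  structure(list(anchors = anchors, fits = fits, tbl_p0 = tbl_p0,
                 tbl_p95 = tbl_p95, tbl_meanlog = log(tbl_p50_pos),
                 tbl_sdlog = tbl_sdlog, copula_corr = copula_corr),
            class = "covariate_spec")
}

#' Sample baseline covariate vectors
#'
#' @param spec a [covariate_spec()]
#' @param n number of subjects
#' @param seed optional integer seed (uses the session RNG stream when
#'   `NULL`)
#' @return data.frame with columns WT, ECD, ALBU, TMBD, TBL, AST; one row
#'   per subject
#' @export
sample_covariates <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "covariate_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nm <- c("WT", "ECD", "ALBU", "TMBD", "AST")
  if (is.null(spec$copula_corr)) {
    z <- matrix(rnorm(n * 5), n, 5)
  } else {
    z <- matrix(rnorm(n * 5), n, 5) %*% chol(spec$copula_corr)
  }
  colnames(z) <- nm
  out <- as.data.frame(lapply(nm, function(v) {
    f <- spec$fits[[v]]
    exp(f$meanlog + f$sdlog * z[, v])
  }))
  names(out) <- nm
  pos <- runif(n) >= spec$tbl_p0
  tbl <- numeric(n)
  tbl[pos] <- rlnorm(sum(pos), spec$tbl_meanlog, spec$tbl_sdlog)
  out$TBL <- tbl
  out[, c("WT", "ECD", "ALBU", "TMBD", "TBL", "AST")]
}

#' Virtual trial design
#'
#' @param n_subjects number of subjects
#' @param regimen `"q3w"` (21-day interval) or `"qw"` (7-day)
#' @param dose_mg_per_kg per-kg dose rate; the labeled regimen is 3.6
#'   mg/kg q3w
#' @param flat_dose_mg optional flat dose in mg overriding per-kg dosing
#' @param n_cycles number of dosing cycles
#' @param schedule `"rich"` (pre-dose, end of infusion, 0.25, 1, 3, 7, 14
#'   days post dose each cycle, phase-I-like) or `"sparse"` (pre-dose +
#'   end of infusion); both add a final trough at the end of the last
#'   cycle. Supply `sampling_offsets` to override.
#' @param sampling_offsets optional numeric offsets (days after each dose)
#' @param mqc minimum quantifiable concentration (ug/mL); the assay range
#'   is 0.04-0.06
#' @param infusion_duration infusion duration in days (default 30 min)
#' @return list of class `trial_design`
#' @export
trial_design <- function(n_subjects, regimen = c("q3w", "qw"),
                         dose_mg_per_kg = 3.6, flat_dose_mg = NULL,
                         n_cycles = 8, schedule = c("rich", "sparse"),
                         sampling_offsets = NULL, mqc = 0.05,
                         infusion_duration = 0.0208) {
  regimen <- match.arg(regimen)
  schedule <- match.arg(schedule)
  tau <- if (regimen == "q3w") 21 else 7
  if (is.null(sampling_offsets)) {
    sampling_offsets <- if (schedule == "rich")
      c(0, infusion_duration, 0.25, 1, 3, 7, 14) else c(0, infusion_duration)
    sampling_offsets <- sampling_offsets[sampling_offsets < tau]
  }
  stopifnot(n_subjects >= 1, n_cycles >= 1,
            all(sampling_offsets >= 0), all(sampling_offsets < tau),
            mqc > 0, infusion_duration >= 0)
  structure(list(n_subjects = as.integer(n_subjects), regimen = regimen,
                 tau = tau, dose_mg_per_kg = dose_mg_per_kg,
                 flat_dose_mg = flat_dose_mg, n_cycles = as.integer(n_cycles),
                 sampling_offsets = sort(unique(sampling_offsets)),
                 mqc = mqc, infusion_duration = infusion_duration),
            class = "trial_design")
}

.design_times <- function(design) {
  starts <- (seq_len(design$n_cycles) - 1) * design$tau
  list(dose_time = starts,
       obs_time = sort(unique(c(outer(design$sampling_offsets, starts, "+"),
                                design$n_cycles * design$tau))))
}

#' Simulate a virtual trial
#'
#' Draws baseline covariates from `spec`, subject random effects from
#' `MVN(0, Omega)`, doses each subject per the design (per-kg by default),
#' evaluates the closed-form concentration at the design's nominal times
#' and applies proportional residual error `DV = f * (1 + eps)`,
#' `eps ~ N(0, cv^2)`. Non-positive draws (possible at high CV) are
#' truncated to a tiny positive value so that quantification-limit
#' censoring removes them. No censoring is applied here; see
#' [apply_mqc_censoring()].
#'
#' @param design a [trial_design()]
#' @param theta,omega,sigma model parameters ([theta_vector()],
#'   [omega_matrix()], [sigma_model()])
#' @param spec a [covariate_spec()]
#' @param seed optional integer seed
#' @return a PK dataset: data.frame with NONMEM-convention columns `ID`,
#'   `TIME`, `EVID` (1 dose / 0 observation), `AMT`, `DUR`, `DV`, `MDV`
#'   and the six covariate columns. True etas and individual parameters
#'   are attached as attributes `etas` and `params` for simulation
#'   studies.
#' @export
simulate_trial <- function(design, theta, omega, sigma, spec = covariate_spec(),
                           seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  cv <- .sigma_cv(sigma)
  covs <- sample_covariates(spec, n)
  etas <- .rmvnorm0(n, unclass(omega))
  tt <- .design_times(design)
  rows <- vector("list", n)
  params <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("CL", "Vc", "Q", "Vp")))
  for (i in seq_len(n)) {
    cvec <- covariate_vector(WT = covs$WT[i], ECD = covs$ECD[i],
                             ALBU = covs$ALBU[i], TMBD = covs$TMBD[i],
                             TBL = covs$TBL[i], AST = covs$AST[i])
    ind <- individual_parameters(theta, cvec, etas[i, ])
    params[i, ] <- c(ind$CL, ind$Vc, ind$Q, ind$Vp)
    amt <- if (is.null(design$flat_dose_mg))
      design$dose_mg_per_kg * covs$WT[i] else design$flat_dose_mg
    doses <- dose_events(tt$dose_time, amt, design$infusion_duration)
    f <- concentration(ind, doses, tt$obs_time)
    dv <- f * (1 + rnorm(length(f), 0, cv))
    dv[dv <= 0] <- 1e-6
    sub <- rbind(
      data.frame(ID = i, TIME = doses$time, EVID = 1L, AMT = doses$amt,
                 DUR = doses$dur, DV = NA_real_, MDV = 1L),
      data.frame(ID = i, TIME = tt$obs_time, EVID = 0L, AMT = NA_real_,
                 DUR = NA_real_, DV = dv, MDV = 0L))
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    rows[[i]] <- cbind(sub, covs[rep(i, nrow(sub)), , drop = FALSE],
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "etas") <- etas
  attr(out, "params") <- params
  out
}

# MVN(0, S) draws tolerating singular S (zero-variance effects)
.rmvnorm0 <- function(n, S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), nrow(S))
  matrix(rnorm(n * nrow(S)), n) %*% t(L)
}

#' Omit observations below the quantification limit
#'
#' Observation records with `DV < mqc` are dropped (not flagged and kept),
#' mirroring the analysis rule that below-MQC observations are omitted.
#' Dose records are untouched. The dropped fraction of observation records
#' is attached as attribute `censored_fraction`.
#'
#' @param data a PK dataset as produced by [simulate_trial()]
#' @param mqc minimum quantifiable concentration (ug/mL); `mqc = 0` leaves
#'   the dataset unchanged
#' @return the filtered dataset
#' @export
apply_mqc_censoring <- function(data, mqc) {
  stopifnot(mqc >= 0)
  obs <- data$EVID == 0
  drop <- obs & !is.na(data$DV) & data$DV < mqc
  out <- data[!drop, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("etas", "params")) attr(out, a) <- attr(data, a)
  attr(out, "censored_fraction") <- sum(drop) / max(sum(obs), 1L)
  out
}
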