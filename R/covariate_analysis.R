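# Covariate-impact analyses: extreme-value effects on CL and Vc,
# steady-state exposure sensitivity, covariate normalization of individual
# parameters, and subgroup exposure comparison.

.cl_covariates <- c("WT", "ECD", "ALBU", "TMBD", "TBL", "AST")

.set_cov <- function(name, value) {
  ref <- as.list(unclass(reference_covariates()))
  ref[[name]] <- value
  do.call(covariate_vector, ref)
}

#' Covariate extreme-value effects on CL and Vc
#'
#' For each covariate of the final model, evaluates the typical parameter
#' with that covariate at its 5th and 95th percentile anchor (all other
#' covariates at reference) and reports the estimate and percent change
#' from the typical value.
#'
#' @param theta a [theta_vector()]
#' @param spec a [covariate_spec()] providing the percentile anchors; TBL
#'   anchors are 0 (5th) and `tbl_p95` (95th)
#' @return data.frame with columns `parameter`, `covariate`, `percentile`,
#'   `value`, `estimate`, `pct_change`
#' @export
covariate_effect_table <- function(theta = reference_theta(),
                                   spec = covariate_spec()) {
  cl_typ <- typical_clearance(theta)
  vc_typ <- typical_central_volume(theta)
  rows <- list()
  for (cov in .cl_covariates) {
    anchors <- if (cov == "TBL") c(0, spec$tbl_p95) else
      spec$anchors[[cov]][c(1, 3)]
    for (k in 1:2) {
      est <- typical_clearance(theta, .set_cov(cov, anchors[k]))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = "CL", covariate = cov,
        percentile = c("p5", "p95")[k], value = anchors[k],
        estimate = est, pct_change = 100 * (est - cl_typ) / cl_typ)
    }
  }
  for (k in 1:2) {
    w <- spec$anchors$WT[c(1, 3)][k]
    est <- typical_central_volume(theta, .set_cov("WT", w))
    rows[[length(rows) + 1]] <- data.frame(
      parameter = "Vc", covariate = "WT",
      percentile = c("p5", "p95")[k], value = w,
      estimate = est, pct_change = 100 * (est - vc_typ) / vc_typ)
  }
  out <- do.call(rbind, rows)
  attr(out, "typical") <- c(CL = cl_typ, Vc = vc_typ)
  out
}

#' Steady-state exposure sensitivity to single-covariate perturbations
#'
#' Computes steady-state AUC, Cmax and Ctrough for a typical (eta = 0)
#' subject with one covariate moved to its 5th or 95th percentile anchor
#' and all others at reference, as percent change from the all-reference
#' base subject. Under per-kg dosing (the default), perturbing body
#' weight rescales the dose as well as the PK parameters; set
#' `weight_rescales_dose = FALSE` to isolate the pure PK effect.
#'
#' @inheritParams covariate_effect_table
#' @param dose_mg_per_kg per-kg dose rate (labeled regimen 3.6 mg/kg)
#' @param tau dosing interval in days
#' @param dur infusion duration in days
#' @param weight_rescales_dose logical; see above
#' @return data.frame with one row per covariate x percentile x metric:
#'   `exposure`, `base`, `pct_change`
#' @export
exposure_sensitivity <- function(theta = reference_theta(),
                                 spec = covariate_spec(),
                                 dose_mg_per_kg = 3.6, tau = 21,
                                 dur = 0.0208,
                                 weight_rescales_dose = TRUE) {
  ref <- reference_covariates()
  base_dose <- dose_mg_per_kg * ref[["WT"]]
  base <- steady_state_exposure(individual_parameters(theta, ref),
                                base_dose, tau, dur)
  base_v <- c(auc = base$auc, cmax = base$cmax, ctrough = base$ctrough)
  rows <- list()
  for (cov in .cl_covariates) {
    anchors <- if (cov == "TBL") c(0, spec$tbl_p95) else
      spec$anchors[[cov]][c(1, 3)]
    for (k in 1:2) {
      cvec <- .set_cov(cov, anchors[k])
      dose <- if (cov == "WT" && weight_rescales_dose)
        dose_mg_per_kg * anchors[k] else base_dose
      ex <- steady_state_exposure(individual_parameters(theta, cvec),
                                  dose, tau, dur)
      exv <- c(auc = ex$auc, cmax = ex$cmax, ctrough = ex$ctrough)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cov, percentile = c("p5", "p95")[k],
        value = anchors[k], metric = names(exv),
        exposure = unname(exv), base = unname(base_v),
        pct_change = unname(100 * (exv - base_v) / base_v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-normalize individual parameters
#'
#' Divides a subject's CL and Vc by the subject-specific covariate
#' multiplier, returning the parameters the subject would have at the
#' reference covariates with the same random effects. Normalizing a
#' subject already at reference covariates is the identity, and the
#' operation is idempotent.
#'
#' @param ind an [individual_parameters()] list (or list with `CL`, `Vc`)
#' @param cov the subject's [covariate_vector()]
#' @param theta a [theta_vector()]
#' @param reference reference covariates
#' @return list with normalized `CL` and `Vc`
#' @export
normalize_individual_parameters <- function(ind, cov,
                                            theta = reference_theta(),
                                            reference = reference_covariates()) {
  stopifnot(is.list(ind), all(c("CL", "Vc") %in% names(ind)))
  mult_cl <- typical_clearance(theta, cov) / typical_clearance(theta, reference)
  mult_vc <- typical_central_volume(theta, cov) /
    typical_central_volume(theta, reference)
  list(CL = ind$CL / mult_cl, Vc = ind$Vc / mult_vc)
}

#' Subgroup steady-state exposure comparison
#'
#' Computes per-subject steady-state AUC, Cmax and Ctrough for repeated
#' dosing from individual (e.g. empirical-Bayes) parameters, then
#' summarizes each metric per group by its mean and 5th-95th percentile
#' interval. Empty groups are omitted with a warning.
#'
#' @param params data.frame with one row per subject: columns `CL`, `Vc`,
#'   `Q`, `Vp` and `WT` (needed for per-kg dosing)
#' @param group vector of group labels, one per subject
#' @param dose_mg_per_kg per-kg dose rate; ignored when `flat_dose_mg`
#'   is given
#' @param flat_dose_mg optional flat dose in mg for all subjects
#' @param tau dosing interval (days)
#' @param dur infusion duration (days)
#' @return list with `summary` (group x metric means and percentiles) and
#'   `exposure` (per-subject metrics)
#' @export
subgroup_exposure <- function(params, group, dose_mg_per_kg = 3.6,
                              flat_dose_mg = NULL, tau = 21, dur = 0.0208) {
  stopifnot(nrow(params) == length(group))
  n <- nrow(params)
  ex <- data.frame(group = group, auc = NA_real_, cmax = NA_real_,
                   ctrough = NA_real_)
  for (i in seq_len(n)) {
    dose <- if (is.null(flat_dose_mg)) dose_mg_per_kg * params$WT[i]
            else flat_dose_mg
    m <- steady_state_exposure(list(CL = params$CL[i], Vc = params$Vc[i],
                                    Q = params$Q[i], Vp = params$Vp[i]),
                               dose, tau, dur)
    ex[i, c("auc", "cmax", "ctrough")] <- c(m$auc, m$cmax, m$ctrough)
  }
  lev <- if (is.factor(group)) levels(group) else unique(group)
  empty <- setdiff(lev, unique(as.character(ex$group)))
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  rows <- lapply(split(ex, as.character(ex$group)), function(d) {
    do.call(rbind, lapply(c("auc", "cmax", "ctrough"), function(m)
      data.frame(group = d$group[1], metric = m, n = nrow(d),
                 mean = mean(d[[m]]),
                 p5 = unname(quantile(d[[m]], 0.05)),
                 p95 = unname(quantile(d[[m]], 0.95)))))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, exposure = ex)
}
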