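# Dataset and configuration I/O plus the end-to-end pipeline driver.

.nm_cols <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV",
              "WT", "ECD", "ALBU", "TMBD", "TBL", "AST")

#' Write a PK dataset as a NONMEM-convention CSV
#'
#' Columns `ID, TIME, EVID, AMT, DUR, DV, MDV` plus the six covariate
#' columns; empty numeric fields are written as `"."`.
#'
#' @param data PK dataset (as from [simulate_trial()])
#' @param path output file
#' @export
write_pkdataset <- function(data, path) {
  miss <- setdiff(.nm_cols, names(data))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  out <- data[, .nm_cols]
  for (cc in .nm_cols) {
    v <- out[[cc]]
    out[[cc]] <- ifelse(is.na(v), ".", format(v, digits = 12, trim = TRUE,
                                              scientific = FALSE))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NONMEM-convention PK dataset CSV
#'
#' Parses `"."` as missing (`MDV` is forced to 1 on observation rows with
#' missing `DV`), checks that every subject has at least one dose event
#' and that `TIME` is non-decreasing within subject, and reports record
#' counts.
#'
#' @param path CSV file with a header row
#' @param quiet suppress the row-count message
#' @return PK dataset data.frame
#' @export
read_pkdataset <- function(path, quiet = FALSE) {
  raw <- read.csv(path, colClasses = "character")
  miss <- setdiff(.nm_cols, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  out <- as.data.frame(lapply(raw[.nm_cols], num))
  out$ID <- as.integer(out$ID)
  out$EVID <- as.integer(out$EVID)
  out$MDV <- as.integer(out$MDV)
  out$MDV[out$EVID == 0 & is.na(out$DV)] <- 1L
  for (id in unique(out$ID)) {
    d <- out[out$ID == id, ]
    if (!any(d$EVID == 1))
      stop("subject ", id, " has no dose events")
    if (is.unsorted(d$TIME))
      stop("non-monotone TIME within subject ", id)
    if (any(d$TIME[d$EVID == 0] < min(d$TIME[d$EVID == 1])))
      stop("subject ", id, " has observations before the first dose")
  }
  if (!quiet)
    message(sprintf("read %d records (%d doses, %d observations, %d missing DV)",
                    nrow(out), sum(out$EVID == 1),
                    sum(out$EVID == 0 & !is.na(out$DV)),
                    sum(out$EVID == 0 & is.na(out$DV))))
  out
}

.known_config <- c("out_dir", "seed", "n_subjects", "regimen", "n_cycles",
                   "schedule", "dose_mg_per_kg", "mqc", "model_file",
                   "n_vpc", "n_boot", "estimate_theta", "run_bootstrap",
                   "run_selection")

#' Run the simulate / fit / diagnose / covariate-analysis pipeline
#'
#' A thin driver tying the stages together with deterministic per-stage
#' seeds spawned from one global seed, so identical configurations give
#' identical outputs. Artifacts (dataset, estimates, VPC/NPC tables,
#' covariate and sensitivity tables) are written as CSV under `out_dir`.
#'
#' @param config named list (or YAML file path). Recognized keys:
#'   `out_dir`, `seed`, `n_subjects`, `regimen`, `n_cycles`, `schedule`,
#'   `dose_mg_per_kg`, `mqc`, `model_file` (defaults to the shipped
#'   published-estimates file), `n_vpc`, `n_boot`, `estimate_theta`
#'   (theta indices to estimate), `run_bootstrap`, `run_selection`.
#'   Unknown keys are rejected.
#' @return invisible named list of output file paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .known_config)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(seed = 1L, n_subjects = 50L, regimen = "q3w", n_cycles = 4L,
              schedule = "rich", dose_mg_per_kg = 3.6, mqc = 0.05,
              model_file = system.file("extdata", "tdm1_final_model.yaml",
                                       package = "tdm1popk"),
              n_vpc = 100L, n_boot = 0L, estimate_theta = 1:11,
              run_bootstrap = FALSE, run_selection = FALSE)
  cfg[names(config)] <- config
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$mqc > 0, cfg$n_vpc >= 1)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  stage_seed <- sample.int(.Machine$integer.max %/% 2, 4)
  model <- read_model_config(cfg$model_file)
  out <- list()
  path <- function(f) file.path(cfg$out_dir, f)
  log <- function(...) message(sprintf(...))

  # stage 1: simulate
  log("[simulate] seed %d, n=%d %s x%d cycles", stage_seed[1],
      cfg$n_subjects, cfg$regimen, cfg$n_cycles)
  design <- trial_design(cfg$n_subjects, cfg$regimen,
                         dose_mg_per_kg = cfg$dose_mg_per_kg,
                         n_cycles = cfg$n_cycles, schedule = cfg$schedule,
                         mqc = cfg$mqc)
  raw <- simulate_trial(design, model$theta, model$omega, model$sigma,
                        seed = stage_seed[1])
  dat <- apply_mqc_censoring(raw, cfg$mqc)
  log("[simulate] censored fraction %.3f", attr(dat, "censored_fraction"))
  out$dataset <- write_pkdataset(dat, path("dataset.csv"))

  # stage 2: fit
  log("[fit] FOCE-I, estimating theta {%s}",
      paste(cfg$estimate_theta, collapse = ","))
  fit <- fit_population(dat, init = model,
                        estimate = list(theta = cfg$estimate_theta))
  est <- data.frame(parameter = c(paste0("theta", 1:11),
                                  "iiv_cl", "iiv_vc", "iiv_q", "iiv_vp",
                                  "omega_cl_vc", "sigma_cv", "ofv"),
                    estimate = c(as.numeric(fit$theta),
                                 100 * sqrt(diag(fit$omega)),
                                 fit$omega[1, 2], fit$sigma$cv, fit$ofv))
  write.csv(est, path("fit_estimates.csv"), row.names = FALSE)
  out$fit <- path("fit_estimates.csv")
  write_model_config(fit$theta, fit$omega, fit$sigma,
                     path("fit_model.yaml"))
  out$fit_model <- path("fit_model.yaml")

  # stage 3: diagnostics
  log("[diagnose] seed %d, %d VPC replicates", stage_seed[2], cfg$n_vpc)
  vpc <- visual_predictive_check(fit$theta, fit$omega, fit$sigma, dat,
                                 n_rep = cfg$n_vpc, mqc = cfg$mqc,
                                 seed = stage_seed[2])
  vtab <- data.frame(bin_time = vpc$bin_time, n = vpc$n_in_bin,
                     obs_p50 = vpc$observed[, "p50"],
                     sim_p50 = vpc$sim_median[, "p50"],
                     sim_p50_lo = vpc$sim_lower[, "p50"],
                     sim_p50_hi = vpc$sim_upper[, "p50"])
  write.csv(vtab, path("vpc.csv"), row.names = FALSE)
  out$vpc <- path("vpc.csv")
  npc <- numerical_predictive_check(fit$theta, fit$omega, fit$sigma, dat,
                                    n_rep = cfg$n_vpc, mqc = cfg$mqc,
                                    seed = stage_seed[3])
  write.csv(npc, path("npc.csv"), row.names = FALSE)
  out$npc <- path("npc.csv")
  shr <- shrinkage(fit)
  write.csv(data.frame(quantity = c(paste0("eta_", names(shr$eta)), "eps"),
                       shrinkage_pct = c(shr$eta, shr$eps)),
            path("shrinkage.csv"), row.names = FALSE)
  out$shrinkage <- path("shrinkage.csv")
  if (isTRUE(cfg$run_bootstrap) && cfg$n_boot >= 2) {
    bs <- bootstrap_fit(dat, init = model, n_boot = cfg$n_boot,
                        estimate = list(theta = cfg$estimate_theta),
                        seed = stage_seed[4])
    write.csv(bs$summary, path("bootstrap.csv"), row.names = FALSE)
    out$bootstrap <- path("bootstrap.csv")
  }

  # stage 4: covariate analysis
  log("[covariates] effect table and exposure sensitivity")
  write.csv(covariate_effect_table(fit$theta),
            path("covariate_effects.csv"), row.names = FALSE)
  out$covariate_effects <- path("covariate_effects.csv")
  write.csv(exposure_sensitivity(fit$theta),
            path("exposure_sensitivity.csv"), row.names = FALSE)
  out$sensitivity <- path("exposure_sensitivity.csv")
  invisible(out)
}
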