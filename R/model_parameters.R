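#' Fixed-effect parameter vector of the covariate model
#'
#' The eleven fixed effects of the final PopPK model: log-scale typical
#' values of the four disposition parameters and seven covariate
#' coefficients. Covariates enter clearance as log-normalized power terms
#' except baseline trastuzumab (TBL), which enters linearly on the log
#' scale; central volume carries a single body-weight power term.
#'
#' @param theta1 log typical clearance CL (CL in L/day)
#' @param theta2 log typical central volume Vc (L)
#' @param theta3 log distribution clearance Q (L/day)
#' @param theta4 log peripheral volume Vp (L)
#' @param theta5 body-weight exponent on Vc
#' @param theta6 body-weight exponent on CL
#' @param theta7 ECD exponent on CL
#' @param theta8 albumin exponent on CL
#' @param theta9 tumor-burden exponent on CL
#' @param theta10 linear TBL coefficient on log CL (per ug/mL)
#' @param theta11 AST exponent on CL
#' @return named numeric vector of class `theta_vector`
#' @export
theta_vector <- function(theta1, theta2, theta3, theta4, theta5 = 0,
                         theta6 = 0, theta7 = 0, theta8 = 0, theta9 = 0,
                         theta10 = 0, theta11 = 0) {
  th <- c(theta1 = theta1, theta2 = theta2, theta3 = theta3,
          theta4 = theta4, theta5 = theta5, theta6 = theta6,
          theta7 = theta7, theta8 = theta8, theta9 = theta9,
          theta10 = theta10, theta11 = theta11)
  if (!all(is.finite(th)))
    stop("all theta components must be finite")
  # exp(theta1..theta4) strictly positive and finite
  if (any(th[1:4] > 700))
    stop("theta1..theta4 imply non-finite typical parameters")
  structure(th, class = "theta_vector")
}

#' @rdname theta_vector
#' @param x numeric vector of length 11 (theta1..theta11)
#' @export
as_theta_vector <- function(x) {
  stopifnot(is.numeric(x), length(x) == 11L)
  do.call(theta_vector, as.list(unname(x)))
}

#' Published fixed-effect estimates of the final model
#'
#' Point estimates of the final PopPK model for the T-DM1 conjugate:
#' typical CL 0.676 L/day, Vc 3.127 L, Q 1.534 L/day, Vp 0.66 L; covariate
#' coefficients 0.596 (weight on Vc), 0.49 (weight on CL), 0.035 (ECD),
#' -0.423 (albumin), 0.052 (tumor burden), -0.002 (TBL, linear), 0.071
#' (AST).
#'
#' @return a [theta_vector()]
#' @export
reference_theta <- function() {
  theta_vector(theta1 = log(0.676), theta2 = log(3.127),
               theta3 = log(1.534), theta4 = log(0.66),
               theta5 = 0.596, theta6 = 0.49, theta7 = 0.035,
               theta8 = -0.423, theta9 = 0.052, theta10 = -0.002,
               theta11 = 0.071)
}

#' Inter-individual variance-covariance matrix
#'
#' Log-scale random effects on (CL, Vc, Q, Vp). Only the CL-Vc
#' covariance is modeled; all other off-diagonals are zero. Inputs are
#' standard deviations of the log-scale etas (so 0.191 corresponds to the
#' conventional "19.1% IIV").
#'
#' @param cl,vc,q,vp standard deviations of the log-scale random effects
#'   (a value of 0 removes that random effect)
#' @param cov_cl_vc covariance between the CL and Vc random effects
#' @return 4x4 matrix of class `omega_matrix`, rows/cols CL, Vc, Q, Vp
#' @export
omega_matrix <- function(cl = 0, vc = 0, q = 0, vp = 0, cov_cl_vc = 0) {
  stopifnot(cl >= 0, vc >= 0, q >= 0, vp >= 0)
  om <- diag(c(cl, vc, q, vp)^2)
  om[1, 2] <- om[2, 1] <- cov_cl_vc
  dimnames(om) <- list(c("CL", "Vc", "Q", "Vp"), c("CL", "Vc", "Q", "Vp"))
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("omega matrix is not positive semi-definite")
  structure(om, class = c("omega_matrix", "matrix"))
}

#' Published inter-individual variability of the final model
#'
#' IIV of 19.11% (CL), 11.66% (Vc), 180.8% (Q) and 74.50% (Vp) read as
#' 100 times the standard deviation of the log-scale eta, plus the CL-Vc
#' covariance 0.011.
#'
#' @param convention `"sd"` (default) reads a printed IIV of p percent as
#'   omega = p/100 on the log-SD scale; `"cv"` reads it as a log-normal CV,
#'   omega = sqrt(log(1 + (p/100)^2)).
#' @return an [omega_matrix()]
#' @export
reference_omega <- function(convention = c("sd", "cv")) {
  convention <- match.arg(convention)
  pct <- c(cl = 19.11, vc = 11.66, q = 180.8, vp = 74.50) / 100
  sds <- if (convention == "sd") pct else sqrt(log(1 + pct^2))
  omega_matrix(cl = sds[["cl"]], vc = sds[["vc"]], q = sds[["q"]],
               vp = sds[["vp"]], cov_cl_vc = 0.011)
}

#' Proportional residual-error model
#'
#' @param cv proportional residual coefficient of variation as a fraction
#'   (the published estimate is 0.3156)
#' @return list of class `sigma_model` with fields `cv` and `form`
#' @export
sigma_model <- function(cv) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv > 0)
  structure(list(cv = cv, form = "proportional"), class = "sigma_model")
}

#' @rdname sigma_model
#' @export
reference_sigma <- function() sigma_model(0.3156)

.sigma_cv <- function(sigma) {
  if (inherits(sigma, "sigma_model")) sigma$cv else as.numeric(sigma)
}

#' Baseline covariate vector
#'
#' The six baseline covariates of the final model with their units:
#' body weight (kg), HER2 shed extracellular domain ECD (ng/mL), serum
#' albumin (g/L), tumor burden TMBD (sum of longest lesion dimensions, cm),
#' baseline residual trastuzumab TBL (ug/mL) and AST (IU/L).
#'
#' @param WT,ECD,ALBU,TMBD,AST strictly positive covariate values
#' @param TBL non-negative baseline trastuzumab concentration
#' @return named numeric vector of class `covariate_vector`
#' @export
covariate_vector <- function(WT = 70, ECD = 25, ALBU = 41, TMBD = 9,
                             TBL = 0, AST = 27) {
  cv <- c(WT = WT, ECD = ECD, ALBU = ALBU, TMBD = TMBD, TBL = TBL, AST = AST)
  if (!all(is.finite(cv))) stop("covariates must be finite")
  if (any(cv[c("WT", "ECD", "ALBU", "TMBD", "AST")] <= 0))
    stop("WT, ECD, ALBU, TMBD and AST must be strictly positive ",
         "(a log is taken of each)")
  if (cv[["TBL"]] < 0) stop("TBL must be non-negative")
  structure(cv, class = "covariate_vector")
}

#' Reference covariate values used to normalize the covariate model
#'
#' 70 kg, ECD 25 ng/mL, albumin 41 g/L, tumor burden 9 cm, TBL 0 ug/mL,
#' AST 27 IU/L. These are the normalizing constants of the covariate model
#' and define the "typical patient".
#'
#' @return a [covariate_vector()]
#' @export
reference_covariates <- function() covariate_vector()

# per-subject design matrix mapping theta -> log(CL, Vc, Q, Vp)
.design_matrix <- function(cov) {
  cov <- covariate_vector(WT = cov[["WT"]], ECD = cov[["ECD"]],
                          ALBU = cov[["ALBU"]], TMBD = cov[["TMBD"]],
                          TBL = cov[["TBL"]], AST = cov[["AST"]])
  D <- matrix(0, 4, 11)
  D[1, 1] <- 1
  D[1, 6] <- log(cov[["WT"]] / 70)
  D[1, 7] <- log(cov[["ECD"]] / 25)
  D[1, 8] <- log(cov[["ALBU"]] / 41)
  D[1, 9] <- log(cov[["TMBD"]] / 9)
  D[1, 10] <- cov[["TBL"]]
  D[1, 11] <- log(cov[["AST"]] / 27)
  D[2, 2] <- 1
  D[2, 5] <- log(cov[["WT"]] / 70)
  D[3, 3] <- 1
  D[4, 4] <- 1
  D
}

#' Read or write a flat model-parameter configuration file
#'
#' Serializes the full parameter set as a flat YAML mapping with keys
#' `theta1`..`theta11`, `omega_cl`, `omega_vc`, `omega_q`, `omega_vp`
#' (log-scale SDs), `omega_cl_vc` (covariance) and `sigma_prop`
#' (proportional CV). The published estimates ship with the package:
#' `system.file("extdata", "tdm1_final_model.yaml", package = "tdm1popk")`.
#'
#' @param theta a [theta_vector()]
#' @param omega an [omega_matrix()]
#' @param sigma a [sigma_model()] or plain CV
#' @param path file path
#' @return `read_model_config()` returns `list(theta, omega, sigma)`
#' @export
write_model_config <- function(theta, omega, sigma, path) {
  sds <- sqrt(diag(omega))
  x <- c(as.list(unclass(theta)),
         list(omega_cl = sds[[1]], omega_vc = sds[[2]], omega_q = sds[[3]],
              omega_vp = sds[[4]], omega_cl_vc = omega[1, 2],
              sigma_prop = .sigma_cv(sigma)))
  yaml::write_yaml(lapply(x, as.numeric), path, precision = 12)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c(paste0("theta", 1:11), "omega_cl", "omega_vc", "omega_q",
            "omega_vp", "omega_cl_vc", "sigma_prop")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("model config is missing keys: ",
                         paste(miss, collapse = ", "))
  list(theta = as_theta_vector(unlist(x[paste0("theta", 1:11)])),
       omega = omega_matrix(cl = x$omega_cl, vc = x$omega_vc, q = x$omega_q,
                            vp = x$omega_vp, cov_cl_vc = x$omega_cl_vc),
       sigma = sigma_model(x$sigma_prop))
}
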