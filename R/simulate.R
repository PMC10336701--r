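#' Configuration for simulating a surrogacy meta-analysis dataset
#'
#' True study effects follow the bivariate random-effects structure the
#' models assume: the true surrogate effect of study i is
#' `delta1_i ~ N(eta1, tau1^2)` and the true final-outcome effect is
#' `delta2_i | delta1_i ~ N(lambda0 + lambda1 * delta1_i, psi2^2)`.
#' The two parameterisations of the between-studies model are linked by
#' `lambda1 = rho * tau2 / tau1` and `psi2^2 = tau2^2 - lambda1^2 * tau1^2`;
#' supply either `(tau2, rho)` or `(lambda1, psi2)` (or `(tau2, lambda1)`,
#' which may be inconsistent and is checked) and the rest is derived.
#'
#' Non-randomized studies receive additive study-level bias on each
#' outcome: comparative real-world studies draw
#' `alpha_ji ~ N(alpha_j, sigma_alpha_j^2)` and matched single-arm studies
#' `beta_ji ~ N(beta_j, sigma_beta_j^2)` (j = 1 surrogate, 2 final);
#' randomized trials are unbiased. Observed effects add bivariate-normal
#' within-study error with standard errors sampled uniformly on `se_range`
#' and correlation `rho_w`.
#'
#' Defaults mirror a small evidence base of antiangiogenic therapy trials
#' in metastatic colorectal cancer: 7 RCTs, 4 comparative and 2 matched
#' single-arm real-world studies; a pooled log hazard ratio on the
#' surrogate of about -0.36 with between-studies SDs 0.20/0.16 and
#' correlation 0.74; within-study standard errors between 0.1 and 0.3 and
#' within-study correlation 0.52.
#'
#' @param n_rct,n_crwe,n_srwe study counts by design.
#' @param eta1 mean true surrogate effect (logHR scale).
#' @param tau1 between-studies SD of the surrogate effect (> 0).
#' @param tau2 between-studies SD of the final-outcome effect.
#' @param rho between-studies correlation in \[-1, 1\].
#' @param lambda0 intercept of the latent regression.
#' @param lambda1 slope of the latent regression.
#' @param psi2 conditional SD of the final-outcome effect (>= 0).
#' @param se_range length-2 interval from which within-study standard
#'   errors are drawn uniformly.
#' @param rho_w within-study correlation in \[0, 1\].
#' @param alpha1,alpha2 mean bias of comparative real-world studies on the
#'   surrogate / final outcome.
#' @param beta1,beta2 mean bias of matched single-arm studies.
#' @param sigma_alpha1,sigma_alpha2,sigma_beta1,sigma_beta2 SDs of the
#'   corresponding bias distributions (>= 0).
#' @param seed integer master seed; each study draws from its own
#'   substream derived from it, so adding studies does not perturb
#'   existing ones.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_rct = 7L, n_crwe = 4L, n_srwe = 2L,
                       eta1 = -0.36, tau1 = 0.20,
                       tau2 = NULL, rho = NULL,
                       lambda0 = 0, lambda1 = NULL, psi2 = NULL,
                       se_range = c(0.1, 0.3), rho_w = 0.52,
                       alpha1 = 0, alpha2 = 0, beta1 = 0, beta2 = 0,
                       sigma_alpha1 = 0.1, sigma_alpha2 = 0.1,
                       sigma_beta1 = 0.1, sigma_beta2 = 0.1,
                       seed = 1L) {
  stopifnot(n_rct >= 0, n_crwe >= 0, n_srwe >= 0,
            n_rct + n_crwe + n_srwe >= 1,
            tau1 > 0, length(se_range) == 2L, all(se_range >= 0),
            se_range[1] <= se_range[2], rho_w >= 0, rho_w <= 1,
            sigma_alpha1 >= 0, sigma_alpha2 >= 0,
            sigma_beta1 >= 0, sigma_beta2 >= 0)
  if (is.null(tau2) && is.null(rho) && is.null(lambda1) && is.null(psi2)) {
    tau2 <- 0.16
    rho <- 0.74
  }
  if (!is.null(tau2) && !is.null(rho)) {
    if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
    if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
    lambda1_d <- rho * tau2 / tau1
    psi2sq <- tau2^2 - lambda1_d^2 * tau1^2
    if (!is.null(lambda1) && abs(lambda1 - lambda1_d) > 1e-8) {
      stop("inconsistent (tau2, rho) and lambda1 supplied", call. = FALSE)
    }
    lambda1 <- lambda1_d
  } else if (!is.null(lambda1) && !is.null(psi2)) {
    if (psi2 < 0) stop("psi2 must be >= 0", call. = FALSE)
    psi2sq <- psi2^2
    tau2 <- sqrt(psi2^2 + lambda1^2 * tau1^2)
    rho <- if (tau2 == 0) 0 else lambda1 * tau1 / tau2
  } else if (!is.null(tau2) && !is.null(lambda1)) {
    psi2sq <- tau2^2 - lambda1^2 * tau1^2
    if (psi2sq < 0) {
      stop("configuration error: derived psi2^2 = ", signif(psi2sq, 4),
           " < 0; tau2, lambda1 and tau1 are inconsistent", call. = FALSE)
    }
    rho <- if (tau2 == 0) 0 else lambda1 * tau1 / tau2
  } else {
    stop("supply either (tau2, rho) or (lambda1, psi2)", call. = FALSE)
  }
  psi2 <- sqrt(max(psi2sq, 0))
  structure(list(n_rct = as.integer(n_rct), n_crwe = as.integer(n_crwe),
                 n_srwe = as.integer(n_srwe),
                 eta1 = eta1, tau1 = tau1, tau2 = tau2, rho = rho,
                 lambda0 = lambda0, lambda1 = lambda1, psi2 = psi2,
                 se_range = se_range, rho_w = rho_w,
                 alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2,
                 sigma_alpha1 = sigma_alpha1, sigma_alpha2 = sigma_alpha2,
                 sigma_beta1 = sigma_beta1, sigma_beta2 = sigma_beta2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a meta-analytic dataset of correlated treatment effects
#'
#' Draws true effects from the between-studies surrogacy model, adds
#' design-specific bias for non-randomized studies, and observes both
#' effects with bivariate-normal within-study error (see [sim_config()]).
#' Latent truth (`delta1`, `delta2`, `bias1`, `bias2`) is kept alongside
#' the observed columns so that parameter-recovery tests can compare
#' against it.
#'
#' @param config a [sim_config()] object.
#' @return data frame with the study-effects columns of
#'   [validate_study_effects()] plus `delta1`, `delta2`, `bias1`, `bias2`.
#' @export
simulate_meta_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  designs <- rep(c("RCT", "cRWE", "sRWE"),
                 times = c(config$n_rct, config$n_crwe, config$n_srwe))
  n <- length(designs)
  # per-study substreams drawn from the master seed; the prefix property
  # of sample.int means adding studies never perturbs existing ones
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max, n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(study_seeds[i])
    se1 <- stats::runif(1, config$se_range[1], config$se_range[2])
    se2 <- stats::runif(1, config$se_range[1], config$se_range[2])
    delta1 <- stats::rnorm(1, config$eta1, config$tau1)
    delta2 <- stats::rnorm(1, config$lambda0 + config$lambda1 * delta1,
                           config$psi2)
    bias1 <- bias2 <- 0
    if (designs[i] == "cRWE") {
      bias1 <- stats::rnorm(1, config$alpha1, config$sigma_alpha1)
      bias2 <- stats::rnorm(1, config$alpha2, config$sigma_alpha2)
    } else if (designs[i] == "sRWE") {
      bias1 <- stats::rnorm(1, config$beta1, config$sigma_beta1)
      bias2 <- stats::rnorm(1, config$beta2, config$sigma_beta2)
    }
    z1 <- stats::rnorm(1)
    z2 <- stats::rnorm(1)
    y1 <- delta1 + bias1 + se1 * z1
    y2 <- delta2 + bias2 +
      se2 * (config$rho_w * z1 + sqrt(1 - config$rho_w^2) * z2)
    out[[i]] <- data.frame(
      study_id = sprintf("S%02d", i), design = designs[i],
      y1 = y1, se1 = se1, y2 = y2, se2 = se2, rho_w = config$rho_w,
      delta1 = delta1, delta2 = delta2, bias1 = bias1, bias2 = bias2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated dataset as observed-effects and truth CSV files
#'
#' @param data output of [simulate_meta_dataset()].
#' @param effects_path path for the observed study-effects CSV.
#' @param truth_path optional path for the latent-truth CSV
#'   (`study_id`, `delta1`, `delta2`, `bias1`, `bias2`).
#' @return `effects_path`, invisibly.
#' @export
write_meta_dataset <- function(data, effects_path, truth_path = NULL) {
  write_study_effects(
    data[, c("study_id", "design", "y1", "se1", "y2", "se2", "rho_w")],
    effects_path)
  if (!is.null(truth_path)) {
    utils::write.csv(
      data[, c("study_id", "delta1", "delta2", "bias1", "bias2")],
      truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(effects_path)
}

#' Simulate one survival arm with exponential event and censoring times
#'
#' Event times are exponential with the given hazard; censoring combines
#' an (optional) independent exponential with an administrative cut-off.
#' Returns both the patient-level records and the exact Kaplan-Meier step
#' coordinates with a numbers-at-risk table, i.e., the digitized inputs
#' the reconstruction stage consumes.
#'
#' @param n_patients number of patients (>= 2).
#' @param hazard event hazard rate (> 0, events per time unit).
#' @param censor_rate exponential censoring rate (0 = none).
#' @param admin_cutoff administrative censoring time (`Inf` = none).
#' @param risk_interval spacing of the numbers-at-risk table.
#' @param seed integer seed.
#' @param arm_id label carried through to the outputs.
#' @return list with `ipd` (data frame `time`, `event`, `arm`) and `km`
#'   (a [km_dataset()]).
#' @export
simulate_survival_arm <- function(n_patients, hazard, censor_rate = 0,
                                  admin_cutoff = Inf, risk_interval = 1,
                                  seed = 1L, arm_id = "arm") {
  stopifnot(n_patients >= 2, hazard > 0, censor_rate >= 0,
            admin_cutoff > 0, risk_interval > 0)
  set.seed(seed)
  t_event <- stats::rexp(n_patients, hazard)
  t_cens <- if (censor_rate > 0) stats::rexp(n_patients, censor_rate)
            else rep(Inf, n_patients)
  t_cens <- pmin(t_cens, admin_cutoff)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  ipd <- data.frame(time = time, event = event, arm = arm_id,
                    stringsAsFactors = FALSE)
  km <- km_estimate(ipd, risk_interval = risk_interval, arm_id = arm_id)
  list(ipd = ipd, km = km)
}

# Default centres and jitter half-widths for the five matching covariates,
# typical of chemotherapy +/- antiangiogenic arms in metastatic
# colorectal cancer.
profile_defaults <- function() {
  list(centers = c(treatment_line = 1.3, age = 63,
                   performance_score = 0.8, tumor_location = 0.65,
                   female = 0.40),
       jitter = c(treatment_line = 0.3, age = 5,
                  performance_score = 0.3, tumor_location = 0.15,
                  female = 0.10))
}

#' Simulate aggregate covariate profiles for single-arm studies
#'
#' Generates study-level values of the five matching covariates
#' (current mean treatment line, median age, mean performance score,
#' proportion with colon primary, proportion female), each drawn
#' uniformly around a centre and clamped to the scaling range of
#' [covariate_spec()]. With `jitter = 0` all profiles are identical, so
#' all pairwise distances downstream are zero.
#'
#' @param n_treat,n_ctrl numbers of treatment-like and control-like
#'   profiles (>= 1).
#' @param seed integer seed.
#' @param centers named numeric vector of covariate centres.
#' @param jitter named numeric vector of uniform half-widths, or a single
#'   number recycled to all covariates.
#' @return data frame with `study_id`, `role`, and one column per
#'   covariate.
#' @export
simulate_covariate_profiles <- function(n_treat, n_ctrl, seed = 1L,
                                        centers = NULL, jitter = NULL) {
  stopifnot(n_treat >= 1, n_ctrl >= 1)
  def <- profile_defaults()
  if (is.null(centers)) centers <- def$centers
  if (is.null(jitter)) jitter <- def$jitter
  if (length(jitter) == 1L) {
    jitter <- stats::setNames(rep(jitter, length(centers)), names(centers))
  }
  spec <- covariate_spec()
  set.seed(seed)
  n <- n_treat + n_ctrl
  role <- rep(c("treatment", "control"), c(n_treat, n_ctrl))
  ids <- c(sprintf("T%02d", seq_len(n_treat)),
           sprintf("C%02d", seq_len(n_ctrl)))
  prof <- data.frame(study_id = ids, role = role,
                     stringsAsFactors = FALSE)
  for (cv in spec$name) {
    lo <- spec$min[spec$name == cv]
    hi <- spec$max[spec$name == cv]
    x <- centers[[cv]] + stats::runif(n, -jitter[[cv]], jitter[[cv]])
    prof[[cv]] <- pmin(pmax(x, lo), hi)
  }
  prof
}
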