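#' Prior configuration for the surrogacy models
#'
#' All models use vague normal priors N(0, 10^4) on location parameters
#' (the per-study true surrogate effects in the Daniels-Hughes model, the
#' regression intercept and slope, the pooled surrogate-effect mean, and
#' the bias-term means), uniform priors on standard deviations, and a
#' Uniform(-1, 1) prior on the between-studies correlation.
#'
#' The within-study correlation of each study's two effect estimates is
#' rarely reported; by default each study with unknown `rho_w` receives an
#' independent Uniform(0, 1) prior. Setting `rho_w_fixed` (e.g., to the
#' bootstrap value 0.52) fixes it for every study, a standard sensitivity
#' analysis. The wider `Uniform(0, 100)` sensitivity priors on the
#' conditional and between-studies standard deviations are obtained with
#' `psi2_upper = 100` / `tau_upper = 100`.
#'
#' @param location_sd prior standard deviation of the normal priors on
#'   location parameters (default 100, i.e., variance 10^4).
#' @param psi2_upper upper bound of the uniform prior on the conditional
#'   standard deviation psi2 (Daniels-Hughes model).
#' @param tau_upper upper bound of the uniform priors on the
#'   between-studies standard deviations tau1, tau2 (BRMA PNF).
#' @param bias_sd_upper upper bound of the uniform priors on the bias-term
#'   standard deviations sigma_alpha1/2, sigma_beta1/2.
#' @param bias_mean_sd prior standard deviation of the normal priors on
#'   the bias-term means alpha1/2, beta1/2 (default: `location_sd`).
#' @param rho_w_fixed optional fixed within-study correlation in \[0, 1\]
#'   applied to every study; `NULL` (default) keeps per-study priors.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(location_sd = 100, psi2_upper = 2, tau_upper = 2,
                         bias_sd_upper = 2, bias_mean_sd = location_sd,
                         rho_w_fixed = NULL) {
  stopifnot(location_sd > 0, psi2_upper > 0, tau_upper > 0,
            bias_sd_upper > 0, bias_mean_sd > 0)
  if (!is.null(rho_w_fixed)) {
    stopifnot(is.numeric(rho_w_fixed), length(rho_w_fixed) == 1L,
              rho_w_fixed >= 0, rho_w_fixed <= 1)
  }
  structure(list(location_sd = location_sd,
                 psi2_upper = psi2_upper,
                 tau_upper = tau_upper,
                 bias_sd_upper = bias_sd_upper,
                 bias_mean_sd = bias_mean_sd,
                 rho_w_fixed = rho_w_fixed),
            class = "prior_config")
}

#' Draw from the prior distributions of a configuration
#'
#' Monte-Carlo draws from the marginal priors, used for prior-predictive
#' checks that the configured supports (e.g., psi2 in \[0, 2\], rho in
#' \[-1, 1\], rho_w in \[0, 1\]) are the ones actually sampled, including
#' under the sensitivity switches.
#'
#' @param priors a [prior_config()] object.
#' @param n number of draws.
#' @return data frame with one column per hyperparameter.
#' @export
sample_prior <- function(priors = prior_config(), n = 1000L) {
  stopifnot(inherits(priors, "prior_config"), n >= 1)
  data.frame(
    lambda0 = stats::rnorm(n, 0, priors$location_sd),
    lambda1 = stats::rnorm(n, 0, priors$location_sd),
    eta1 = stats::rnorm(n, 0, priors$location_sd),
    psi2 = stats::runif(n, 0, priors$psi2_upper),
    tau1 = stats::runif(n, 0, priors$tau_upper),
    tau2 = stats::runif(n, 0, priors$tau_upper),
    rho = stats::runif(n, -1, 1),
    rho_w = if (is.null(priors$rho_w_fixed)) stats::runif(n, 0, 1)
            else rep(priors$rho_w_fixed, n),
    alpha1 = stats::rnorm(n, 0, priors$bias_mean_sd),
    alpha2 = stats::rnorm(n, 0, priors$bias_mean_sd),
    beta1 = stats::rnorm(n, 0, priors$bias_mean_sd),
    beta2 = stats::rnorm(n, 0, priors$bias_mean_sd),
    sigma_alpha1 = stats::runif(n, 0, priors$bias_sd_upper),
    sigma_alpha2 = stats::runif(n, 0, priors$bias_sd_upper),
    sigma_beta1 = stats::runif(n, 0, priors$bias_sd_upper),
    sigma_beta2 = stats::runif(n, 0, priors$bias_sd_upper)
  )
}
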