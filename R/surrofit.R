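#' Map bivariate random-effects parameters to the product-normal scale
#'
#' The between-studies model can be written either with heterogeneity
#' SDs `(tau1, tau2)` and correlation `rho`, or as a product of
#' conditionals with slope and conditional variances. The exact map is
#' `lambda1 = rho * tau2 / tau1`, `psi1^2 = tau1^2`,
#' `psi2^2 = tau2^2 - lambda1^2 * tau1^2`; `|rho| <= 1` guarantees
#' `psi2^2 >= 0`, with equality exactly at `rho = +/-1` (perfect
#' trial-level surrogacy).
#'
#' @param tau1 between-studies SD on the surrogate effect (> 0).
#' @param tau2 between-studies SD on the final-outcome effect (>= 0).
#' @param rho between-studies correlation in \[-1, 1\].
#' @return data frame with columns `lambda1`, `psi1_sq`, `psi2_sq`
#'   (vectorized over the inputs).
#' @export
transform_brma_params <- function(tau1, tau2, rho) {
  if (any(tau1 <= 0)) stop("tau1 must be > 0", call. = FALSE)
  if (any(tau2 < 0)) stop("tau2 must be >= 0", call. = FALSE)
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]", call. = FALSE)
  lambda1 <- rho * tau2 / tau1
  psi2_sq <- tau2^2 - lambda1^2 * tau1^2
  psi2_sq[abs(rho) == 1] <- 0
  data.frame(lambda1 = lambda1, psi1_sq = tau1^2, psi2_sq = psi2_sq)
}

# --- JAGS model code ------------------------------------------------------

# Shared within-study likelihood: the bivariate normal for (Y1, Y2) is
# written as Y1 and Y2 | Y1, which lets JAGS treat a missing Y2 (the
# cross-validation case) as an ordinary unobserved node.
jags_within_block <- function(bias) {
  mu1 <- if (bias) "delta1[i] + b1[i]" else "delta1[i]"
  mu2 <- if (bias) "delta2[i] + b2[i]" else "delta2[i]"
  paste0(
    "    mu1[i] <- ", mu1, "\n",
    "    mu2[i] <- ", mu2, "\n",
    "    Y1[i] ~ dnorm(mu1[i], prec1[i])\n",
    "    prec1[i] <- pow(sigma1[i], -2)\n",
    "    condmu2[i] <- mu2[i] + rhow[i] * sigma2[i] / sigma1[i] * (Y1[i] - mu1[i])\n",
    "    prec2[i] <- pow(sigma2[i], -2) / (1 - pow(rhow[i], 2))\n",
    "    Y2[i] ~ dnorm(condmu2[i], prec2[i])\n",
    "    rhow[i] ~ dunif(0, 1)\n")
}

jags_bias_block <- function() {
  paste0(
    "    alpha1i[i] ~ dnorm(alpha1, prec.sa1)\n",
    "    alpha2i[i] ~ dnorm(alpha2, prec.sa2)\n",
    "    beta1i[i] ~ dnorm(beta1, prec.sb1)\n",
    "    beta2i[i] ~ dnorm(beta2, prec.sb2)\n",
    "    b1[i] <- equals(des[i], 2) * alpha1i[i] + equals(des[i], 3) * beta1i[i]\n",
    "    b2[i] <- equals(des[i], 2) * alpha2i[i] + equals(des[i], 3) * beta2i[i]\n")
}

jags_model_code <- function(model) {
  bias <- model == "brma_bias"
  between <- if (model == "dh") {
    paste0(
      "    delta1[i] ~ dnorm(0, prec.loc)\n",
      "    delta2[i] ~ dnorm(lambda0 + lambda1 * delta1[i], prec.psi2)\n")
  } else {
    paste0(
      "    delta1[i] ~ dnorm(eta1, prec.tau1)\n",
      "    eta2[i] <- lambda0 + lambda1 * delta1[i]\n",
      "    delta2[i] ~ dnorm(eta2[i], prec.psi2)\n")
  }
  hyper <- if (model == "dh") {
    paste0(
      "  lambda0 ~ dnorm(0, prec.loc)\n",
      "  lambda1 ~ dnorm(0, prec.loc)\n",
      "  psi2 ~ dunif(0, psi2.upper)\n",
      "  prec.psi2 <- pow(psi2, -2)\n",
      "  psi2sq <- pow(psi2, 2)\n")
  } else {
    paste0(
      "  eta1 ~ dnorm(0, prec.loc)\n",
      "  lambda0 ~ dnorm(0, prec.loc)\n",
      "  tau1 ~ dunif(0, tau.upper)\n",
      "  tau2 ~ dunif(0, tau.upper)\n",
      "  rho ~ dunif(-1, 1)\n",
      "  prec.tau1 <- pow(tau1, -2)\n",
      "  lambda1 <- rho * tau2 / tau1\n",
      "  psi2sq <- pow(tau2, 2) * (1 - pow(rho, 2))\n",
      "  prec.psi2 <- 1 / psi2sq\n",
      "  d1 <- eta1\n",
      "  d2 <- lambda0 + lambda1 * eta1\n",
      "  R2 <- pow(rho, 2)\n")
  }
  bias_hyper <- if (bias) {
    paste0(
      "  alpha1 ~ dnorm(0, prec.bias.mean)\n",
      "  alpha2 ~ dnorm(0, prec.bias.mean)\n",
      "  beta1 ~ dnorm(0, prec.bias.mean)\n",
      "  beta2 ~ dnorm(0, prec.bias.mean)\n",
      "  sig.alpha1 ~ dunif(0, bias.sd.upper)\n",
      "  sig.alpha2 ~ dunif(0, bias.sd.upper)\n",
      "  sig.beta1 ~ dunif(0, bias.sd.upper)\n",
      "  sig.beta2 ~ dunif(0, bias.sd.upper)\n",
      "  prec.sa1 <- pow(sig.alpha1, -2)\n",
      "  prec.sa2 <- pow(sig.alpha2, -2)\n",
      "  prec.sb1 <- pow(sig.beta1, -2)\n",
      "  prec.sb2 <- pow(sig.beta2, -2)\n")
  } else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    between,
    if (bias) jags_bias_block() else "",
    jags_within_block(bias),
    "  }\n",
    hyper, bias_hyper,
    "}\n")
}

scalar_params <- function(model) {
  switch(model,
    dh = c("lambda0", "lambda1", "psi2sq"),
    brma = c("d1", "d2", "rho", "tau1", "tau2", "lambda0", "lambda1",
             "psi2sq", "R2"),
    brma_bias = c("d1", "d2", "rho", "tau1", "tau2", "lambda0", "lambda1",
                  "psi2sq", "R2", "alpha1", "alpha2", "beta1", "beta2",
                  "sig.alpha1", "sig.alpha2", "sig.beta1", "sig.beta2"))
}

# Parameters reported as medians by default (right-skewed posteriors).
median_params <- c("psi2sq", "R2", "tau1", "tau2",
                   "sig.alpha1", "sig.alpha2", "sig.beta1", "sig.beta2")

#' Fit a Bayesian bivariate surrogacy model
#'
#' Fits one of three models for the trial-level association between
#' treatment effects on a surrogate endpoint (`y1`, a log hazard ratio)
#' and a final outcome (`y2`) by MCMC (JAGS):
#'
#' \describe{
#'   \item{`"dh"`}{the Daniels-Hughes model — independent fixed true
#'     surrogate effects, and a linear conditional model
#'     `delta2_i | delta1_i ~ N(lambda0 + lambda1 * delta1_i, psi2^2)`;}
#'   \item{`"brma"`}{bivariate random-effects meta-analysis in the
#'     product normal formulation — exchangeable true effects
#'     `delta1_i ~ N(eta1, tau1^2)` with the same conditional
#'     regression, where `lambda1 = rho * tau2 / tau1` and
#'     `psi2^2 = tau2^2 - lambda1^2 * tau1^2` make the between-studies
#'     correlation `rho` and `R^2 = rho^2` explicit;}
#'   \item{`"brma_bias"`}{the BRMA PNF with additive study-level bias
#'     terms in the within-study model of non-randomized studies:
#'     comparative real-world studies get `alpha_ji ~ N(alpha_j,
#'     sigma_alpha_j^2)` and matched single-arm studies `beta_ji ~
#'     N(beta_j, sigma_beta_j^2)` on outcome j.}
#' }
#'
#' In every model the observed effects are bivariate normal around the
#' (possibly bias-shifted) true effects with the study's standard errors
#' and within-study correlation; unknown within-study correlations get
#' independent Uniform(0, 1) priors. A study with missing `y2` is
#' treated as missing at random and its true final-outcome effect is
#' imputed by the sampler — this is how cross-validation predictions are
#' produced.
#'
#' Convergence is assessed by split R-hat (< 1.05) and effective sample
#' size (> 400) on the reported scalar parameters; failures flag the
#' fit with a warning but never silently alter it.
#'
#' @param data study-effects data frame (see [validate_study_effects()]);
#'   at least 3 studies with positive SEs.
#' @param model `"dh"`, `"brma"`, or `"brma_bias"`.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param monitor_extra additional node names to monitor.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `surrofit` with elements `draws` (matrix
#'   of pooled posterior draws), `chains` (a [coda::mcmc.list]),
#'   `summary` (parameter summary table), `diagnostics` (split R-hat and
#'   effective sample size per reported parameter), `converged`, `data`,
#'   `model`, `priors`, `mcmc`.
#' @seealso [fit_dh()], [fit_brma_pnf()], [fit_brma_pnf_bias()],
#'   [evaluate_criteria()], [crossvalidate()]
#' @export
surrofit <- function(data, model = c("dh", "brma", "brma_bias"),
                     priors = prior_config(), mcmc = mcmc_settings(),
                     monitor_extra = NULL, quiet = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "prior_config"),
            inherits(mcmc, "mcmc_settings"))
  data <- validate_study_effects(data)
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 studies", call. = FALSE)
  if (model == "brma_bias" && all(data$design == "RCT")) {
    stop("all studies are RCTs; the bias-adjusted model needs at least ",
         "one non-RCT study - use model = 'brma' instead", call. = FALSE)
  }
  rhow <- if (!is.null(priors$rho_w_fixed)) {
    rep(priors$rho_w_fixed, n)
  } else {
    data$rho_w
  }
  jdata <- list(N = n, Y1 = data$y1, Y2 = data$y2,
                sigma1 = data$se1, sigma2 = data$se2,
                rhow = rhow,
                prec.loc = priors$location_sd^-2)
  if (model == "dh") {
    jdata$psi2.upper <- priors$psi2_upper
  } else {
    jdata$tau.upper <- priors$tau_upper
  }
  if (model == "brma_bias") {
    jdata$des <- match(data$design, STUDY_DESIGNS)
    jdata$prec.bias.mean <- priors$bias_mean_sd^-2
    jdata$bias.sd.upper <- priors$bias_sd_upper
  }

  y2_fill <- ifelse(is.na(data$y2), data$y1, data$y2)
  base_inits <- list(delta1 = data$y1, delta2 = y2_fill,
                     lambda0 = 0)
  if (model == "dh") {
    base_inits$lambda1 <- 0
    base_inits$psi2 <- min(0.1, priors$psi2_upper / 2)
  } else {
    base_inits$eta1 <- mean(data$y1)
    base_inits$tau1 <- min(0.2, priors$tau_upper / 2)
    base_inits$tau2 <- min(0.2, priors$tau_upper / 2)
    base_inits$rho <- 0
  }
  if (model == "brma_bias") {
    base_inits$alpha1 <- 0; base_inits$alpha2 <- 0
    base_inits$beta1 <- 0; base_inits$beta2 <- 0
    s0 <- min(0.1, priors$bias_sd_upper / 2)
    base_inits$sig.alpha1 <- s0; base_inits$sig.alpha2 <- s0
    base_inits$sig.beta1 <- s0; base_inits$sig.beta2 <- s0
  }
  rhow_init <- ifelse(is.na(rhow), 0.5, NA_real_)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    ini <- base_inits
    if (any(is.na(rhow))) ini$rhow <- rhow_init
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- mcmc$seed + (ch - 1L)
    ini
  })

  monitors <- unique(c(scalar_params(model), "delta1", "delta2",
                       monitor_extra))
  jm <- rjags::jags.model(textConnection(jags_model_code(model)),
                          data = jdata, inits = inits,
                          n.chains = mcmc$n_chains, quiet = quiet)
  if (mcmc$n_burnin > 0) {
    stats::update(jm, n.iter = mcmc$n_burnin,
                  progress.bar = if (quiet) "none" else "text")
  }
  chains <- rjags::coda.samples(jm, variable.names = monitors,
                                n.iter = mcmc$n_iter - mcmc$n_burnin,
                                thin = mcmc$thin,
                                progress.bar = if (quiet) "none" else "text")
  draws <- as.matrix(chains)

  report <- intersect(scalar_params(model), colnames(draws))
  diag <- data.frame(
    parameter = report,
    rhat = vapply(report, function(p) {
      split_rhat(lapply(chains, function(ch) as.numeric(ch[, p])))
    }, numeric(1)),
    ess = vapply(report, function(p) {
      as.numeric(coda::effectiveSize(chains[, p]))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  converged <- all(is.finite(diag$rhat) & diag$rhat < 1.05) &&
    all(diag$ess > 400)
  if (!converged) {
    warning("MCMC convergence not established (split R-hat >= 1.05 or ",
            "ESS <= 400 for some reported parameter); inspect ",
            "$diagnostics and consider longer chains", call. = FALSE)
  }

  summ <- do.call(rbind, lapply(report, function(p) {
    summarize_posterior(draws, p,
                        style = if (p %in% median_params) "median"
                                else "mean")
  }))
  structure(list(draws = draws, chains = chains, summary = summ,
                 diagnostics = diag, converged = converged,
                 data = data, model = model, priors = priors,
                 mcmc = mcmc, call = match.call()),
            class = "surrofit")
}

#' @rdname surrofit
#' @param ... passed on to [surrofit()].
#' @export
fit_dh <- function(data, ...) surrofit(data, model = "dh", ...)

#' @rdname surrofit
#' @export
fit_brma_pnf <- function(data, ...) surrofit(data, model = "brma", ...)

#' @rdname surrofit
#' @export
fit_brma_pnf_bias <- function(data, ...) {
  surrofit(data, model = "brma_bias", ...)
}

# Split R-hat: each chain is halved, then the standard potential
# scale-reduction factor is computed over the split chains. Works for a
# single chain.
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    m <- floor(length(x) / 2)
    list(x[seq_len(m)], x[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.surrofit <- function(x, digits = 3, ...) {
  labels <- c(dh = "Daniels-Hughes",
              brma = "BRMA (product normal formulation)",
              brma_bias = "BRMA PNF with design-specific bias adjustment")
  cat("Bayesian surrogacy model:", labels[[x$model]], "\n")
  tab <- table(factor(x$data$design, levels = STUDY_DESIGNS))
  cat("Studies:", nrow(x$data),
      sprintf("(%s)", paste(names(tab), tab, sep = "=", collapse = ", ")),
      "\n")
  cat(sprintf("MCMC: %d chains x %d iterations (%d burn-in); %s\n",
              x$mcmc$n_chains, x$mcmc$n_iter, x$mcmc$n_burnin,
              if (x$converged) "converged" else "CONVERGENCE NOT ESTABLISHED"))
  s <- x$summary
  s$point <- signif(s$point, digits)
  s$cri_low <- signif(s$cri_low, digits)
  s$cri_high <- signif(s$cri_high, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.surrofit <- function(object, ...) object$summary

#' @export
coef.surrofit <- function(object, ...) {
  stats::setNames(object$summary$point, object$summary$parameter)
}

#' Posterior of the surrogacy line at new surrogate-effect values
#'
#' Evaluates the conditional mean of the true final-outcome effect,
#' `lambda0 + lambda1 * delta1`, over the posterior draws at each value
#' of `newdata$y1`. This is the fitted surrogacy line; for a full
#' leave-one-out prediction of a new study's observed effect (which adds
#' between-study conditional variance and sampling noise) use
#' [loo_predict()].
#'
#' @param object a [surrofit] object.
#' @param newdata data frame with a `y1` column (default: the fitted
#'   studies).
#' @param ... unused.
#' @return data frame with `y1`, `mean`, `cri_low`, `cri_high`.
#' @export
predict.surrofit <- function(object, newdata = NULL, ...) {
  y1 <- if (is.null(newdata)) object$data$y1 else newdata$y1
  l0 <- object$draws[, "lambda0"]
  l1 <- object$draws[, "lambda1"]
  out <- t(vapply(y1, function(v) {
    line <- l0 + l1 * v
    c(mean(line), stats::quantile(line, c(0.025, 0.975), names = FALSE))
  }, numeric(3)))
  data.frame(y1 = y1, mean = out[, 1], cri_low = out[, 2],
             cri_high = out[, 3])
}

#' @export
residuals.surrofit <- function(object, ...) {
  idx <- seq_len(nrow(object$data))
  d2 <- vapply(idx, function(i) {
    mean(object$draws[, sprintf("delta2[%d]", i)])
  }, numeric(1))
  stats::setNames(object$data$y2 - d2, object$data$study_id)
}

#' Posterior-predictive replicates of the observed effects
#'
#' For each replicate a posterior draw is selected and new observed
#' effects are generated from the within-study model around that draw's
#' true effects — a posterior-predictive check of the fitted model.
#'
#' @param object a [surrofit] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames with columns `study_id`, `y1`, `y2`.
#' @export
simulate.surrofit <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  n <- nrow(object$data)
  picks <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  rw <- ifelse(is.na(object$data$rho_w), 0.5, object$data$rho_w)
  lapply(picks, function(r) {
    d1 <- object$draws[r, sprintf("delta1[%d]", seq_len(n))]
    d2 <- object$draws[r, sprintf("delta2[%d]", seq_len(n))]
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    data.frame(study_id = object$data$study_id,
               y1 = d1 + object$data$se1 * z1,
               y2 = d2 + object$data$se2 *
                 (rw * z1 + sqrt(1 - rw^2) * z2))
  })
}

#' Scatter plot of observed effects with the fitted surrogacy line
#'
#' @param x a [surrofit] object.
#' @param ... passed to [plot()].
#' @export
plot.surrofit <- function(x, ...) {
  d <- x$data
  grid <- data.frame(y1 = seq(min(d$y1) - 0.1, max(d$y1) + 0.1,
                              length.out = 50))
  line <- predict.surrofit(x, grid)
  plot(d$y1, d$y2, pch = c(RCT = 19, cRWE = 15, sRWE = 17)[d$design],
       xlab = "logHR on surrogate outcome",
       ylab = "logHR on final outcome", ...)
  graphics::arrows(d$y1, d$y2 - 1.96 * d$se2, d$y1, d$y2 + 1.96 * d$se2,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::lines(line$y1, line$mean, lwd = 2)
  graphics::lines(line$y1, line$cri_low, lty = 2)
  graphics::lines(line$y1, line$cri_high, lty = 2)
  invisible(x)
}

#' Evaluate the surrogacy criteria from posterior summaries
#'
#' Applies the standard criteria for a perfect trial-level surrogate:
#' the intercept credible interval contains zero (no effect on the
#' surrogate implies no effect on the final outcome), the slope credible
#' interval excludes zero (there is an association), and the conditional
#' variance `psi2^2` is close to zero (its point estimate and interval
#' are reported, not thresholded). For the random-effects models the
#' between-studies correlation is also reported, `rho = +/-1`
#' corresponding to perfect surrogacy.
#'
#' @param summaries a [surrofit] object or a summary data frame with
#'   columns `parameter`, `point`, `cri_low`, `cri_high`.
#' @param model `"dh"` or `"brma"` (a `brma_bias` fit is reported the
#'   same way as `brma`).
#' @return data frame of class `criteria_report` with columns
#'   `criterion`, `satisfied` (NA for reported-only criteria), `detail`.
#' @export
evaluate_criteria <- function(summaries,
                              model = c("dh", "brma", "brma_bias")) {
  if (inherits(summaries, "surrofit")) {
    model <- summaries$model
    summaries <- summaries$summary
  }
  model <- match.arg(model)
  get <- function(p) {
    row <- summaries[summaries$parameter == p, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("parameter '", p, "' not found in the summaries", call. = FALSE)
    }
    row
  }
  l0 <- get("lambda0"); l1 <- get("lambda1"); p2 <- get("psi2sq")
  fmt <- function(r) sprintf("%.3g (95%% CrI %.3g, %.3g)",
                             r$point, r$cri_low, r$cri_high)
  out <- data.frame(
    criterion = c("intercept_zero", "slope_nonzero",
                  "conditional_variance_zero"),
    satisfied = c(l0$cri_low <= 0 && l0$cri_high >= 0,
                  l1$cri_low > 0 || l1$cri_high < 0,
                  NA),
    detail = c(paste0("lambda0 = ", fmt(l0)),
               paste0("lambda1 = ", fmt(l1)),
               paste0("psi2sq = ", fmt(p2),
                      "; closeness to zero reported, not thresholded")),
    stringsAsFactors = FALSE)
  if (model %in% c("brma", "brma_bias")) {
    rr <- get("rho")
    out <- rbind(out, data.frame(
      criterion = "correlation_perfect",
      satisfied = NA,
      detail = paste0("rho = ", fmt(rr),
                      "; perfect surrogacy at rho = +/-1")))
  }
  class(out) <- c("criteria_report", "data.frame")
  out
}
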