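#' Predict one study's final-outcome effect from all other studies
#'
#' Take-one-out prediction: the left-out study's observed effect on the
#' final outcome is treated as missing at random and the model is refit,
#' so the study contributes only its surrogate effect. The predicted
#' mean is the posterior mean of the study's true final-outcome effect;
#' the predictive variance adds the study's within-study sampling
#' variance, `sigma2i^2 + var(delta2_i | data)`. Two 95% predicted
#' intervals are returned: equal-tailed quantiles of posterior-predictive
#' draws (true-effect draws plus observation noise) and the normal
#' approximation `mean +/- 1.96 * sqrt(variance)`. The reported width
#' ratio uses the normal-approximation width over the observed Wald CI
#' width `2 * 1.96 * sigma2i`, so it is bounded below by 1 by
#' construction; the quantile-based ratio is reported alongside.
#'
#' @param data study-effects data frame.
#' @param model `"dh"`, `"brma"`, or `"brma_bias"`.
#' @param leave_out study id whose `y2` is withheld.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @return one-row data frame (class `prediction_record`) with the
#'   predicted mean, variance, both intervals, the observed effect and
#'   CI, the absolute discrepancy and the width ratios, plus a
#'   `converged` flag.
#' @export
loo_predict <- function(data, model = c("dh", "brma", "brma_bias"),
                        leave_out, priors = prior_config(),
                        mcmc = mcmc_settings()) {
  model <- match.arg(model)
  data <- validate_study_effects(data)
  i <- match(leave_out, data$study_id)
  if (is.na(i)) stop("unknown study id '", leave_out, "'", call. = FALSE)
  if (is.na(data$y1[i])) {
    stop("left-out study must have an observed surrogate effect",
         call. = FALSE)
  }
  if (sum(!is.na(data$y2[-i])) < 3L) {
    stop("need at least 3 remaining studies with observed y2",
         call. = FALSE)
  }
  y2_obs <- data$y2[i]
  se2 <- data$se2[i]
  data$y2[i] <- NA_real_
  fit <- withCallingHandlers(
    surrofit(data, model = model, priors = priors, mcmc = mcmc),
    warning = function(w) {
      if (grepl("convergence", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  d2 <- fit$draws[, sprintf("delta2[%d]", i)]
  pred_mean <- mean(d2)
  pred_var <- se2^2 + stats::var(d2)
  set.seed(mcmc$seed)
  ypred <- d2 + stats::rnorm(length(d2), 0, se2)
  qi <- stats::quantile(ypred, c(0.025, 0.975), names = FALSE)
  norm_half <- 1.96 * sqrt(pred_var)
  obs_half <- 1.96 * se2
  out <- data.frame(
    study_id = leave_out,
    model = model,
    y1 = data$y1[i],
    y2_obs = y2_obs,
    pred_mean = pred_mean,
    pred_var = pred_var,
    pi_low = qi[1], pi_high = qi[2],
    pi_low_norm = pred_mean - norm_half,
    pi_high_norm = pred_mean + norm_half,
    obs_low = y2_obs - obs_half, obs_high = y2_obs + obs_half,
    abs_discrepancy = abs(pred_mean - y2_obs),
    width_ratio = (2 * norm_half) / (2 * obs_half),
    width_ratio_q = (qi[2] - qi[1]) / (2 * obs_half),
    converged = fit$converged,
    stringsAsFactors = FALSE)
  class(out) <- c("prediction_record", "data.frame")
  out
}

#' Take-one-out cross-validation of surrogate-based predictions
#'
#' Repeats [loo_predict()] for every study in the dataset (each refit
#' uses the seed `mcmc$seed + study index`, so runs are independently
#' reproducible) and summarises accuracy as the median and range of the
#' absolute discrepancy between predicted and observed final-outcome
#' effects, and precision as the median and range of the ratio of the
#' predicted-interval width to the observed-CI width.
#'
#' @inheritParams loo_predict
#' @return an object of class `surro_cv` with elements `records` (one
#'   row per study), `summary`, `failed` (study ids whose refit errored),
#'   `model`.
#' @export
crossvalidate <- function(data, model = c("dh", "brma", "brma_bias"),
                          priors = prior_config(),
                          mcmc = mcmc_settings()) {
  model <- match.arg(model)
  data <- validate_study_effects(data)
  if (nrow(data) < 4L) stop("need at least 4 studies", call. = FALSE)
  records <- list()
  failed <- character(0)
  for (i in seq_len(nrow(data))) {
    mc_i <- mcmc_settings(n_iter = mcmc$n_iter, n_burnin = mcmc$n_burnin,
                          n_chains = mcmc$n_chains,
                          seed = mcmc$seed + i, thin = mcmc$thin)
    rec <- tryCatch(
      loo_predict(data, model, data$study_id[i], priors, mc_i),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failed <- c(failed, data$study_id[i])
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(failed) > 0) {
    warning("prediction failed for ", length(failed), " study(ies): ",
            paste(failed, collapse = ", "),
            "; summaries use the remaining studies", call. = FALSE)
  }
  records <- do.call(rbind, records)
  summarise <- function(x) {
    c(median = stats::median(x), min = min(x), max = max(x))
  }
  out <- list(records = records,
              summary = list(
                abs_discrepancy = summarise(records$abs_discrepancy),
                width_ratio = summarise(records$width_ratio),
                width_ratio_q = summarise(records$width_ratio_q)),
              failed = failed, model = model)
  class(out) <- "surro_cv"
  out
}

#' @export
print.surro_cv <- function(x, ...) {
  cat("Take-one-out cross-validation (", x$model, " model), ",
      nrow(x$records), " studies\n", sep = "")
  s <- x$summary
  cat(sprintf("  absolute discrepancy: median %.3g (range %.3g, %.3g)\n",
              s$abs_discrepancy["median"], s$abs_discrepancy["min"],
              s$abs_discrepancy["max"]))
  cat(sprintf("  predicted/observed width ratio: median %.3g (range %.3g, %.3g)\n",
              s$width_ratio["median"], s$width_ratio["min"],
              s$width_ratio["max"]))
  if (length(x$failed) > 0) {
    cat("  failed refits:", paste(x$failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export cross-validation records as a tidy forest-plot table
#'
#' One row per study with the observed CI and predicted interval on the
#' log hazard ratio scale, ready for plotting.
#'
#' @param cv a `surro_cv` object.
#' @return data frame with `study_id`, `y2_obs`, `obs_low`, `obs_high`,
#'   `pred_mean`, `pi_low`, `pi_high`.
#' @export
forest_table <- function(cv) {
  stopifnot(inherits(cv, "surro_cv"))
  cv$records[, c("study_id", "y2_obs", "obs_low", "obs_high",
                 "pred_mean", "pi_low", "pi_high")]
}
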