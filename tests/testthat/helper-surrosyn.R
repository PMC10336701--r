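# Shared fixtures and independent oracles used across the test files.

# Studies lying exactly on y2 = lambda0 + lambda1 * y1 with tiny
# within-study error, the deterministic limit of the surrogacy models.
make_line_data <- function(n = 20, lambda0 = 0.1, lambda1 = 0.7,
                           se = 1e-6, seed = 1, sd_y1 = 0.3,
                           mean_y1 = -0.4) {
  set.seed(seed)
  y1 <- rnorm(n, mean_y1, sd_y1)
  data.frame(study_id = sprintf("S%02d", seq_len(n)), design = "RCT",
             y1 = y1, se1 = se, y2 = lambda0 + lambda1 * y1, se2 = se,
             rho_w = NA_real_, stringsAsFactors = FALSE)
}

# Hand-rolled product-limit estimator (textbook definition), independent
# of survival::survfit.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  cur <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    cur <- cur * (1 - d / n_risk)
    surv[i] <- cur
  }
  data.frame(time = ut, surv = surv)
}

# Hand-coded Cox partial log-likelihood for a binary covariate with no
# tied event times, maximised numerically — the oracle for cox_loghr.
cox_oracle <- function(time, event, z) {
  stopifnot(!anyDuplicated(time[event == 1]))
  loglik <- function(beta) {
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      beta * z[i] - log(sum(exp(beta * z[risk])))
    }, numeric(1)))
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE)$maximum
}

# Short MCMC settings for tests; long enough for stable posterior means
# on the small fixtures used here.
test_mcmc <- function(seed = 1, n_iter = 8000, n_burnin = 2000,
                      n_chains = 2) {
  mcmc_settings(n_iter = n_iter, n_burnin = n_burnin,
                n_chains = n_chains, seed = seed)
}

# Maximum absolute deviation between a km_dataset's coordinates and the
# step function implied by a second km_dataset.
km_max_dev <- function(reference, estimate) {
  f <- stats::stepfun(estimate$coords$time, c(1, estimate$coords$surv))
  max(abs(f(reference$coords$time) - reference$coords$surv))
}
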