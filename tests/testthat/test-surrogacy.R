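test_that("the parameter transformation is exact and invertible", {
  got <- transform_brma_params(1, 1, 0.5)
  expect_equal(got$lambda1, 0.5)
  expect_equal(got$psi2_sq, 0.75)
  expect_equal(got$psi1_sq, 1)
  # perfect surrogacy limit is exact
  expect_identical(transform_brma_params(0.3, 0.7, 1)$psi2_sq, 0)
  expect_identical(transform_brma_params(0.3, 0.7, -1)$psi2_sq, 0)
  # inverse recovery on random valid inputs
  set.seed(71)
  tau1 <- runif(500, 0.05, 2); tau2 <- runif(500, 0, 2)
  rho <- runif(500, -1, 1)
  fwd <- transform_brma_params(tau1, tau2, rho)
  tau2_back <- sqrt(fwd$psi2_sq + fwd$lambda1^2 * tau1^2)
  rho_back <- ifelse(tau2_back > 0, fwd$lambda1 * tau1 / tau2_back, 0)
  expect_equal(tau2_back, tau2, tolerance = 1e-12)
  expect_equal(rho_back, rho, tolerance = 1e-12)
  expect_error(transform_brma_params(0, 1, 0.5), "tau1")
})

test_that("prior sampling respects the configured supports, including sensitivity switches", {
  p <- sample_prior(prior_config(), n = 2000)
  expect_true(all(p$psi2 >= 0 & p$psi2 <= 2))
  expect_true(all(p$tau1 >= 0 & p$tau1 <= 2))
  expect_true(all(p$rho >= -1 & p$rho <= 1))
  expect_true(all(p$rho_w >= 0 & p$rho_w <= 1))
  wide <- sample_prior(prior_config(psi2_upper = 100, tau_upper = 100),
                       n = 2000)
  expect_gt(max(wide$psi2), 2)
  expect_gt(max(wide$tau2), 2)
  fixed <- sample_prior(prior_config(rho_w_fixed = 0.52), n = 50)
  expect_true(all(fixed$rho_w == 0.52))
})

test_that("the Daniels-Hughes posterior approaches the least-squares line as SEs vanish", {
  dat <- make_line_data(n = 20, lambda0 = 0.1, lambda1 = 0.7, se = 1e-6,
                        seed = 2)
  # add small residual scatter so the OLS line is non-degenerate
  set.seed(3)
  dat$y2 <- dat$y2 + rnorm(20, 0, 0.05)
  fit <- fit_dh(dat, mcmc = test_mcmc(seed = 5, n_iter = 12000))
  ols <- coef(lm(y2 ~ y1, data = dat))
  expect_lt(abs(coef(fit)[["lambda0"]] - ols[[1]]), 0.01)
  expect_lt(abs(coef(fit)[["lambda1"]] - ols[[2]]), 0.01)
})

test_that("an exact linear relationship drives the conditional variance to zero", {
  dat <- make_line_data(n = 20, lambda0 = 0.1, lambda1 = 0.7, se = 1e-6)
  fit <- suppressWarnings(fit_dh(dat, mcmc = test_mcmc(seed = 6)))
  expect_lt(abs(coef(fit)[["lambda0"]] - 0.1), 0.01)
  expect_lt(abs(coef(fit)[["lambda1"]] - 0.7), 0.01)
  expect_lt(coef(fit)[["psi2sq"]], 1e-4)
})

test_that("BRMA PNF satisfies the product-normal identities draw by draw", {
  dat <- simulate_meta_dataset(sim_config(n_rct = 12, n_crwe = 0,
                                          n_srwe = 0, seed = 13))
  fit <- suppressWarnings(
    fit_brma_pnf(dat, mcmc = test_mcmc(seed = 7, n_iter = 4000,
                                       n_burnin = 1000)))
  dr <- fit$draws
  expect_lt(max(abs(dr[, "lambda1"] - dr[, "rho"] * dr[, "tau2"] /
                      dr[, "tau1"])), 1e-10)
  expect_lt(max(abs(dr[, "psi2sq"] -
                      (dr[, "tau2"]^2 - dr[, "lambda1"]^2 * dr[, "tau1"]^2))),
            1e-10)
  expect_lt(max(abs(dr[, "R2"] - dr[, "rho"]^2)), 1e-12)
  expect_true(all(dr[, "psi2sq"] >= 0))
  expect_equal(unname(dr[, "d2"]),
               unname(dr[, "lambda0"] + dr[, "lambda1"] * dr[, "d1"]),
               tolerance = 1e-12)
})

test_that("a null association yields a correlation posterior concentrated near zero", {
  cfg <- sim_config(n_rct = 40, n_crwe = 0, n_srwe = 0, tau1 = 0.3,
                    tau2 = 0.3, rho = 0, se_range = c(0.02, 0.05),
                    seed = 19)
  dat <- simulate_meta_dataset(cfg)
  fit <- suppressWarnings(
    fit_brma_pnf(dat, mcmc = test_mcmc(seed = 8, n_iter = 12000,
                                       n_burnin = 3000)))
  expect_lt(abs(coef(fit)[["rho"]]), 0.2)
  expect_lt(coef(fit)[["R2"]], 0.2)
})

test_that("identical seeds reproduce identical posterior draws", {
  dat <- simulate_meta_dataset(sim_config(seed = 1))
  f1 <- suppressWarnings(fit_dh(dat, mcmc = test_mcmc(seed = 42,
                                                      n_iter = 3000,
                                                      n_burnin = 500)))
  f2 <- suppressWarnings(fit_dh(dat, mcmc = test_mcmc(seed = 42,
                                                      n_iter = 3000,
                                                      n_burnin = 500)))
  expect_identical(f1$draws, f2$draws)
})

test_that("model preconditions are enforced", {
  dat <- simulate_meta_dataset(sim_config(n_rct = 7, n_crwe = 0,
                                          n_srwe = 0, seed = 1))
  expect_error(surrofit(dat[1:2, ], "dh"), "at least 3")
  expect_error(fit_brma_pnf_bias(dat), "brma")
})

test_that("pinning the bias priors reduces the bias model to the base BRMA", {
  # informative regime (small SEs) so the heterogeneity parameters, and
  # hence the derived slope, are well identified in both fits
  cfg <- sim_config(n_rct = 10, n_crwe = 10, n_srwe = 0, tau1 = 0.25,
                    se_range = c(0.03, 0.08),
                    alpha1 = 0, alpha2 = 0,
                    sigma_alpha1 = 0, sigma_alpha2 = 0,
                    sigma_beta1 = 0, sigma_beta2 = 0, seed = 29)
  dat <- simulate_meta_dataset(cfg)
  mc <- test_mcmc(seed = 9, n_iter = 15000, n_burnin = 3000)
  base <- suppressWarnings(fit_brma_pnf(dat, mcmc = mc))
  pinned <- suppressWarnings(fit_brma_pnf_bias(
    dat, priors = prior_config(bias_sd_upper = 1e-5, bias_mean_sd = 1e-5),
    mcmc = mc))
  for (p in c("rho", "lambda0", "lambda1", "d1", "d2")) {
    expect_lt(abs(coef(base)[[p]] - coef(pinned)[[p]]), 0.05)
  }
  expect_lt(abs(coef(base)[["psi2sq"]] - coef(pinned)[["psi2sq"]]), 0.01)
})

test_that("surrogacy criteria flags follow the credible-interval rules", {
  mk <- function(par, point, lo, hi) {
    data.frame(parameter = par, point = point, cri_low = lo,
               cri_high = hi, point_style = "mean")
  }
  summaries <- rbind(mk("lambda0", 0.11, -0.13, 0.34),
                     mk("lambda1", 0.68, 0.31, 1.04),
                     mk("psi2sq", 0.0089, 0, 0.11))
  rep1 <- evaluate_criteria(summaries, "dh")
  expect_true(rep1$satisfied[rep1$criterion == "intercept_zero"])
  expect_true(rep1$satisfied[rep1$criterion == "slope_nonzero"])
  expect_true(is.na(rep1$satisfied[rep1$criterion ==
                                     "conditional_variance_zero"]))
  # a slope interval containing zero fails the association criterion
  summaries2 <- rbind(mk("lambda0", 0.054, -0.22, 0.33),
                      mk("lambda1", 0.54, -0.16, 1.31),
                      mk("psi2sq", 0.013, 0.0008, 0.099),
                      mk("rho", 0.75, -0.25, 0.99))
  rep2 <- evaluate_criteria(summaries2, "brma")
  expect_true(rep2$satisfied[rep2$criterion == "intercept_zero"])
  expect_false(rep2$satisfied[rep2$criterion == "slope_nonzero"])
  expect_true("correlation_perfect" %in% rep2$criterion)
  expect_error(evaluate_criteria(summaries[1:2, ], "dh"), "psi2sq")
})

test_that("fit objects expose the standard modelling methods", {
  dat <- simulate_meta_dataset(sim_config(n_rct = 8, n_crwe = 0,
                                          n_srwe = 0, seed = 3))
  fit <- suppressWarnings(fit_dh(dat, mcmc = test_mcmc(seed = 2,
                                                       n_iter = 3000,
                                                       n_burnin = 500)))
  expect_s3_class(fit, "surrofit")
  expect_named(coef(fit), c("lambda0", "lambda1", "psi2sq"))
  expect_equal(summary(fit), fit$summary)
  pr <- predict(fit, data.frame(y1 = c(-0.5, 0)))
  expect_equal(nrow(pr), 2L)
  expect_true(all(pr$cri_low <= pr$mean & pr$mean <= pr$cri_high))
  res <- residuals(fit)
  expect_length(res, 8L)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3L)
  expect_named(sims[[1]], c("study_id", "y1", "y2"))
  expect_output(print(fit), "Daniels-Hughes")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
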