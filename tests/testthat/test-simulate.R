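test_that("the two between-studies parameterisations are linked exactly", {
  cfg <- sim_config(tau1 = 1, tau2 = 1, rho = 0.5)
  expect_equal(cfg$lambda1, 0.5)
  expect_equal(cfg$psi2^2, 0.75)

  cfg2 <- sim_config(tau1 = 0.25, lambda1 = 0.7, psi2 = 0.1)
  expect_equal(cfg2$tau2, sqrt(0.1^2 + 0.7^2 * 0.25^2))
  expect_equal(cfg2$rho, 0.7 * 0.25 / cfg2$tau2)

  # datasets generated under equivalent configurations are identical
  a <- simulate_meta_dataset(sim_config(tau1 = 0.3, tau2 = 0.24,
                                        rho = 0.8, seed = 5))
  b <- simulate_meta_dataset(sim_config(
    tau1 = 0.3, lambda1 = 0.8 * 0.24 / 0.3,
    psi2 = sqrt(0.24^2 * (1 - 0.8^2)), seed = 5))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("inconsistent variance inputs raise a configuration error", {
  expect_error(sim_config(tau1 = 1, tau2 = 0.5, lambda1 = 2),
               "psi2\\^2")
  expect_error(sim_config(tau1 = 1, tau2 = 0.5, rho = 1.3), "rho")
  expect_error(sim_config(tau1 = 1, tau2 = 0.5, rho = 0.5, lambda1 = 2),
               "inconsistent")
  expect_error(sim_config(tau1 = 1, lambda1 = 0.5), "supply either")
})

test_that("noise-free limit puts every study exactly on the line", {
  cfg <- sim_config(n_rct = 15, n_crwe = 0, n_srwe = 0,
                    lambda0 = 0.1, lambda1 = 0.7, psi2 = 0,
                    se_range = c(0, 0), seed = 3)
  dat <- simulate_meta_dataset(cfg)
  expect_equal(dat$y2, 0.1 + 0.7 * dat$y1, tolerance = 1e-12)
  expect_equal(dat$y1, dat$delta1, tolerance = 1e-12)
})

test_that("simulated moments match the generating model", {
  cfg <- sim_config(n_rct = 2000, n_crwe = 0, n_srwe = 0,
                    eta1 = -0.3, tau1 = 0.4, tau2 = 0.3, rho = 0.6,
                    seed = 17)
  dat <- simulate_meta_dataset(cfg)
  expect_lt(abs(cor(dat$delta1, dat$delta2) - 0.6), 0.02)
  expect_lt(abs(var(dat$delta2) / 0.3^2 - 1), 0.03)
  expect_lt(abs(var(dat$delta1) / 0.4^2 - 1), 0.03)
})

test_that("bias terms are zero for RCTs and distribution-free when switched off", {
  cfg <- sim_config(n_rct = 5, n_crwe = 5, n_srwe = 5,
                    alpha1 = 0.3, beta1 = -0.2, seed = 2)
  dat <- simulate_meta_dataset(cfg)
  expect_true(all(dat$bias1[dat$design == "RCT"] == 0))
  expect_true(all(dat$bias2[dat$design == "RCT"] == 0))
  expect_true(any(dat$bias1[dat$design != "RCT"] != 0))

  # with all bias means and SDs zero, designs are exchangeable
  cfg0 <- sim_config(n_rct = 400, n_crwe = 400, n_srwe = 0,
                     alpha1 = 0, alpha2 = 0, beta1 = 0, beta2 = 0,
                     sigma_alpha1 = 0, sigma_alpha2 = 0,
                     sigma_beta1 = 0, sigma_beta2 = 0, seed = 23)
  d0 <- simulate_meta_dataset(cfg0)
  ks <- suppressWarnings(
    ks.test(d0$y1[d0$design == "RCT"], d0$y1[d0$design == "cRWE"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-study substreams keep existing studies fixed as studies are added", {
  small <- simulate_meta_dataset(sim_config(n_rct = 10, n_crwe = 0,
                                            n_srwe = 0, seed = 4))
  large <- simulate_meta_dataset(sim_config(n_rct = 14, n_crwe = 0,
                                            n_srwe = 0, seed = 4))
  expect_equal(small, large[1:10, ], tolerance = 1e-15)
  again <- simulate_meta_dataset(sim_config(n_rct = 10, n_crwe = 0,
                                            n_srwe = 0, seed = 4))
  expect_identical(small, again)
})

test_that("meta-dataset files round-trip through the study-effects reader", {
  dat <- simulate_meta_dataset(sim_config(seed = 8))
  eff <- withr::local_tempfile(fileext = ".csv")
  tru <- withr::local_tempfile(fileext = ".csv")
  write_meta_dataset(dat, eff, tru)
  back <- read_study_effects(eff)
  expect_equal(back$y1, dat$y1, tolerance = 1e-12)
  truth <- read.csv(tru)
  expect_equal(truth$delta2, dat$delta2, tolerance = 1e-12)
})

test_that("simulated survival arms have textbook Kaplan-Meier structure", {
  arm <- simulate_survival_arm(5, hazard = 0.2, seed = 31)
  km <- arm$km
  expect_equal(km$risk_table$n_risk[1], 5)
  expect_equal(sort(km$coords$surv[km$coords$time > 0], decreasing = TRUE),
               c(0.8, 0.6, 0.4, 0.2, 0))

  big <- simulate_survival_arm(10000, hazard = 0.1, seed = 32,
                               risk_interval = 5)
  f <- stats::stepfun(big$km$coords$time, c(1, big$km$coords$surv))
  expect_lt(abs(f(log(2) / 0.1) - 0.5), 0.02)
})

test_that("covariate profiles are deterministic and respect scaling ranges", {
  p1 <- simulate_covariate_profiles(4, 3, seed = 9)
  p2 <- simulate_covariate_profiles(4, 3, seed = 9)
  expect_identical(p1, p2)
  spec <- covariate_spec()
  for (cv in spec$name) {
    expect_true(all(p1[[cv]] >= spec$min[spec$name == cv]))
    expect_true(all(p1[[cv]] <= spec$max[spec$name == cv]))
  }
  flat <- simulate_covariate_profiles(2, 2, seed = 1, jitter = 0)
  expect_equal(total_distance(flat[1, ], flat[3, ]), 0)
})
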