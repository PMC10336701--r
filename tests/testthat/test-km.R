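test_that("km_estimate matches a hand-rolled product-limit oracle", {
  # five events at distinct times, no censoring
  ipd <- data.frame(time = c(2, 5, 1, 9, 7), event = 1)
  km <- km_estimate(ipd)
  expect_equal(km$coords$surv[km$coords$time > 0],
               c(0.8, 0.6, 0.4, 0.2, 0))
  # all censored: flat at 1
  flat <- km_estimate(data.frame(time = 1:4, event = 0))
  expect_true(all(flat$coords$surv == 1))
  # random fixtures against the oracle
  set.seed(51)
  for (rep in 1:5) {
    n <- 40
    time <- round(rexp(n, 0.2), 3)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(data.frame(time = time, event = event))
    oracle <- km_oracle(time, event)
    got <- km$coords[km$coords$time > 0, ]
    expect_equal(got$time, oracle$time, tolerance = 1e-12)
    expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
  }
})

test_that("km_dataset repairs digitization noise and validates risk tables", {
  noisy <- data.frame(time = c(0, 1, 2, 3), surv = c(1, 0.9, 0.905, 0.7))
  km <- km_dataset(noisy, n_start = 100)
  expect_true(all(diff(km$coords$surv) <= 0))
  expect_lt(attr(km, "repair"), 0.02)
  very_noisy <- data.frame(time = c(0, 1, 2), surv = c(1, 0.8, 0.9))
  expect_warning(km_dataset(very_noisy, n_start = 100), "repair")
  expect_error(km_dataset(data.frame(time = c(0, 1), surv = c(1, 0.9)),
                          risk_table = data.frame(time = c(0, 2),
                                                  n_risk = c(10, 12))),
               "non-increasing")
  expect_error(km_dataset(data.frame(time = c(0, 1), surv = c(1, 0.9))),
               "n_start")
})

test_that("reconstruction is exact when there is no censoring", {
  arm <- simulate_survival_arm(5, hazard = 0.2, seed = 3, risk_interval = 1)
  rec <- reconstruct_ipd(arm$km)
  expect_equal(nrow(rec), 5L)
  expect_equal(sum(rec$event), sum(arm$ipd$event))
  expect_equal(sort(rec$time[rec$event == 1]), sort(arm$ipd$time),
               tolerance = 1e-12)
})

test_that("reconstruction round-trips digitized curves within tolerance", {
  # with a numbers-at-risk table: 0.02 absolute survival
  for (sd in 1:3) {
    arm <- simulate_survival_arm(300, hazard = 0.08, censor_rate = 0.02,
                                 risk_interval = 1, seed = sd)
    rec <- reconstruct_ipd(arm$km)
    expect_equal(nrow(rec), 300L)
    back <- km_estimate(rec, risk_interval = 1)
    expect_lt(km_max_dev(arm$km, back), 0.02)
  }
  # with totals only: 0.05 absolute survival
  arm <- simulate_survival_arm(300, hazard = 0.08, censor_rate = 0.02,
                               risk_interval = 1, seed = 4)
  totals <- km_dataset(arm$km$coords, n_start = 300,
                       total_events = sum(arm$ipd$event))
  rec <- reconstruct_ipd(totals)
  expect_equal(nrow(rec), 300L)
  expect_equal(sum(rec$event), sum(arm$ipd$event))
  back <- km_estimate(rec, risk_interval = 1)
  expect_lt(km_max_dev(arm$km, back), 0.05)
})

test_that("a flat curve with zero events reconstructs as all censored", {
  km <- km_dataset(data.frame(time = c(0, 10), surv = c(1, 1)),
                   n_start = 10, total_events = 0)
  rec <- reconstruct_ipd(km)
  expect_equal(nrow(rec), 10L)
  expect_true(all(rec$event == 0))
})

test_that("infeasible risk tables are rejected", {
  km <- km_dataset(data.frame(time = c(0, 1), surv = c(1, 0.5)),
                   risk_table = data.frame(time = c(0, 2),
                                           n_risk = c(10, 10)))
  km$risk_table$n_risk <- c(10, 15) # bypass constructor check
  km$risk_table$n_risk[1] <- 10
  expect_error(reconstruct_ipd(km), "infeasible")
})

test_that("cox_loghr maximises the partial likelihood", {
  # relabelling identical data gives logHR 0 by symmetry
  a <- data.frame(time = c(1, 3, 5, 7), event = 1)
  same <- cox_loghr(a, a)
  expect_lt(abs(same$loghr), 1e-8)
  # no events is not estimable
  none <- data.frame(time = 1:3, event = 0)
  expect_error(cox_loghr(none, none), "no events")
  # hand-maximised partial likelihood oracle on tie-free data
  set.seed(61)
  for (rep in 1:4) {
    n <- 30
    df <- data.frame(time = rexp(2 * n, 0.1) + (1:(2 * n)) * 1e-9,
                     event = rbinom(2 * n, 1, 0.7),
                     z = rep(c(1, 0), each = n))
    if (sum(df$event) < 2) df$event[1:2] <- 1
    est <- cox_loghr(df[df$z == 1, ], df[df$z == 0, ])
    oracle <- cox_oracle(df$time, df$event, df$z)
    expect_equal(est$loghr, oracle, tolerance = 1e-4)
  }
})

test_that("cox_loghr recovers a known hazard ratio and is scale invariant", {
  treat <- simulate_survival_arm(2000, hazard = 0.07, seed = 11)$ipd
  ctrl <- simulate_survival_arm(2000, hazard = 0.10, seed = 12)$ipd
  est <- cox_loghr(treat, ctrl)
  expect_lt(abs(est$loghr - log(0.7)), 0.05)
  expect_gt(est$se, 0)
  scaled <- cox_loghr(transform(treat, time = time * 365.25),
                      transform(ctrl, time = time * 365.25))
  expect_equal(scaled$loghr, est$loghr, tolerance = 1e-10)
})

test_that("km datasets and reconstructed records survive CSV round trips", {
  arm <- simulate_survival_arm(50, hazard = 0.1, censor_rate = 0.02,
                               seed = 77, risk_interval = 2)
  cpath <- withr::local_tempfile(fileext = ".csv")
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_km_dataset(arm$km, cpath, rpath)
  back <- read_km_dataset(cpath, rpath, arm_id = "arm")
  expect_equal(back$coords$surv, arm$km$coords$surv, tolerance = 1e-12)
  expect_equal(back$risk_table, arm$km$risk_table)
  ipath <- withr::local_tempfile(fileext = ".csv")
  rec <- reconstruct_ipd(arm$km)
  write_ipd(rec, ipath)
  expect_equal(read.csv(ipath)$time, rec$time, tolerance = 1e-12)
})
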