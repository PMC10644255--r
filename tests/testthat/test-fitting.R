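# Global regression, offset-Weibull fitting, information criteria,
# model comparison.

test_that("noise-free pulse-chase fits recover the generating rates", {
  # four-compartment disease truth
  ds4 <- generate_pulse_chase(dhe_params("disease"),
                              grid = seq(0, 360, length.out = 13),
                              noise = noise_spec(sigma = 0))
  fit4 <- global_fit(ds4, "closed_four",
                     initial_guess = c(k1 = .05, k2 = .3, k3 = .1,
                                       k4 = .01, km4 = .005))
  truth4 <- c(k1 = .03216, k2 = .4331, k3 = .1744, k4 = .0084, km4 = .0039)
  expect_true(fit4$converged)
  expect_lt(max(abs(fit4$estimates[names(truth4)] - truth4) / truth4), 1e-3)
  expect_lt(fit4$rss, 1e-12)

  # three-compartment control truth
  ds3 <- generate_pulse_chase(dhe_params("control"), variant = "closed_three",
                              grid = seq(0, 360, length.out = 13),
                              noise = noise_spec(sigma = 0))
  fit3 <- global_fit(ds3, "closed_three",
                     initial_guess = c(k1 = .05, k2 = .3, k3 = .1))
  truth3 <- c(k1 = .01204, k2 = .2465, k3 = .09351)
  expect_lt(max(abs(fit3$estimates[names(truth3)] - truth3) / truth3), 1e-3)
})

test_that("refitting from the optimum reproduces it", {
  ds <- generate_pulse_chase(dhe_params("disease"),
                             grid = seq(0, 360, length.out = 13),
                             noise = noise_spec(sigma = 0.02, seed = 5))
  fit <- global_fit(ds, "closed_four",
                    initial_guess = c(k1 = .05, k2 = .3, k3 = .1,
                                      k4 = .01, km4 = .005))
  refit <- global_fit(ds, "closed_four", initial_guess = fit$estimates)
  expect_lte(refit$rss, fit$rss * (1 + 1e-8))
  expect_equal(refit$estimates, fit$estimates, tolerance = 1e-4)
})

test_that("multi-start never worsens the single-start optimum", {
  ds <- generate_pulse_chase(dhe_params("disease"),
                             grid = seq(0, 360, length.out = 13),
                             noise = noise_spec(sigma = 0.02, seed = 6))
  guess <- c(k1 = .05, k2 = .3, k3 = .1, k4 = .01, km4 = .005)
  f1 <- global_fit(ds, "closed_four", initial_guess = guess)
  f5 <- global_fit(ds, "closed_four", initial_guess = guess,
                   n_starts = 5, seed = 99)
  expect_lte(f5$rss, f1$rss * (1 + 1e-8))
  expect_equal(f5$seed, 99)
})

test_that("global fit pools datasets in parallel and honours weights", {
  # two noise-free pulse-chase runs on different grids, fitted jointly
  truth <- c(k1 = .03216, k2 = .4331, k3 = .1744, k4 = .0084, km4 = .0039)
  ds1 <- generate_pulse_chase(dhe_params("disease"),
                              grid = c(0, 2.5, 5, 10, 20, 40, 80, 160,
                                       240, 360),
                              noise = noise_spec(sigma = 0))
  ds2 <- generate_pulse_chase(dhe_params("disease"),
                              grid = c(0, 5, 15, 30, 60, 120, 240, 480, 600),
                              noise = noise_spec(sigma = 0))
  fit <- global_fit(list(ds1, ds2), "closed_four",
                    initial_guess = c(k1 = .05, k2 = .3, k3 = .1,
                                      k4 = .01, km4 = .005))
  expect_equal(fit$n_obs, 3 * (10 + 9))
  expect_lt(max(abs(fit$estimates[names(truth)] - truth) / truth), 1e-3)

  # explicit per-point sd enters the weighting: a constant sd of 0.5
  # leaves the optimum unchanged and scales the rss by 1/0.5^2
  ds_n <- generate_pulse_chase(dhe_params("disease"),
                               grid = c(0, 2.5, 5, 10, 20, 40, 80, 160,
                                        240, 360),
                               noise = noise_spec(sigma = 0.02, seed = 12))
  ds_w <- ds_n
  ds_w$data$sd <- 0.5
  guess <- c(k1 = .05, k2 = .3, k3 = .1, k4 = .01, km4 = .005)
  fit_u <- global_fit(ds_n, "closed_four", initial_guess = guess)
  fit_w <- global_fit(ds_w, "closed_four", initial_guess = guess)
  expect_equal(fit_w$estimates, fit_u$estimates, tolerance = 1e-4)
  expect_equal(fit_w$rss, fit_u$rss / 0.25, tolerance = 1e-6)
})

test_that("fixed parameters are held at their values during optimisation", {
  p <- disease_params(v0 = 0.01, k5 = 0.001)
  grid <- c(0, 5, 10, 20, 40, 80, 160, 320, 640, 1280, 2560, 4000, 6000)
  ds <- generate_continuous_uptake(p, grid = grid,
                                   noise = noise_spec(sigma = 0))
  truth <- c(k1 = .03216, k2 = .4331, k3 = .1744, k4 = .0084, km4 = .0039)
  fit <- global_fit(ds, "open_four", free_params = names(truth),
                    fixed = c(v0 = 0.01, k5 = 0.001),
                    initial_guess = truth)
  # truth is an exact zero of the objective with the influx/efflux pinned
  expect_lt(fit$rss, 1e-12)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth) / truth), 1e-6)
  expect_error(global_fit(ds, "open_four", free_params = names(truth),
                          fixed = c(k1 = 0.01), initial_guess = truth),
               "both free and fixed")
})

test_that("fit results carry sd, cv = sd/estimate and information criteria", {
  ds <- generate_pulse_chase(dhe_params("disease"),
                             grid = seq(0, 360, length.out = 13),
                             noise = noise_spec(sigma = 0.02, seed = 7))
  fit <- global_fit(ds, "closed_four",
                    initial_guess = c(k1 = .05, k2 = .3, k3 = .1,
                                      k4 = .01, km4 = .005))
  expect_true(all(is.finite(fit$sd)))
  expect_equal(unname(fit$cv), unname(fit$sd / fit$estimates))
  ic <- information_criteria(fit$rss, fit$n_obs, fit$n_params)
  expect_equal(fit$aic, ic$aic)
  expect_equal(fit$bic, ic$bic)
  rep <- fit_report(fit)
  expect_named(rep, c("parameter", "estimate", "sd", "cv"))
})

test_that("offset-Weibull fit recovers noise-free truth exactly", {
  tt <- c(0, 12, 24, 48, 72, 96)
  y <- 0.05 + 0.35 * weibull_survival(tt, 135.14, 2.577)
  fit <- fit_weibull_efflux(tt, y,
                            initial_guess = c(tau = 60, mu = 1.5,
                                              f0 = 0.5, f_inf = 0.01))
  expect_equal(fit$tau, 135.14, tolerance = 1e-6)
  expect_equal(fit$mu, 2.577, tolerance = 1e-6)
  expect_equal(fit$f0, 0.4, tolerance = 1e-6)
  expect_equal(fit$f_inf, 0.05, tolerance = 1e-6)
})

test_that("Weibull fit with mu fixed at 1 recovers an exponential decay", {
  tt <- seq(0, 96, by = 8)
  y <- 0.3 * exp(-tt / 40)
  fit <- fit_weibull_efflux(tt, y, fixed = c(mu = 1))
  expect_equal(fit$tau, 40, tolerance = 1e-6)
  expect_equal(fit$mu, 1)
  expect_equal(fit$f_inf, 0, tolerance = 1e-6)
})

test_that("Weibull fit is scale-consistent in time", {
  tt <- c(0, 12, 24, 48, 72, 96)
  y <- 0.05 + 0.35 * weibull_survival(tt, 135.14, 2.577)
  fit_h <- fit_weibull_efflux(tt, y)
  fit_min <- fit_weibull_efflux(tt * 60, y)
  expect_equal(fit_min$tau, fit_h$tau * 60, tolerance = 1e-4)
  expect_equal(fit_min$mu, fit_h$mu, tolerance = 1e-4)
})

test_that("Weibull fit rejects degenerate inputs", {
  expect_error(fit_weibull_efflux(c(0, 1, 2), c(1, 1, 1)), ">= 5")
  expect_error(fit_weibull_efflux(0:5, rep(0.3, 6)), "non-identifiable")
  expect_error(fit_weibull_efflux(0:5, c(2, rep(0.3, 5))), "\\[0, 1\\]")
})

test_that("noisy Weibull recovery is unbiased at the experimental scale", {
  # 1% additive noise on the 0-96 h efflux grid, disease truth
  truth <- dhe_efflux_weibull("disease")
  tt <- c(0, 12, 24, 48, 72, 96)
  clean <- 0.05 + 0.35 * weibull_survival(tt, truth$tau_h, truth$mu)
  set.seed(404)
  taus <- vapply(1:200, function(i) {
    y <- pmin(pmax(clean + rnorm(length(tt), 0, 0.01), 0), 1)
    fit_weibull_efflux(tt, y, initial_guess = c(tau = 100, mu = 2,
                                                f0 = 0.45, f_inf = 0.02))$tau
  }, numeric(1))
  expect_lt(abs(stats::median(taus) - truth$tau_h) / truth$tau_h, 0.05)
})

test_that("information criteria follow the Gaussian least-squares forms", {
  ic <- information_criteria(0.01, 30, 3)
  expect_equal(ic$aic, -234.191, tolerance = 1e-4)
  expect_equal(ic$bic, -229.9874, tolerance = 1e-4)
  # parsimony ordering at equal rss
  ic2 <- information_criteria(0.01, 30, 5)
  expect_lt(ic$aic, ic2$aic)
  expect_lt(ic$bic, ic2$bic)
  # BIC penalty exceeds AIC penalty for n >= 8
  expect_gt(ic2$bic - ic$bic, ic2$aic - ic$aic)
  expect_error(information_criteria(0, 30, 3), "degenerate")
  expect_error(information_criteria(0.01, 3, 3), "exceed")
})

test_that("single-variant comparison is a one-row table with zero deltas", {
  ds <- generate_pulse_chase(dhe_params("disease"),
                             grid = seq(0, 360, length.out = 13),
                             noise = noise_spec(sigma = 0.02, seed = 8))
  cmp <- compare_models(ds, "closed_four",
                        initial_guesses = list(
                          closed_four = c(k1 = .05, k2 = .3, k3 = .1,
                                          k4 = .01, km4 = .005)))
  expect_equal(nrow(cmp$table), 1)
  expect_equal(cmp$table$delta_bic, 0)
  expect_equal(cmp$table$delta_aic, 0)
})

test_that("BIC selects the generating variant on both data shapes", {
  study <- mc_model_recovery()
  # biphasic four-compartment truth
  expect_gte(mean(study$biphasic_winner == "closed_four"), 0.9)
  # single-phase three-compartment truth: parsimony wins
  expect_gte(mean(study$single_phase_winner == "closed_three"), 0.9)
})

test_that("rate recovery at 2% noise is unbiased with CVs at the reported scale", {
  study <- mc_model_recovery()
  est <- study$biphasic_estimates
  truth <- study$truth4
  bias <- abs(apply(est, 2, stats::median) - truth) / truth
  expect_lt(max(bias), 0.05)
  cv <- apply(est, 2, stats::sd) / apply(est, 2, mean)
  expect_lte(max(cv), 0.4)
})
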