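# Numerical integration and scenario runners.

test_that("integration matches the matrix-exponential solution", {
  set.seed(31)
  times <- seq(0, 600, length.out = 7)
  for (variant in c("closed_three", "closed_four", "open_four",
                    "efflux_two_pathway")) {
    for (rep in 1:3) {
      p <- random_rates(variant)
      init <- c(1, 0, 0.2, 0.1)
      if (variant == "closed_three") init[4] <- 0
      tr <- simulate_model(variant, p, init = init, times = times)
      oracle <- expm_solution(variant, p, init, times)
      expect_lt(max(abs(as.matrix(tr[, c("n1", "n2", "n3", "n4")]) - oracle)),
                1e-7)
    }
  }
})

test_that("closed simulations conserve total sterol", {
  tr <- simulate_model("closed_four", dhe_params("disease"),
                       init = c(1, 0, 0, 0), t_end = 360, n_points = 73)
  expect_lt(max(abs(tr$total - 1)), 1e-8)
  expect_true(all(tr[, c("PM", "RE", "LM", "ILV")] >= 0))
})

test_that("all-zero rates freeze the state", {
  tr <- simulate_model("closed_four", rate_constants(),
                       init = c(0.4, 0.3, 0.2, 0.1), t_end = 100,
                       n_points = 5)
  expect_equal(max(abs(sweep(as.matrix(tr[, c("n1", "n2", "n3", "n4")]), 2,
                             c(0.4, 0.3, 0.2, 0.1)))), 0, tolerance = 1e-12)
})

test_that("long closed_four runs relax to the open-system steady fractions", {
  tr <- run_pulse_chase(dhe_params("disease"), t_end = 5000, n_points = 11)
  expect_equal(tail(tr$intracellular_fraction, 1), 0.3960755,
               tolerance = 1e-3)
  fr_end <- unlist(tail(tr[, c("PM", "RE", "LM", "ILV")], 1))
  expect_equal(unname(fr_end),
               unname(steady_fractions(dhe_params("disease"))),
               tolerance = 1e-6)
})

test_that("grid refinement leaves the solution unchanged", {
  p <- disease_params(k5 = 1e-4, k6 = 0.0015, mu = 2.577)
  coarse <- run_efflux(p, t_end = 6000, n_points = 26)
  fine <- run_efflux(p, t_end = 6000, n_points = 51)
  shared <- match(coarse$time, fine$time)
  expect_lt(max(abs(fine$LELY[shared] - coarse$LELY)), 1e-6)
  expect_lt(max(abs(fine$total[shared] - coarse$total)), 1e-6)
})

test_that("pulse-chase starts at the pulse state and rejects open variants", {
  tr <- run_pulse_chase(dhe_params("disease"), t_end = 120, n_points = 13)
  expect_equal(unlist(tr[1, c("PM", "RE", "LELY")]),
               c(PM = 1, RE = 0, LELY = 0))
  expect_error(run_pulse_chase(disease_params(v0 = 1, k5 = 1e-3),
                               variant = "open_four"), "closed variant")
})

test_that("control pulse-chase approaches the closed-form PM asymptote", {
  tr <- run_pulse_chase(dhe_params("control"), variant = "closed_three",
                        t_end = 5000, n_points = 11)
  expect_equal(tail(tr$PM, 1), 0.8491847, tolerance = 1e-4)
})

test_that("disease pulse-chase shows delayed ILV accumulation", {
  tr <- run_pulse_chase(dhe_params("disease"), t_end = 5000, n_points = 501)
  # LM rises fast; ILV lags behind it early and dominates late
  t_early <- tr$time <= 60
  expect_true(all(tr$ILV[t_early] <= tr$LM[t_early]))
  expect_gt(tail(tr$ILV, 1), tail(tr$LM, 1))
  # delay: ILV reaches half its final level later than LM does
  t_half <- function(x) tr$time[which(x >= 0.5 * tail(x, 1))[1]]
  expect_gt(t_half(tr$ILV), t_half(tr$LM))
})

test_that("efflux with k5 = k6 = 0 conserves total", {
  p <- disease_params(mu = 2.577)
  tr <- run_efflux(p, t_end = 6000, n_points = 25)
  expect_lt(max(abs(tr$total - 1)), 1e-8)
})

test_that("PM-only efflux leaves the LE/LYS fraction constant while total declines", {
  p <- disease_params(k5 = 1e-4)  # k6 = 0: pathway II off
  tr <- run_efflux(p, t_end = 12000, n_points = 49)
  expect_lt(tail(tr$total, 1), 0.65)
  dev <- abs(tr$lely_fraction - tr$lely_fraction[1]) / tr$lely_fraction[1]
  expect_lt(max(dev), 0.02)
})

test_that("two-pathway efflux fraction is sigmoid: flat start, declining, plateau", {
  p <- disease_params(k5 = 1e-4, k6 = 0.0015, mu = 2.577)
  tr <- run_efflux(p, t_end = 18000, n_points = 301)
  f <- tr$lely_fraction
  # initial delay: almost no change over the first two hours, and the
  # starting slope is far below the steepest decline
  expect_lt(abs(f[3] - f[1]) / f[1], 0.01)
  slope <- -diff(f) / diff(tr$time)
  expect_lt(abs(slope[1]), 0.1 * max(slope))
  # then a pronounced drop
  expect_lt(min(f), 0.5 * f[1])
  # late plateau: relative change over the last 10% of the window is small
  expect_lt(abs(f[301] - f[271]) / f[271], 0.01)
  # total is non-increasing
  expect_true(all(diff(tr$total) <= 1e-10))
})

test_that("scenario batches are deterministic and labelled", {
  p <- disease_params(k5 = 1e-4, k6 = 0.0015, mu = 2.577)
  sp <- scenario_spec("efflux_two_pathway", p, "steady_fractions",
                      t_end = 3000, n_points = 11, label = "disease_low_k5")
  out <- scenario_batch(list(sp, sp))
  expect_named(out, c("trajectories", "table"))
  expect_equal(out$trajectories[[1]]$LELY, out$trajectories[[2]]$LELY)
  expect_setequal(unique(out$table$observable),
                  c("PM", "RE", "LM", "ILV", "LELY", "total",
                    "intracellular_fraction"))
  expect_true(all(out$table$scenario_label == "disease_low_k5"))
})

test_that("matched-k5 efflux drops faster with control-like ILV exchange", {
  # control rates with q2 = 0.2 vs disease rates, same efflux parameters
  mk <- function(params) update_rates(params, k5 = 1e-4, k6 = 0.0015,
                                      mu = 2.57)
  dis <- run_efflux(mk(dhe_params("disease")), t_end = 12000, n_points = 25,
                    init = steady_fractions(dhe_params("disease")))
  ctl <- run_efflux(mk(dhe_params("control_full")), t_end = 12000,
                    n_points = 25,
                    init = steady_fractions(dhe_params("disease")))
  expect_lt(tail(ctl$lely_fraction, 1), tail(dis$lely_fraction, 1))
})

test_that("invalid scenario inputs are rejected with informative errors", {
  p <- dhe_params("disease")
  expect_error(simulate_model("closed_four", p, init = c(1, 0, 0, -1),
                              t_end = 10), "negative")
  expect_error(simulate_model("closed_four", p, init = c(1, 0, 0, 0),
                              t_end = -5), "t_end")
  expect_error(scenario_spec("closed_four", p, "steady_fractions",
                             t_end = 100), "efflux_two_pathway")
})
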