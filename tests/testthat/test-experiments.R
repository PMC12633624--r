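test_that("mega-synapse ablation removes exactly the largest weights", {
  w <- matrix(c(0.1, -5, 2, 0.3), 2, 2)
  expect_identical(ablate_top_weights(w, 0), w)
  expect_identical(ablate_top_weights(w, 4), matrix(0, 2, 2))
  a1 <- ablate_top_weights(w, 1)
  expect_identical(a1[2, 1], 0)       # the -5 goes first
  expect_identical(a1[1, 2], 2)
  expect_error(ablate_top_weights(w, 5), "between")

  # ties broken in row-major order: (1,1) and (1,2) tie, (1,1) removed first
  wt <- matrix(c(1, 0.5, 1, 0.2), 2, 2)
  at <- ablate_top_weights(wt, 1)
  expect_identical(at[1, 1], 0)
  expect_identical(at[1, 2], 1)
})

test_that("removing the top weights weakens chaotic expansion on average", {
  ab <- run_ablation_experiment(1, 100, gain = 0.6, n_remove = 10,
                                n_trials = 5, horizon = 1000, seed = 13)
  expect_lt(mean(ab$mle_ablated), mean(ab$mle_full))
  expect_identical(ab$frac_removed, rep(10 / 100^2, 5))
})

test_that("transition experiment is deterministic and saturates in deep quiescence", {
  gains <- c(0.05, 0.1)
  a <- run_transition_experiment(1, 100, gains, n_realizations = 3,
                                 depth = 50, seed = 31)
  b <- run_transition_experiment(1, 100, gains, n_realizations = 3,
                                 depth = 50, seed = 31)
  expect_identical(a, b)
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a, f1, row.names = FALSE); write.csv(b, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  # both gains sit far below g*(100, 1) ~ 0.3: everything quiescent
  expect_true(all(a$order_parameter == 1))
  expect_setequal(unique(a$mode), c("annealed", "quenched"))
})

test_that("per-realization transition gain interpolates the f = 1/2 crossing", {
  expect_equal(order_transition_gain(c(1, 2, 3, 4), c(1, 1, 0.4, 0)),
               2 + 0.5 / 0.6)
  expect_true(is.na(order_transition_gain(c(1, 2), c(1, 1))))
  expect_error(order_transition_gain(c(2, 1), c(1, 0)))
})

test_that("MLE sweeps are reproducible and expose crossing and window summaries", {
  gains <- c(0.2, 0.5, 0.8, 1.1)
  s1 <- run_mle_sweep(2, 80, gains, n_trials = 3, horizon = 400,
                      k_accum = 100, seed = 41)
  s2 <- run_mle_sweep(2, 80, gains, n_trials = 3, horizon = 400,
                      k_accum = 100, seed = 41)
  expect_identical(s1$table, s2$table)
  expect_identical(dim(s1$trials), c(3L, 4L))

  # synthetic sweep: window of |mle| <= 0.05 for mle = g - 1 has width 0.1
  syn <- structure(list(table = data.frame(gain = seq(0.5, 1.5, 0.1),
                                           mle_mean = seq(0.5, 1.5, 0.1) - 1)),
                   class = "sweep_result")
  expect_equal(edge_window_width(syn, band = 0.05), 0.1, tolerance = 1e-12)
  expect_equal(estimate_transition_gain(syn), 1, tolerance = 1e-12)
})

test_that("dimensionality experiment returns coherent per-trial measures", {
  res <- run_dimensionality_experiment(2, 60, gains = c(0.3, 1.6),
                                       n_trials = 3, horizon = 400,
                                       warmup = 100, n_exponents = 20,
                                       retain = 100, seed = 51)
  tab <- res$table
  expect_identical(nrow(tab), 6L)
  # deep quiescence: all exponents negative, D_KY = 0
  expect_true(all(tab$d_ky[tab$gain == 0.3] == 0))
  # chaotic side: expanding directions exist and activity has variance
  expect_true(all(tab$d_ky[tab$gain == 1.6] > 0))
  expect_true(all(tab$pr[tab$gain == 1.6] > 1))
  expect_identical(dim(res$spectra[[1]]), c(20L, 3L))
  # spectra sorted nonincreasing
  expect_true(all(apply(res$spectra[[2]], 2, function(x) all(diff(x) <= 0))))
})

test_that("delayed-XOR reservoir: chance without recurrence, learnable near the edge", {
  # gain 0: states carry only the instantaneous input, XOR of past lags is
  # unpredictable; accuracy within 3 binomial SEs of 1/2
  x0 <- run_xor_reservoir(2, gains = 0, n_units = 100, seed = 12)
  expect_lt(abs(x0$accuracy - 0.5), 3 * sqrt(0.25 / 1000))

  # untrained (random) readout on a driven reservoir is also at chance
  set.seed(61)
  states <- matrix(rnorm(1000 * 20), 1000, 20)
  y <- sample(c(-1, 1), 1000, replace = TRUE)
  pred <- sign(states %*% rnorm(20))
  expect_lt(abs(mean(pred == y) - 0.5), 3 * sqrt(0.25 / 1000))

  # reservoirs near the edge of chaos solve delay-1 XOR; deep chaos degrades
  # the Gaussian network faster than the heavy-tailed one
  xh <- run_xor_reservoir(c(1, 2), gains = c(0.8, 2), n_units = 200,
                          input_scale = 1, seed = 11)
  expect_gt(xh$accuracy[xh$alpha == 1 & xh$gain == 0.8], 0.9)
  expect_gt(xh$accuracy[xh$alpha == 2 & xh$gain == 0.8], 0.9)
  expect_gt(xh$accuracy[xh$alpha == 1 & xh$gain == 2],
            xh$accuracy[xh$alpha == 2 & xh$gain == 2])

  # degenerate task: a single-step training window has constant targets
  expect_error(run_xor_reservoir(2, gains = 0.5, n_units = 20, delay = 0,
                                 train_steps = 1, test_steps = 10,
                                 washout = 5, seed = 1), "degenerate")
})

test_that("high-accuracy gain-window width interpolates threshold crossings", {
  g <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  acc <- c(0.5, 0.95, 1.0, 0.95, 0.5)
  # crossings of 0.9 at 0.2 + 0.2*(0.4/0.45) and symmetric on the way down
  w <- accuracy_window_width(g, acc, threshold = 0.9)
  lo <- 0.2 + 0.2 * (0.9 - 0.5) / (0.95 - 0.5)
  hi <- 0.8 + 0.2 * (0.95 - 0.9) / (0.95 - 0.5)
  expect_equal(w, hi - lo, tolerance = 1e-12)
  expect_identical(accuracy_window_width(g, rep(0.5, 5)), 0)
})
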