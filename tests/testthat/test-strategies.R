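test_that("strategy comparison reproduces the canonical beta values and orderings", {
  cc <- make_cell_cycle(20, mean_T = 2)
  b <- burst_model("geometric1", mean = 4)
  tab <- compare_strategies(
    c("start_only", "midpoint_only", "constant", "duplication_midpoint",
      "end_only"), cc, b, alpha = 1, target_mean = 150)

  expect_equal(nrow(tab), 5)
  expect_equal(tab$mean_x, rep(150, 5), tolerance = 1e-9)
  expect_equal(tab$beta[tab$strategy == "start_only"], 1, tolerance = 1e-12)
  expect_equal(tab$beta[tab$strategy == "constant"], 40 / 21,
               tolerance = 1e-12)
  expect_equal(tab$beta[tab$strategy == "end_only"], 20, tolerance = 1e-12)

  # bursty-synthesis noise decreases start -> midpoint -> constant ->
  # duplication -> end; partitioning noise shows the opposite trend
  ord <- match(c("start_only", "midpoint_only", "constant",
                 "duplication_midpoint", "end_only"), tab$strategy)
  expect_true(all(diff(tab$eta_burst_x[ord]) < 0))
  expect_true(all(diff(tab$eta_partition_x[ord]) > 0))
  # returned sorted by decreasing bursty-synthesis noise
  expect_true(all(diff(tab$eta_burst_x) <= 0))

  # midpoint duplication sits strictly between constant and end-only
  eb <- function(nm) tab$eta_burst_x[tab$strategy == nm]
  expect_lt(eb("duplication_midpoint"), eb("constant"))
  expect_gt(eb("duplication_midpoint"), eb("end_only"))
})

test_that("duplication timing scan is self-normalized and monotone", {
  cc <- make_cell_cycle(200, mean_T = 2)
  b <- burst_model("geometric1", mean = 4)
  # the corner minimum (largest f, T1/T nearest 1) needs folds large
  # relative to u/(1-u)^2 at the latest switch time; see the vignette
  t1s <- c(0.2, 0.5, 0.8, 0.9)
  fs <- c(1, 2, 5, 20, 100, 1000)
  grid <- suppressWarnings(
    duplication_scan(cc, b, alpha = 1, target_mean = 150,
                     t1_fractions = t1s, folds = fs))

  # f = 1 is the constant strategy: normalized value 1 everywhere
  expect_equal(grid$eta_burst_normalized[grid$fold == 1], rep(1, length(t1s)),
               tolerance = 1e-9)
  # for fixed T1, noise decreases with increasing fold change
  for (t1 in t1s) {
    v <- grid$eta_burst_normalized[grid$t1_frac == t1][order(fs)]
    expect_true(all(diff(v) < 0))
  }
  # grid minimum at the largest f with the switch closest to the cycle end
  best <- grid[which.min(grid$eta_burst_normalized), ]
  expect_equal(best$fold, max(fs))
  expect_equal(best$t1_frac, max(t1s))

  expect_error(duplication_scan(cc, b, 1, 150, numeric(0), fs), "non-empty")
  expect_error(duplication_scan(cc, b, 1, 150, c(0.5, 1.2), fs), "inside")
})

test_that("beta extremization finds the vertex optima", {
  cc6 <- make_cell_cycle(6, mean_T = 2)
  ex <- extremize_beta(cc6, n_samples = 20000, seed = 10)
  expect_equal(ex$min_beta, 1, tolerance = 1e-12)
  expect_equal(ex$min_profile, c(1, 0, 0, 0, 0, 0))
  expect_equal(ex$max_beta, 6, tolerance = 1e-12)
  expect_equal(ex$max_profile, c(0, 0, 0, 0, 0, 1))
  bb <- beta_bounds(cc6)
  expect_true(all(ex$betas >= bb["lower"] - 1e-12))
  expect_true(all(ex$betas <= bb["upper"] + 1e-12))

  cc2 <- make_cell_cycle(2, lambdas = c(1, 1))
  ex2 <- extremize_beta(cc2, n_samples = 2000, seed = 11)
  expect_equal(ex2$max_beta, 2, tolerance = 1e-12)
})

test_that("noise products depend on the profile only through beta", {
  cc <- make_cell_cycle(4, mean_T = 2)
  b <- burst_model("geometric1", mean = 4)
  part <- partition_model(0.8)
  target_beta <- regulation_beta(
    model_spec(cc, make_strategy("constant", 1, cc), b, part))
  # mix start-only and end-only until the mixture matches beta of 'constant'
  mix_beta <- function(theta) {
    ks <- theta * c(1, 0, 0, 0) + (1 - theta) * c(0, 0, 0, 1)
    regulation_beta(model_spec(cc, ks, b, part))
  }
  theta <- uniroot(function(th) mix_beta(th) - target_beta, c(1e-6, 1 - 1e-6),
                   tol = 1e-14)$root
  ks_mix <- theta * c(1, 0, 0, 0) + (1 - theta) * c(0, 0, 0, 1)
  m1 <- calibrate_rate(model_spec(cc, make_strategy("constant", 1, cc),
                                  b, part), 120)
  m2 <- calibrate_rate(model_spec(cc, ks_mix, b, part), 120)
  n1 <- noise_decomposition(m1)
  n2 <- noise_decomposition(m2)
  expect_equal(n1$beta, n2$beta, tolerance = 1e-9)
  expect_equal(n1$eta_burst * n1$mean_x, n2$eta_burst * n2$mean_x,
               tolerance = 1e-9)
  expect_equal(n1$eta_partition * n1$mean_x, n2$eta_partition * n2$mean_x,
               tolerance = 1e-9)
})
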