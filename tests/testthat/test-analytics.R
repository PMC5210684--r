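test_that("stage occupancy is the normalized mean sojourn time", {
  expect_equal(stage_occupancy(make_cell_cycle(4, mean_T = 1)), rep(0.25, 4))
  expect_equal(stage_occupancy(make_cell_cycle(2, lambdas = c(1, 3))),
               c(0.75, 0.25))
  set.seed(3)
  cc <- make_cell_cycle(6, lambdas = rexp(6) + 0.1)
  expect_equal(sum(stage_occupancy(cc)), 1)
})

test_that("mean_protein matches closed forms and the brute-force oracle", {
  for (n in c(2, 5, 20, 101)) {
    cc <- make_cell_cycle(n, mean_T = 2)
    m <- model_spec(cc, make_strategy("constant", 3, cc),
                    burst_model("geometric1", mean = 4), partition_model(1))
    expect_equal(mean_protein(m), 4 * 2 * 3 * (3 / 2 + 1 / (2 * n)),
                 tolerance = 1e-12)
  }
  # deterministic-cycle limit: <x>/(<B> T k) -> 3/2 within 1e-4 at n = 1e4
  cc <- make_cell_cycle(1e4, mean_T = 2)
  m <- model_spec(cc, make_strategy("constant", 1, cc),
                  burst_model("geometric1", mean = 4), partition_model(1))
  expect_equal(mean_protein(m) / (4 * 2 * 1), 1.5, tolerance = 1e-4)

  set.seed(11)
  for (rep in 1:10) {
    m <- random_model()
    expect_equal(mean_protein(m), brute_mean_protein(m), tolerance = 1e-12)
  }
})

test_that("conditional means are consistent with the stage-resolved formula", {
  cc <- make_cell_cycle(50, mean_T = 2)
  m <- model_spec(cc, make_strategy("constant", 3, cc),
                  burst_model("geometric1", mean = 4), partition_model(1))
  cm <- conditional_mean(m)
  # last stage holds twice the per-cycle synthesis: 2 <B> k T exactly
  expect_equal(cm[50], 2 * 4 * 3 * 2, tolerance = 1e-12)
  expect_true(all(diff(cm) >= 0))
  expect_equal(sum(cm * stage_occupancy(cc)), mean_protein(m),
               tolerance = 1e-12)

  # start-only expression: every stage carries 2 <B> k_1 / lambda_1
  set.seed(5)
  cc2 <- make_cell_cycle(5, lambdas = rexp(5) + 0.2)
  ms <- model_spec(cc2, make_strategy("start_only", 4, cc2),
                   burst_model("geometric0", mean = 2), partition_model(1))
  expect_equal(conditional_mean(ms),
               rep(2 * 2 * 4 / cc2$lambdas[1], 5), tolerance = 1e-12)
})

test_that("beta matches its closed forms and the brute-force double sums", {
  cc20 <- make_cell_cycle(20, mean_T = 2)
  b <- burst_model("geometric1", mean = 4)
  expect_equal(regulation_beta(
    model_spec(cc20, make_strategy("constant", 1, cc20), b)), 40 / 21,
    tolerance = 1e-12)
  # constant k, equal rates: beta = 2n/(n+1) for every n
  for (n in c(1, 2, 7, 64, 301)) {
    cc <- make_cell_cycle(n, mean_T = 1.3)
    m <- model_spec(cc, rep(2.5, n), b)
    expect_equal(regulation_beta(m), 2 * n / (n + 1), tolerance = 1e-12)
  }
  # start-only gives beta = 1 on any cycle, end-only gives beta_max
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(2:9, 1)
    cc <- make_cell_cycle(n, lambdas = exp(runif(n, -1, 1)))
    expect_equal(regulation_beta(
      model_spec(cc, make_strategy("start_only", 2, cc), b)), 1,
      tolerance = 1e-12)
    expect_equal(regulation_beta(
      model_spec(cc, make_strategy("end_only", 2, cc), b)),
      unname(beta_bounds(cc)["upper"]), tolerance = 1e-12)
    m <- random_model()
    expect_equal(regulation_beta(m), brute_beta(m), tolerance = 1e-12)
    bts <- beta_bounds(m$cycle)
    expect_gte(regulation_beta(m), bts["lower"] - 1e-12)
    expect_lte(regulation_beta(m), bts["upper"] + 1e-12)
  }
})

test_that("beta_bounds covers the documented cases", {
  expect_equal(beta_bounds(make_cell_cycle(20, mean_T = 2)),
               c(lower = 1, upper = 20))
  expect_equal(beta_bounds(make_cell_cycle(1, mean_T = 2)),
               c(lower = 1, upper = 1))
  wide <- make_cell_cycle(3, lambdas = c(1, 1, 1e8))
  expect_gt(beta_bounds(wide)["upper"], 1e7)
})

test_that("noise decomposition reproduces the limiting coefficients", {
  b <- burst_model("geometric1", mean = 4)
  b2b <- b$second_moment / b$mean
  alpha <- 0.7
  # beta = 2 (no regulation, deterministic cycle): 5/9 and 4 alpha / 9
  co2 <- noise_coefficients(2, b, alpha)
  expect_equal(unname(co2["burst"]), 5 / 9 * b2b, tolerance = 1e-12)
  expect_equal(unname(co2["partition"]), 4 * alpha / 9, tolerance = 1e-12)
  # beta = 1 (start-only): 2/3 and alpha/3
  co1 <- noise_coefficients(1, b, alpha)
  expect_equal(unname(co1["burst"]), 2 / 3 * b2b, tolerance = 1e-12)
  expect_equal(unname(co1["partition"]), alpha / 3, tolerance = 1e-12)
  # beta = Inf (end-only, vanishing last stage): 1/3 and 2 alpha / 3
  coI <- noise_coefficients(Inf, b, alpha)
  expect_equal(unname(coI["burst"]), 1 / 3 * b2b, tolerance = 1e-12)
  expect_equal(unname(coI["partition"]), 2 * alpha / 3, tolerance = 1e-12)
})

test_that("Poisson identity: B = 1, alpha = 1 gives eta * <x> = 1", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(1:8, 1)
    cc <- make_cell_cycle(n, lambdas = exp(runif(n, -1, 1)))
    ks <- rexp(n)
    m <- model_spec(cc, ks, burst_model("deterministic", mean = 1),
                    partition_model(1))
    ns <- noise_decomposition(m)
    expect_equal(ns$eta_total * ns$mean_x, 1, tolerance = 1e-12)
  }
})

test_that("the two noise terms move in opposite directions with beta", {
  b <- burst_model("geometric1", mean = 4)
  grid <- c(1, 1.5, 2, 4, 10, 100, 1e4)
  cos <- sapply(grid, function(bb) noise_coefficients(bb, b, alpha = 1))
  expect_true(all(diff(cos["burst", ]) < 0))
  expect_true(all(diff(cos["partition", ]) > 0))
})

test_that("noise summary is internally consistent", {
  set.seed(17)
  for (rep in 1:5) {
    m <- random_model()
    ns <- noise_decomposition(m)
    expect_equal(ns$eta_total, ns$eta_burst + ns$eta_partition,
                 tolerance = 1e-12)
    expect_true(all(c(ns$eta_burst, ns$eta_partition) >= 0))
    expect_gte(ns$beta, 1 - 1e-12)
  }
})

test_that("molecule budget per cycle matches the strategy accounting", {
  b <- burst_model("geometric1", mean = 4)
  cc <- make_cell_cycle(2000, mean_T = 2)  # near-deterministic cycle
  # constant rate: 2 <x> / 3 molecules per cycle
  m <- model_spec(cc, make_strategy("constant", 1, cc), b)
  mpc <- molecules_per_cycle(m)
  expect_equal(mpc$molecules_per_cycle / mean_protein(m), 2 / 3,
               tolerance = 1e-3)
  expect_equal(mpc$molecules_per_cycle, 4 * mpc$bursts_per_cycle)
  # start-only: <x>/2 per cycle (exact for any cycle)
  ms <- model_spec(cc, make_strategy("start_only", 1, cc), b)
  expect_equal(molecules_per_cycle(ms)$molecules_per_cycle / mean_protein(ms),
               1 / 2, tolerance = 1e-12)
  # end-only: <x> per cycle in the deterministic-cycle limit
  me <- model_spec(cc, make_strategy("end_only", 1, cc), b)
  expect_equal(molecules_per_cycle(me)$molecules_per_cycle / mean_protein(me),
               1, tolerance = 1e-3)
})
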