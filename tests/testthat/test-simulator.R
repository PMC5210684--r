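test_that("partition_sample has conditional mean x/2 and variance alpha*x/4", {
  set.seed(53)
  # alpha = 0, even x: exact halving with probability one
  expect_equal(partition_sample(rep(100, 50), partition_model(0)),
               rep(50, 50))
  # alpha = 0, odd x: randomized rounding preserves the mean
  odd <- partition_sample(rep(101, 4000), partition_model(0))
  expect_true(all(odd %in% c(50, 51)))
  expect_equal(mean(odd), 50.5, tolerance = 0.01)

  check_moments <- function(alpha, x, ndraw, tol_var) {
    draws <- partition_sample(rep(x, ndraw), partition_model(alpha))
    expect_true(all(draws >= 0 & draws <= x))
    expect_equal(mean(draws), x / 2, tolerance = 4 * sqrt(x / 4 / ndraw) / (x / 2) + 1e-9)
    if (alpha > 0) {
      expect_equal(var(draws), alpha * x / 4, tolerance = tol_var)
    }
  }
  check_moments(1, 1e6, 2e4, tol_var = 0.05)      # binomial
  check_moments(0.5, 10000, 4e4, tol_var = 0.05)  # sub-binomial mixture
  check_moments(2, 10000, 4e4, tol_var = 0.05)    # clustered, even x
  check_moments(2.5, 10000, 4e4, tol_var = 0.05)  # non-integer alpha > 1

  expect_error(partition_sample(-1, partition_model(1)), "non-negative")
  expect_error(partition_model(-0.5), "alpha")
})

test_that("a silent gene stays at zero", {
  cc <- make_cell_cycle(5, mean_T = 1)
  m <- model_spec(cc, rep(0, 5), burst_model("geometric1", mean = 4),
                  partition_model(1))
  traj <- simulate_lineage(m, n_cycles = 20, burn_in_cycles = 2, seed = 1)
  expect_true(all(traj$x == 0))
  expect_true(all(traj$z == 0))
})

test_that("identical seed and model give bit-identical trajectories", {
  m <- fig1_model(50)
  t1 <- simulate_lineage(m, n_cycles = 30, burn_in_cycles = 5, seed = 99)
  t2 <- simulate_lineage(m, n_cycles = 30, burn_in_cycles = 5, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_lineage(m, n_cycles = 30, burn_in_cycles = 5, seed = 100)
  expect_false(identical(t1$time, t3$time))
})

test_that("time-averaged statistics match the closed forms on the reference model", {
  m <- fig1_model(150)
  traj <- simulate_lineage(m, n_cycles = 1500, burn_in_cycles = 50, seed = 202)
  s <- estimate_stats(traj)
  ns <- noise_decomposition(m)

  # the two estimator routes for eta agree within their joint spread
  expect_equal(s$eta_z, s$eta_diff, tolerance = 0.15)
  # <x> ~ <y> (both estimate the same stationary mean)
  expect_equal(s$mean_x, s$mean_y, tolerance = 0.03)
  # mean and intrinsic noise within 3 batch-mean SE of the analytics
  expect_lt(abs(s$mean_x - ns$mean_x), 3 * s$se_mean_x)
  expect_lt(abs(s$eta_z - ns$eta_total), 3 * s$se_eta)

  # empirical stage occupancy matches 1/(lambda_i sum_j 1/lambda_j)
  segs <- diff(traj$time)
  occ <- as.numeric(tapply(segs, traj$stage[-nrow(traj)], sum))
  occ <- occ / sum(occ)
  expect_equal(occ, stage_occupancy(m$cycle), tolerance = 0.05)
})

test_that("Poisson identity holds in simulation for an uneven profile", {
  cc <- make_cell_cycle(6, lambdas = c(2, 5, 3, 8, 4, 6))
  m <- model_spec(cc, c(0, 40, 0, 10, 80, 0),
                  burst_model("deterministic", mean = 1), partition_model(1))
  traj <- simulate_lineage(m, n_cycles = 1200, burn_in_cycles = 50, seed = 77)
  s <- estimate_stats(traj)
  product <- s$eta_z * s$mean_x
  expect_lt(abs(product - 1), 3 * s$se_eta * s$mean_x)
})

test_that("two-colour assay recovers the intrinsic noise", {
  m <- fig1_model(150)
  tc <- simulate_two_colour(m, n_cycles = 1500, burn_in_cycles = 50,
                            seed = 303)
  ns <- noise_decomposition(m)
  expect_lt(abs(tc$eta_intrinsic - ns$eta_total), 3 * tc$se_eta)

  # non-bursty, error-free partitioning: burst-arrival noise only,
  # strictly positive and equal to the alpha = 0, <B^2>/<B> = 1 closed form
  cc <- make_cell_cycle(10, mean_T = 2)
  m0 <- model_spec(cc, make_strategy("constant", 60, cc),
                   burst_model("deterministic", mean = 1), partition_model(0))
  tc0 <- simulate_two_colour(m0, n_cycles = 1200, burn_in_cycles = 50,
                             seed = 304)
  ns0 <- noise_decomposition(m0)
  expect_gt(tc0$eta_intrinsic, 0)
  expect_lt(abs(tc0$eta_intrinsic - ns0$eta_total), 3.5 * tc0$se_eta)
})

test_that("degradation is honoured by the simulator and refused by analytics", {
  cc <- make_cell_cycle(10, mean_T = 2)
  m <- model_spec(cc, make_strategy("constant", 10, cc),
                  burst_model("geometric1", mean = 4), partition_model(1),
                  degradation_rate = 0.4)
  traj <- simulate_lineage(m, n_cycles = 400, burn_in_cycles = 40, seed = 9)
  s <- estimate_stats(traj)
  stable <- model_spec(cc, m$regulation, m$burst, m$partition)
  # decay lowers the mean below the stable-protein value; y tracks x
  expect_lt(s$mean_x, mean_protein(stable))
  expect_gt(s$mean_x, 0)
  expect_equal(s$mean_x, s$mean_y, tolerance = 0.1)
})

test_that("simulator input validation", {
  m <- fig1_model(50)
  expect_error(simulate_lineage(m, n_cycles = 10, burn_in_cycles = 10),
               "burn_in")
  expect_error(simulate_lineage(m, n_cycles = 0), "positive integer")
  bad <- model_spec(m$cycle, m$regulation,
                    burst_model("deterministic", mean = 1.5), m$partition)
  expect_error(simulate_lineage(bad, n_cycles = 10, burn_in_cycles = 2),
               "integer")
})
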