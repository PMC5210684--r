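# Independent oracles: deliberately brute-force O(n^2) double-loop
# evaluations of the steady-state mean, the per-stage moments and the
# regulation parameter beta, kept separate from the package's O(n)
# cumulative-sum implementations.

brute_mean_protein <- function(model) {
  lam <- model$cycle$lambdas
  k <- model$regulation
  n <- model$cycle$n
  s1 <- 0
  s2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) s1 <- s1 + k[j] / (lam[i] * lam[j])
    for (j in seq_len(i)) s2 <- s2 + k[j] / (lam[i] * lam[j])
  }
  model$burst$mean / sum(1 / lam) * (s1 + s2)
}

brute_beta <- function(model) {
  lam <- model$cycle$lambdas
  k <- model$regulation
  n <- model$cycle$n
  s1 <- 0
  s2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) s1 <- s1 + k[j] / (lam[i] * lam[j])
    for (j in seq_len(i)) s2 <- s2 + k[j] / (lam[i] * lam[j])
  }
  s1 / s2
}

# per-stage mixed moments <x c_i> at steady state, explicit closed form
brute_xc <- function(model) {
  lam <- model$cycle$lambdas
  k <- model$regulation
  n <- model$cycle$n
  q <- k / lam
  sapply(seq_len(n), function(i) {
    model$burst$mean / lam[i] * (sum(q) + sum(q[seq_len(i)])) / sum(1 / lam)
  })
}

random_model <- function(n_range = 2:8, alphas = c(0, 0.5, 1, 2),
                         kinds = c("geometric1", "geometric0",
                                   "deterministic")) {
  n <- sample(n_range, 1)
  cc <- make_cell_cycle(n, lambdas = exp(runif(n, -1.5, 1.5)))
  ks <- rexp(n)
  zero_out <- sample(0:(n - 1), 1)
  if (zero_out > 0) ks[sample(n, zero_out)] <- 0
  if (all(ks == 0)) ks[1] <- 1
  kind <- sample(kinds, 1)
  b <- burst_model(kind,
                   mean = if (kind == "deterministic") sample(1:5, 1)
                          else runif(1, 1, 6))
  model_spec(cc, ks, b, partition_model(sample(alphas, 1)))
}

# the reference parameter set: 20 equal stages over 2 h, geometric bursts of
# mean 4, binomial partitioning, constant rate calibrated to a target mean
fig1_model <- function(target_mean = 150) {
  cc <- make_cell_cycle(20, mean_T = 2)
  m <- model_spec(cc, make_strategy("constant", k = 1, cycle = cc),
                  burst_model("geometric1", mean = 4), partition_model(1))
  calibrate_rate(m, target_mean)
}
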