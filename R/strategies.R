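# Mathematically controlled comparison of cell-cycle regulation strategies:
# every strategy is recalibrated to the same mean protein level, so
# differences in noise reflect only when in the cycle the protein is made.

#' Compare regulation strategies at a fixed mean expression level
#'
#' Builds each named strategy (see [make_strategy()]), rescales it to the
#' common target mean with [calibrate_rate()], and scores it with
#' [noise_decomposition()]. Because the mean is shared, the products
#' `eta * <x>` isolate the effect of timing: bursty-synthesis noise is
#' highest for start-of-cycle expression and lowest for end-of-cycle
#' expression, and the partitioning-error contribution shows the exact
#' opposite ordering.
#'
#' @param names Character vector of strategy names.
#' @param cycle A [make_cell_cycle()] object.
#' @param burst A [burst_model()].
#' @param alpha Partitioning-error magnitude (default 1, binomial).
#' @param target_mean Common mean copy number for all strategies.
#' @return An object of class `"strategy_comparison"`: a data frame with
#'   columns `strategy`, `k` (calibrated base rate), `beta`,
#'   `eta_burst_x` and `eta_partition_x` (the `eta * <x>` products),
#'   `eta_total`, sorted by decreasing bursty-synthesis noise.
#' @export
compare_strategies <- function(names, cycle, burst, alpha = 1, target_mean) {
  stopifnot(inherits(cycle, "cell_cycle"), inherits(burst, "burst_model"))
  part <- partition_model(alpha)
  rows <- lapply(names, function(nm) {
    prof <- make_strategy(nm, k = 1, cycle = cycle)
    m <- calibrate_rate(model_spec(cycle, prof, burst, part), target_mean)
    ns <- noise_decomposition(m)
    i1 <- which(prof > 0)[1L]
    data.frame(strategy = nm,
               k = m$regulation[i1] / prof[i1],  # calibrated base rate
               beta = ns$beta,
               eta_burst_x = ns$eta_burst * ns$mean_x,
               eta_partition_x = ns$eta_partition * ns$mean_x,
               eta_total = ns$eta_total,
               mean_x = ns$mean_x,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$eta_burst_x), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_mean") <- target_mean
  class(out) <- c("strategy_comparison", "data.frame")
  out
}

#' Scan gene-duplication timing and fold change
#'
#' Models an `f`-fold jump in the synthesis rate (from `k` to `f k`) at a
#' time `T1` into a near-deterministic cell cycle (equal-rate stages, large
#' `n`). For every grid point the step profile is recalibrated to the target
#' mean and the bursty-synthesis noise is recorded, normalized to the
#' constant-rate (`f = 1`) strategy at the same mean. For fixed `T1` the
#' normalized noise always decreases with `f`; the grid minimum sits at the
#' largest fold change with the switch closest to the end of the cycle.
#'
#' @param cycle An equal-rate [make_cell_cycle()]; use a large `n` (e.g. 200)
#'   to approximate deterministic stage timing.
#' @param burst A [burst_model()].
#' @param alpha Partitioning-error magnitude.
#' @param target_mean Common mean copy number.
#' @param t1_fractions Grid of switch times as fractions of the cycle, in
#'   `(0, 1)`; values off a stage boundary are rounded (with a warning from
#'   [make_strategy()]).
#' @param folds Grid of fold changes, all `>= 1`.
#' @return Data frame with columns `t1_frac`, `fold`, `eta_burst_normalized`.
#' @export
duplication_scan <- function(cycle, burst, alpha = 1, target_mean,
                             t1_fractions, folds) {
  stopifnot(inherits(cycle, "cell_cycle"))
  if (length(t1_fractions) == 0 || length(folds) == 0) {
    stopf("'t1_fractions' and 'folds' must be non-empty grids")
  }
  if (any(t1_fractions <= 0) || any(t1_fractions >= 1)) {
    stopf("'t1_fractions' must lie strictly inside (0, 1)")
  }
  if (any(folds < 1)) stopf("all fold changes must be >= 1")
  part <- partition_model(alpha)
  baseline <- noise_decomposition(calibrate_rate(
    model_spec(cycle, make_strategy("constant", 1, cycle), burst, part),
    target_mean))$eta_burst

  grid <- expand.grid(t1_frac = t1_fractions, fold = folds,
                      KEEP.OUT.ATTRS = FALSE)
  grid$eta_burst_normalized <- vapply(seq_len(nrow(grid)), function(r) {
    prof <- make_strategy("step", 1, cycle,
                          params = list(T1_fraction = grid$t1_frac[r],
                                        fold = grid$fold[r]))
    m <- calibrate_rate(model_spec(cycle, prof, burst, part), target_mean)
    noise_decomposition(m)$eta_burst / baseline
  }, numeric(1))
  grid
}

# vectorized beta over rows of a profile matrix (Eq. of regulation_beta,
# factorized through cumulative sums)
beta_for_profiles <- function(K, lambdas) {
  w <- 1 / lambdas
  num_w <- w * sum(w)
  den_w <- w * rev(cumsum(rev(w)))
  as.numeric((K %*% num_w) / (K %*% den_w))
}

#' Extremize the regulation parameter over synthesis profiles
#'
#' Evaluates `beta` on the `n` canonical single-stage profiles and on
#' `n_samples` random profiles drawn uniformly from the simplex (flat
#' Dirichlet; `beta` is scale-invariant so only the direction matters), and
#' returns the observed extrema. The extrema are attained at vertices:
#' `beta = 1` for the stage-1-only profile and `beta = beta_max` (see
#' [beta_bounds()]) for the stage-`n`-only profile, so the random sampling
#' is a sanity net over the interior rather than an optimizer.
#'
#' @param cycle A [make_cell_cycle()] object with `n >= 2`.
#' @param n_samples Number of random simplex profiles.
#' @param seed Optional integer seed.
#' @return List with `min_profile`, `min_beta`, `max_profile`, `max_beta`,
#'   `n_evaluated`, and the vector `betas` of all evaluated values.
#' @export
extremize_beta <- function(cycle, n_samples = 10000L, seed = NULL) {
  stopifnot(inherits(cycle, "cell_cycle"))
  if (cycle$n < 2) stopf("extremizing beta needs at least 2 stages")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- cycle$n
  K <- matrix(stats::rexp(n_samples * n), n_samples, n)
  K <- K / rowSums(K)
  K <- rbind(diag(n), K)  # canonical single-stage profiles first
  betas <- beta_for_profiles(K, cycle$lambdas)
  imin <- which.min(betas)
  imax <- which.max(betas)
  list(min_profile = K[imin, ], min_beta = betas[imin],
       max_profile = K[imax, ], max_beta = betas[imax],
       n_evaluated = nrow(K), betas = betas)
}
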