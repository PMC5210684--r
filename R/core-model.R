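# Model objects: cell cycle, regulation profile, burst-size model,
# partitioning model, and the combined model specification.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Construct a multi-stage cell-cycle specification
#'
#' The cell cycle is modelled phenomenologically as `n` sequential stages
#' `C_1, ..., C_n`. A newborn cell is in stage 1 and leaves stage `i` at rate
#' `lambda_i` (so the stage-`i` sojourn is exponential with mean
#' `1/lambda_i`); division is triggered on exit from stage `n`. The total
#' cycle duration is a sum of independent exponentials, i.e. Erlang when all
#' rates are equal, with squared coefficient of variation `1/n` in that case.
#'
#' @param n Number of stages (positive integer).
#' @param mean_T Mean cycle duration in hours. Used to set equal stage exit
#'   rates `lambda_i = n / mean_T` when `lambdas` is not supplied.
#' @param lambdas Optional explicit vector of `n` positive stage exit rates
#'   (per hour). When given, `mean_T` is ignored and the mean cycle time is
#'   `sum(1 / lambdas)`.
#' @return An object of class `"cell_cycle"` with fields `n`, `lambdas` and
#'   `mean_T`.
#' @examples
#' cc <- make_cell_cycle(20, mean_T = 2)
#' cc$lambdas[1]          # 10 per hour
#' cycle_time_cv2(cc)     # 1/20 = 0.05
#' @export
make_cell_cycle <- function(n, mean_T = NULL, lambdas = NULL) {
  if (!is_count(n)) stopf("'n' must be a positive integer, got %s", format(n))
  n <- as.integer(n)
  if (is.null(lambdas)) {
    if (is.null(mean_T) || !is.numeric(mean_T) || length(mean_T) != 1L ||
        !is.finite(mean_T) || mean_T <= 0) {
      stopf("'mean_T' must be a positive duration (hours) when 'lambdas' is omitted")
    }
    lambdas <- rep(n / mean_T, n)
  } else {
    lambdas <- as.numeric(lambdas)
    if (length(lambdas) != n) {
      stopf("'lambdas' must have length n = %d, got %d", n, length(lambdas))
    }
    if (any(!is.finite(lambdas)) || any(lambdas <= 0)) {
      stopf("all 'lambdas' must be positive and finite")
    }
  }
  structure(
    list(n = n, lambdas = lambdas, mean_T = sum(1 / lambdas)),
    class = "cell_cycle"
  )
}

#' Squared coefficient of variation of the cell-cycle duration
#'
#' The cycle time is a sum of independent exponential sojourns, so
#' `CV^2 = sum(1/lambda_i^2) / (sum(1/lambda_i))^2`; equal rates give `1/n`.
#'
#' @param cycle A [make_cell_cycle()] object.
#' @return The squared CV of the total cycle duration.
#' @export
cycle_time_cv2 <- function(cycle) {
  stopifnot(inherits(cycle, "cell_cycle"))
  sum(1 / cycle$lambdas^2) / sum(1 / cycle$lambdas)^2
}

#' @export
print.cell_cycle <- function(x, ...) {
  cat(sprintf("cell cycle: %d stage(s), mean duration %.4g h, CV^2 = %.4g\n",
              x$n, x$mean_T, cycle_time_cv2(x)))
  invisible(x)
}

#' Burst-size distribution
#'
#' Protein is produced in instantaneous bursts; each burst adds `B` molecules,
#' drawn independently from this distribution. Only the first two moments
#' enter the closed-form analytics; the simulator draws actual burst sizes.
#'
#' Supported kinds:
#' * `"deterministic"`: `B = mean` with probability one.
#' * `"geometric0"`: geometric on support 0, 1, 2, ... with the given mean
#'   `m`; second moment `m (2 m + 1)`.
#' * `"geometric1"`: shifted geometric on support 1, 2, ... (every burst makes
#'   at least one molecule) with mean `m >= 1`; second moment `m (2 m - 1)`.
#' * `"custom"`: arbitrary probability mass function `pmf` over counts
#'   `0, 1, ..., length(pmf) - 1`.
#'
#' @param kind One of `"geometric1"`, `"geometric0"`, `"deterministic"`,
#'   `"custom"`.
#' @param mean Mean burst size (ignored for `"custom"`).
#' @param pmf Probability mass function over `0:(length(pmf) - 1)` for
#'   `kind = "custom"`.
#' @return An object of class `"burst_model"` with fields `kind`, `mean`,
#'   `second_moment` and a sampler.
#' @examples
#' b <- burst_model("geometric1", mean = 4)
#' b$second_moment            # 4 * 7 = 28
#' @export
burst_model <- function(kind = c("geometric1", "geometric0", "deterministic",
                                 "custom"),
                        mean = NULL, pmf = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(pmf) || any(!is.finite(pmf)) || any(pmf < 0) ||
        abs(sum(pmf) - 1) > 1e-10) {
      stopf("'pmf' must be a non-negative vector summing to 1")
    }
    support <- seq_along(pmf) - 1
    m1 <- sum(support * pmf)
    m2 <- sum(support^2 * pmf)
    if (m1 <= 0) stopf("custom burst pmf must have positive mean")
    sample_fun <- function(nn) sample(support, nn, replace = TRUE, prob = pmf)
  } else {
    if (is.null(mean) || !is.numeric(mean) || length(mean) != 1L ||
        !is.finite(mean) || mean <= 0) {
      stopf("'mean' must be a single positive number")
    }
    m1 <- mean
    if (kind == "deterministic") {
      m2 <- mean^2
      sample_fun <- function(nn) rep(mean, nn)
    } else if (kind == "geometric0") {
      # success prob p with (1 - p)/p = mean
      p <- 1 / (1 + mean)
      m2 <- mean * (2 * mean + 1)
      sample_fun <- function(nn) stats::rgeom(nn, p)
    } else { # geometric1, support {1, 2, ...}
      if (mean < 1) stopf("geometric1 bursts need mean >= 1")
      p <- 1 / mean
      m2 <- mean * (2 * mean - 1)
      sample_fun <- function(nn) stats::rgeom(nn, p) + 1
    }
  }
  structure(
    list(kind = kind, mean = m1, second_moment = m2, sample = sample_fun,
         pmf = pmf),
    class = "burst_model"
  )
}

#' @export
print.burst_model <- function(x, ...) {
  cat(sprintf("burst model: %s, <B> = %.4g, <B^2> = %.4g\n",
              x$kind, x$mean, x$second_moment))
  invisible(x)
}

#' Molecule partitioning model at cell division
#'
#' At division the `x` molecules of the mother are split between daughters.
#' Conditional on `x`, the inherited count `x_+` has mean `x/2` and variance
#' `alpha * x / 4`. `alpha = 0` is deterministic halving, `alpha = 1` is
#' binomial partitioning (each molecule independently assigned to a daughter),
#' `alpha < 1` models sub-binomial control, and `alpha > 1` models clustered
#' (super-binomial) segregation, e.g. molecules riding inside organelles.
#'
#' @param alpha Non-negative partitioning-error magnitude.
#' @param kind Sampler family; by default chosen from `alpha`:
#'   `"deterministic-half"` (`alpha = 0`), `"binomial"` (`alpha = 1`),
#'   `"mixture-subbinomial"` (`0 < alpha < 1`),
#'   `"clustered-superbinomial"` (`alpha > 1`).
#' @return An object of class `"partition_model"`.
#' @seealso [partition_sample()] for the sampler itself.
#' @export
partition_model <- function(alpha = 1, kind = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stopf("'alpha' must be a single non-negative number")
  }
  if (is.null(kind)) {
    kind <- if (alpha == 0) "deterministic-half"
            else if (alpha == 1) "binomial"
            else if (alpha < 1) "mixture-subbinomial"
            else "clustered-superbinomial"
  }
  kind <- match.arg(kind, c("deterministic-half", "binomial",
                            "mixture-subbinomial", "clustered-superbinomial"))
  structure(list(alpha = alpha, kind = kind), class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("partitioning: %s, alpha = %.4g\n", x$kind, x$alpha))
  invisible(x)
}

#' Combine components into a full model specification
#'
#' @param cycle A [make_cell_cycle()] object.
#' @param regulation Numeric vector of `n` non-negative burst arrival rates
#'   `k_i` (bursts per hour in stage `i`), e.g. from [make_strategy()].
#' @param burst A [burst_model()].
#' @param partition A [partition_model()]; default binomial (`alpha = 1`).
#' @param degradation_rate First-order protein decay rate per hour
#'   (default 0). A positive rate is a simulator-only extension: the
#'   closed-form analytics and the moment solver assume a stable protein and
#'   refuse models with degradation.
#' @return An object of class `"model_spec"`.
#' @examples
#' cc <- make_cell_cycle(20, mean_T = 2)
#' m <- model_spec(cc, make_strategy("constant", k = 1, cycle = cc),
#'                 burst_model("geometric1", mean = 4))
#' @export
model_spec <- function(cycle, regulation, burst,
                       partition = partition_model(1),
                       degradation_rate = 0) {
  stopifnot(inherits(cycle, "cell_cycle"), inherits(burst, "burst_model"),
            inherits(partition, "partition_model"))
  regulation <- as.numeric(regulation)
  if (length(regulation) != cycle$n) {
    stopf("'regulation' must have length n = %d, got %d",
          cycle$n, length(regulation))
  }
  if (any(!is.finite(regulation)) || any(regulation < 0)) {
    stopf("all burst arrival rates k_i must be finite and >= 0")
  }
  if (!is.numeric(degradation_rate) || length(degradation_rate) != 1L ||
      !is.finite(degradation_rate) || degradation_rate < 0) {
    stopf("'degradation_rate' must be a single non-negative number")
  }
  structure(
    list(cycle = cycle, regulation = regulation, burst = burst,
         partition = partition, degradation_rate = degradation_rate),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  print(x$cycle)
  cat(sprintf("burst arrival rates k_i: %s\n",
              paste(signif(x$regulation, 4), collapse = " ")))
  print(x$burst)
  print(x$partition)
  if (x$degradation_rate > 0) {
    cat(sprintf("protein degradation rate: %.4g per hour (simulator only)\n",
                x$degradation_rate))
  }
  invisible(x)
}

# analytics and the moment solver require a stable protein
require_no_degradation <- function(model) {
  if (model$degradation_rate > 0) {
    stopf(paste("closed-form analytics require degradation_rate = 0;",
                "use the stochastic simulator for decaying proteins"))
  }
  invisible(model)
}

require_active_profile <- function(ks) {
  if (all(ks == 0)) stopf("regulation profile is identically zero")
  invisible(ks)
}

#' Canonical cell-cycle regulation strategies
#'
#' Builds a per-stage burst-arrival-rate profile `k_1..k_n` for the standard
#' strategies used to compare cell-cycle coupling at fixed mean expression:
#'
#' * `"constant"`: `k_i = k` in every stage (dosage-compensated expression).
#' * `"duplication_midpoint"`: `k` in the first half of the cycle, `2k`
#'   afterwards (gene duplication at the cycle midpoint); requires even `n`.
#' * `"start_only"`: expression only in stage 1.
#' * `"end_only"`: expression only in stage `n` (just before division).
#' * `"midpoint_only"`: expression only in stage `n/2`; requires even `n`.
#' * `"step"`: `k` before a boundary placed at a fraction `T1_fraction` of the
#'   cycle, `fold * k` after it (an `f`-fold dosage change at duplication
#'   time `T1`). The continuous fraction is mapped onto the nearest stage
#'   boundary of an equal-rate cycle, `round(n * T1_fraction)`; off-boundary
#'   values are rounded with a warning.
#'
#' @param name Strategy name (see above).
#' @param k Base burst arrival rate (bursts per hour).
#' @param cycle A [make_cell_cycle()] object supplying `n`.
#' @param params For `"step"`: `list(T1_fraction =, fold =)` with
#'   `T1_fraction` in `[0, 1]` and `fold > 0`.
#' @return Numeric vector of `n` rates.
#' @examples
#' cc4 <- make_cell_cycle(4, mean_T = 2)
#' make_strategy("duplication_midpoint", k = 1, cycle = cc4)  # 1 1 2 2
#' @export
make_strategy <- function(name = c("constant", "duplication_midpoint",
                                   "start_only", "end_only", "midpoint_only",
                                   "step"),
                          k, cycle, params = list()) {
  name <- match.arg(name)
  stopifnot(inherits(cycle, "cell_cycle"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stopf("'k' must be a single non-negative rate")
  }
  n <- cycle$n
  ks <- numeric(n)
  if (name %in% c("duplication_midpoint", "midpoint_only") && n %% 2 != 0) {
    stopf("strategy '%s' requires an even number of stages, got n = %d",
          name, n)
  }
  switch(name,
    constant = ks[] <- k,
    duplication_midpoint = {
      ks[seq_len(n / 2)] <- k
      ks[(n / 2 + 1):n] <- 2 * k
    },
    start_only = ks[1] <- k,
    end_only = ks[n] <- k,
    midpoint_only = ks[n / 2] <- k,
    step = {
      t1 <- params$T1_fraction
      f <- params$fold
      if (is.null(t1) || !is.numeric(t1) || t1 < 0 || t1 > 1) {
        stopf("step strategy needs params$T1_fraction in [0, 1]")
      }
      if (is.null(f) || !is.numeric(f) || f <= 0) {
        stopf("step strategy needs params$fold > 0")
      }
      boundary <- round(n * t1)
      if (abs(n * t1 - boundary) > 1e-8) {
        warning(sprintf(
          "T1_fraction = %g is not on a stage boundary; switching after stage %d",
          t1, boundary), call. = FALSE)
      }
      ks[] <- f * k
      if (boundary >= 1) ks[seq_len(min(boundary, n))] <- k
    }
  )
  ks
}

#' Rescale a regulation profile to achieve a target mean protein level
#'
#' The steady-state mean is homogeneous of degree 1 in the profile
#' `k_1..k_n`, so a single positive factor `target_mean / mean_protein(model)`
#' brings the model to any desired mean. This is the "mathematically
#' controlled comparison" device: strategies are compared at equal mean.
#'
#' @param model A [model_spec()] with `degradation_rate = 0` and a profile
#'   that is not identically zero.
#' @param target_mean Desired steady-state mean copy number (> 0).
#' @return A copy of `model` with the rescaled profile.
#' @export
calibrate_rate <- function(model, target_mean) {
  stopifnot(inherits(model, "model_spec"))
  require_no_degradation(model)
  require_active_profile(model$regulation)
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      !is.finite(target_mean) || target_mean <= 0) {
    stopf("'target_mean' must be a single positive number")
  }
  scale <- target_mean / mean_protein(model)
  model$regulation <- model$regulation * scale
  model
}
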