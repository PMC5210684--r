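# Exact event-driven stochastic simulation of a single-cell lineage.
#
# No time discretization anywhere: within a stage the next event is drawn by
# exponential competition between burst arrival (rate k_i), stage exit
# (rate lambda_i) and, optionally, first-order protein decay (rate d * x).
# Alongside the integer copy number x(t) the simulator propagates its
# deterministic counterpart y(t) (growth rate <B> k_i, exact halving at
# division); z(t) = x(t) - y(t) is the cell-cycle-corrected fluctuation
# whose steady-state variance defines the intrinsic noise eta.

#' Sample a daughter's inherited copy number at division
#'
#' Draws `x_+` from a mother with `x` molecules such that, conditional on
#' `x`, the mean is `x/2` and the variance `alpha * x / 4`:
#'
#' * `alpha = 0`: deterministic halving. On odd `x` an exact integer half
#'   does not exist; floor/ceil randomized rounding preserves the mean
#'   exactly and adds variance 1/4 on odd counts only.
#' * `alpha = 1`: binomial, each molecule independently assigned.
#' * `0 < alpha < 1`: mixture — binomial with probability `alpha`, otherwise
#'   deterministic halving.
#' * `alpha > 1`: clustered segregation — molecules are grouped into clusters
#'   of integer size `m` (randomized between `floor(alpha)` and
#'   `ceiling(alpha)` to hit non-integer `alpha` in expectation) and clusters
#'   partition binomially; the `x mod m` remainder partitions binomially.
#'
#' @param x Vector of non-negative integer mother copy numbers (one draw per
#'   element).
#' @param partition A [partition_model()].
#' @return Integer-valued vector of daughter copy numbers, each `<= x`.
#' @export
partition_sample <- function(x, partition) {
  stopifnot(inherits(partition, "partition_model"))
  if (any(x < 0) || any(x != round(x))) {
    stopf("'x' must contain non-negative integers")
  }
  len <- length(x)
  alpha <- partition$alpha
  det_half <- function(v) {
    fl <- floor(v / 2)
    fl + stats::rbinom(length(v), 1L, v / 2 - fl)
  }
  out <- switch(partition$kind,
    "deterministic-half" = det_half(x),
    "binomial" = stats::rbinom(len, x, 0.5),
    "mixture-subbinomial" = {
      pick <- stats::runif(len) < alpha
      res <- numeric(len)
      res[pick] <- stats::rbinom(sum(pick), x[pick], 0.5)
      res[!pick] <- det_half(x[!pick])
      res
    },
    "clustered-superbinomial" = {
      m_lo <- floor(alpha)
      m <- m_lo + (stats::runif(len) < (alpha - m_lo))
      ncl <- x %/% m
      rem <- x %% m
      m * stats::rbinom(len, ncl, 0.5) + stats::rbinom(len, rem, 0.5)
    }
  )
  as.numeric(out)
}

#' Sample total cell-cycle durations
#'
#' Draws i.i.d. cycle durations as sums of the `n` exponential stage
#' sojourns — Erlang for equal rates, hypoexponential otherwise.
#'
#' @param cycle A [make_cell_cycle()] object.
#' @param n_cycles Number of durations to draw.
#' @return Numeric vector of `n_cycles` durations (hours).
#' @export
sample_cycle_durations <- function(cycle, n_cycles) {
  stopifnot(inherits(cycle, "cell_cycle"), is_count(n_cycles))
  n <- cycle$n
  soj <- matrix(stats::rexp(n_cycles * n, rate = rep(cycle$lambdas, each = n_cycles)),
                nrow = n_cycles, ncol = n)
  rowSums(soj)
}

# Cycle-invariant birth level of the deterministic counterpart y(t), used as
# the default initial condition to shorten burn-in. Without degradation the
# fixed point is closed form: y_birth = <B> sum_i k_i / lambda_i (what a
# deterministic cycle adds, halved at division). With degradation, iterate
# a deterministic cycle at the expected sojourns to convergence.
invariant_y_birth <- function(model) {
  mB <- model$burst$mean
  k <- model$regulation
  lam <- model$cycle$lambdas
  d <- model$degradation_rate
  if (d == 0) return(mB * sum(k / lam))
  y <- mB * sum(k / lam)
  for (rep in seq_len(10000)) {
    y_new <- y
    for (i in seq_along(lam)) {
      a <- mB * k[i] / d
      y_new <- a + (y_new - a) * exp(-d / lam[i])
    }
    y_new <- y_new / 2
    if (abs(y_new - y) < 1e-12 * (1 + abs(y))) { y <- y_new; break }
    y <- y_new
  }
  y
}

#' Simulate a single-cell lineage through many cell cycles
#'
#' Exact continuous-time simulation of the coupled cell-cycle/expression
#' model: stage sojourns are exponential, bursts arrive as a stage-modulated
#' Poisson process and add a random `B` to `x`, optional first-order decay
#' removes single molecules, and at each division `x` is partitioned by
#' [partition_sample()], `y` is exactly halved, and a single daughter is
#' followed (single-lineage statistics; no population tree).
#'
#' @param model A [model_spec()]. `degradation_rate > 0` is honoured here
#'   (simulator-only extension).
#' @param n_cycles Total number of cell cycles to simulate.
#' @param burn_in_cycles Default burn-in recorded on the trajectory and used
#'   by [estimate_stats()]; must be `< n_cycles`. Default 50.
#' @param seed Optional integer seed for exact reproducibility.
#' @param x0,y0 Optional initial copy number / deterministic level. By
#'   default `y0` is started at its cycle-invariant birth value and
#'   `x0 = round(y0)`, which shortens the transient.
#' @return An object of class `"lineage_trajectory"`: a data frame with one
#'   row per event (`time`, `generation`, `stage`, `x`, `y`, `z`, `event`
#'   in `{sample, stage-advance, burst, division, decay}`), each row holding
#'   the post-event state, with the model and burn-in attached as attributes.
#' @export
simulate_lineage <- function(model, n_cycles, burn_in_cycles = 50L,
                             seed = NULL, x0 = NULL, y0 = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (!is_count(n_cycles)) stopf("'n_cycles' must be a positive integer")
  if (!is.numeric(burn_in_cycles) || burn_in_cycles < 0 ||
      burn_in_cycles >= n_cycles) {
    stopf("need n_cycles > burn_in_cycles >= 0")
  }
  if (model$burst$kind == "deterministic" &&
      model$burst$mean != round(model$burst$mean)) {
    stopf("deterministic burst size must be an integer for simulation")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- model$cycle$n
  lam <- model$cycle$lambdas
  k <- model$regulation
  mB <- model$burst$mean
  d <- model$degradation_rate
  draw_burst <- model$burst$sample

  if (is.null(y0)) y0 <- invariant_y_birth(model)
  if (is.null(x0)) x0 <- max(0, round(y0))
  if (x0 < 0 || x0 != round(x0)) stopf("'x0' must be a non-negative integer")

  cap <- 4096L
  t_v <- numeric(cap); gen_v <- integer(cap); st_v <- integer(cap)
  x_v <- numeric(cap); y_v <- numeric(cap); ev_v <- integer(cap)
  m <- 0L

  tt <- 0; gen <- 1L; stage <- 1L; x <- x0; y <- y0
  m <- m + 1L
  t_v[m] <- tt; gen_v[m] <- gen; st_v[m] <- stage
  x_v[m] <- x; y_v[m] <- y; ev_v[m] <- 1L

  while (gen <= n_cycles) {
    rb <- k[stage]; rs <- lam[stage]; rd <- d * x
    tot <- rb + rs + rd
    dt <- stats::rexp(1L, tot)
    if (d == 0) {
      y <- y + mB * rb * dt
    } else {
      a <- mB * rb / d
      y <- a + (y - a) * exp(-d * dt)
    }
    tt <- tt + dt
    u <- stats::runif(1L) * tot
    if (u < rb) {
      x <- x + draw_burst(1L)
      ev <- 3L
    } else if (u < rb + rd) {
      x <- x - 1
      ev <- 5L
    } else if (stage < n) {
      stage <- stage + 1L
      ev <- 2L
    } else {
      x <- partition_sample(x, model$partition)
      y <- y / 2
      stage <- 1L
      gen <- gen + 1L
      ev <- 4L
    }
    if (m == cap) {
      cap <- cap * 2L
      length(t_v) <- cap; length(gen_v) <- cap; length(st_v) <- cap
      length(x_v) <- cap; length(y_v) <- cap; length(ev_v) <- cap
    }
    m <- m + 1L
    t_v[m] <- tt; gen_v[m] <- gen; st_v[m] <- stage
    x_v[m] <- x; y_v[m] <- y; ev_v[m] <- ev
  }

  idx <- seq_len(m)
  traj <- data.frame(
    time = t_v[idx], generation = gen_v[idx], stage = st_v[idx],
    x = x_v[idx], y = y_v[idx], z = x_v[idx] - y_v[idx],
    event = c("sample", "stage-advance", "burst", "division",
              "decay")[ev_v[idx]],
    stringsAsFactors = FALSE
  )
  attr(traj, "model") <- model
  attr(traj, "burn_in_cycles") <- burn_in_cycles
  attr(traj, "n_cycles") <- n_cycles
  class(traj) <- c("lineage_trajectory", "data.frame")
  traj
}

# Exact integrals of x, x^2, y, y^2, x*y over trajectory segments.
# x is piecewise constant; y is piecewise linear (no degradation) or
# piecewise exponential-relaxation (with degradation).
segment_integrals <- function(traj, model) {
  mrow <- nrow(traj)
  dt <- diff(traj$time)
  i <- seq_len(mrow - 1L)
  x <- traj$x[i]
  y0 <- traj$y[i]
  stg <- traj$stage[i]
  gen <- traj$generation[i]
  mB <- model$burst$mean
  d <- model$degradation_rate
  rate <- model$regulation[stg] * mB
  if (d == 0) {
    y1 <- y0 + rate * dt
    Iy <- dt * (y0 + y1) / 2
    Iy2 <- dt * (y0^2 + y0 * y1 + y1^2) / 3
  } else {
    a <- rate / d
    E <- exp(-d * dt)
    cc <- y0 - a
    Iy <- a * dt + cc * (1 - E) / d
    Iy2 <- a^2 * dt + 2 * a * cc * (1 - E) / d + cc^2 * (1 - E^2) / (2 * d)
  }
  list(dt = dt, gen = gen,
       Ix = x * dt, Ix2 = x^2 * dt, Iy = Iy, Iy2 = Iy2, Ixy = x * Iy)
}

#' Time-averaged statistics of a simulated lineage
#'
#' Computes exact time averages from the piecewise-constant `x` and
#' piecewise-linear (or exponential, under degradation) `y` segments —
#' closed-form segment integrals of `x, x^2, y, y^2, x y` and hence
#' `z^2 = (x - y)^2`; no snapshot sampling. Intrinsic noise is reported both
#' as `eta_z = <z^2> / <x>^2` and as the equivalent difference of total and
#' extrinsic noise, `<x^2>/<x>^2 - <y^2>/<y>^2`; the two agree up to Monte
#' Carlo error. Standard errors come from batch means over blocks of whole
#' cell cycles.
#'
#' @param traj A [simulate_lineage()] trajectory.
#' @param burn_in_cycles Cycles to discard; defaults to the trajectory's own
#'   burn-in attribute.
#' @param block_cycles Cycles per batch-mean block; default splits the
#'   retained cycles into ~30 blocks.
#' @return An object of class `"sim_summary"`: list with `mean_x`, `mean_y`,
#'   `total_noise`, `extrinsic_noise`, `eta_z`, `eta_diff`, `se_mean_x`,
#'   `se_eta`, `n_blocks`, `n_cycles`, `time_total`.
#' @export
estimate_stats <- function(traj, burn_in_cycles = NULL, block_cycles = NULL) {
  stopifnot(inherits(traj, "lineage_trajectory"))
  model <- attr(traj, "model")
  if (is.null(burn_in_cycles)) burn_in_cycles <- attr(traj, "burn_in_cycles")
  segs <- segment_integrals(traj, model)
  keep <- segs$gen > burn_in_cycles & segs$dt > 0
  if (!any(keep)) stopf("no trajectory left after burn-in")
  gen <- segs$gen[keep]
  n_cycles <- max(gen) - burn_in_cycles
  if (is.null(block_cycles)) block_cycles <- max(1L, n_cycles %/% 30L)
  block <- (gen - burn_in_cycles - 1L) %/% block_cycles

  sums <- function(v) rowsum(v[keep], block)
  Tb <- sums(segs$dt)
  Ixb <- sums(segs$Ix); Ix2b <- sums(segs$Ix2)
  Iyb <- sums(segs$Iy); Iy2b <- sums(segs$Iy2); Ixyb <- sums(segs$Ixy)
  Iz2b <- Ix2b - 2 * Ixyb + Iy2b

  Ttot <- sum(Tb)
  mx <- sum(Ixb) / Ttot
  mx2 <- sum(Ix2b) / Ttot
  my <- sum(Iyb) / Ttot
  my2 <- sum(Iy2b) / Ttot
  mz2 <- sum(Iz2b) / Ttot

  mean_x_b <- Ixb / Tb
  eta_b <- (Iz2b / Tb) / (Ixb / Tb)^2
  nb <- length(Tb)
  se <- function(v) if (nb > 1) stats::sd(v) / sqrt(nb) else NA_real_

  structure(
    list(mean_x = mx, mean_y = my,
         total_noise = mx2 / mx^2 - 1,
         extrinsic_noise = my2 / my^2 - 1,
         eta_z = mz2 / mx^2,
         eta_diff = mx2 / mx^2 - my2 / my^2,
         se_mean_x = se(mean_x_b),
         se_eta = se(eta_b),
         n_blocks = nb, n_cycles = n_cycles, time_total = Ttot),
    class = "sim_summary"
  )
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("lineage time averages over %d cycles (%d batch blocks)\n",
              x$n_cycles, x$n_blocks))
  cat(sprintf("  <x> = %.6g (se %.3g), <y> = %.6g\n",
              x$mean_x, x$se_mean_x, x$mean_y))
  cat(sprintf("  total noise = %.6g, extrinsic = %.6g\n",
              x$total_noise, x$extrinsic_noise))
  cat(sprintf("  eta (z-based) = %.6g (se %.3g), eta (difference) = %.6g\n",
              x$eta_z, x$se_eta, x$eta_diff))
  invisible(x)
}

#' Two-colour (dual-reporter) intrinsic-noise estimate
#'
#' Simulates two identically regulated reporter copies `x1`, `x2` that share
#' one cell's stage process and division times but have independent burst
#' arrivals, burst sizes and partitioning draws. The intrinsic noise is
#' estimated as `<(x1 - x2)^2> / (2 <x>^2)` from exact time averages, which
#' matches the `z`-based definition used by [estimate_stats()].
#'
#' @inheritParams simulate_lineage
#' @param block_cycles Cycles per batch-mean block for the standard error.
#' @return An object of class `"two_colour_summary"`: list with
#'   `eta_intrinsic`, `se_eta`, `mean_x`, `n_cycles`.
#' @export
simulate_two_colour <- function(model, n_cycles, burn_in_cycles = 50L,
                                seed = NULL, block_cycles = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (!is_count(n_cycles)) stopf("'n_cycles' must be a positive integer")
  if (burn_in_cycles < 0 || burn_in_cycles >= n_cycles) {
    stopf("need n_cycles > burn_in_cycles >= 0")
  }
  if (model$degradation_rate > 0) {
    stopf("two-colour mode supports stable proteins only")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- model$cycle$n
  lam <- model$cycle$lambdas
  k <- model$regulation
  G <- n_cycles

  # shared cell-cycle skeleton: sojourns tau[g, i], then window/division times
  tau <- matrix(stats::rexp(G * n, rate = rep(lam, each = G)), G, n)
  cyc_len <- rowSums(tau)
  div_time <- cumsum(cyc_len)
  gen_start <- c(0, div_time[-G])
  win_end <- t(apply(tau, 1L, cumsum))
  if (n == 1L) win_end <- matrix(win_end, ncol = 1L)
  win_start <- gen_start + cbind(0, win_end[, -n, drop = FALSE])

  x_birth0 <- max(0, round(invariant_y_birth(model)))

  one_colour <- function() {
    counts <- stats::rpois(G * n, lambda = rep(k, each = G) * as.numeric(tau))
    N <- sum(counts)
    wtimes <- rep(as.numeric(win_start), counts) +
      stats::runif(N) * rep(as.numeric(tau), counts)
    sizes <- model$burst$sample(N)
    gid <- rep(rep(seq_len(G), n), counts)
    o <- order(wtimes)
    wtimes <- wtimes[o]; sizes <- sizes[o]; gid <- gid[o]
    gen_totals <- numeric(G)
    if (N > 0) {
      tab <- rowsum(sizes, gid)
      gen_totals[as.integer(rownames(tab))] <- tab[, 1L]
    }
    # sequential division resets (one daughter followed)
    x_birth <- numeric(G + 1L)
    x_birth[1L] <- x_birth0
    for (g in seq_len(G)) {
      x_birth[g + 1L] <- partition_sample(x_birth[g] + gen_totals[g],
                                          model$partition)
    }
    cum <- cumsum(sizes)
    base <- c(0, cumsum(gen_totals))[gid]
    x_after <- x_birth[gid] + (cum - base)
    te <- c(wtimes, div_time)
    xe <- c(x_after, x_birth[-1L])
    o2 <- order(te, method = "radix")
    list(te = te[o2], xe = xe[o2], x0 = x_birth[1L])
  }

  c1 <- one_colour()
  c2 <- one_colour()

  tb <- sort(c(0, c1$te, c2$te), method = "radix")
  tb <- tb[tb < div_time[G]]
  dt <- diff(c(tb, div_time[G]))
  val_at <- function(col, tt) {
    idx <- findInterval(tt, col$te)
    ifelse(idx == 0L, col$x0, col$xe[pmax(idx, 1L)])
  }
  x1 <- val_at(c1, tb)
  x2 <- val_at(c2, tb)
  gen <- findInterval(tb, div_time) + 1L

  keep <- gen > burn_in_cycles & dt > 0
  gen <- gen[keep]; dt <- dt[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  nc <- G - burn_in_cycles
  if (is.null(block_cycles)) block_cycles <- max(1L, nc %/% 30L)
  block <- (gen - burn_in_cycles - 1L) %/% block_cycles

  Tb <- rowsum(dt, block)
  Id2 <- rowsum((x1 - x2)^2 * dt, block)
  Ix <- rowsum((x1 + x2) / 2 * dt, block)

  mx <- sum(Ix) / sum(Tb)
  eta <- (sum(Id2) / sum(Tb)) / (2 * mx^2)
  eta_b <- (Id2 / Tb) / (2 * (Ix / Tb)^2)
  nb <- length(Tb)
  structure(
    list(eta_intrinsic = eta,
         se_eta = if (nb > 1) stats::sd(eta_b) / sqrt(nb) else NA_real_,
         mean_x = mx, n_cycles = nc, n_blocks = nb),
    class = "two_colour_summary"
  )
}

#' @export
print.two_colour_summary <- function(x, ...) {
  cat(sprintf(
    "two-colour assay over %d cycles: eta = %.6g (se %.3g), <x> = %.6g\n",
    x$n_cycles, x$eta_intrinsic, x$se_eta, x$mean_x))
  invisible(x)
}
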