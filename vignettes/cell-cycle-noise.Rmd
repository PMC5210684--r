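---
title: "Methods: noise in cell-cycle-coupled bursty gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise in cell-cycle-coupled bursty gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclenoise)
```

# The model and its assumptions

`cyclenoise` studies a stable protein expressed in instantaneous bursts
whose arrival rate is coupled to cell-cycle progression. The assumptions
baked into the closed forms are worth stating explicitly:

* **Phenomenological cell cycle.** The cycle is a chain of `n` memoryless
  stages with exit rates `λ_i` (per hour); the cycle duration is a sum of
  exponentials. Equal rates `λ_i = n/T` give an Erlang(`n`) duration with
  mean `T` and squared CV `1/n`, so `n` doubles as a dial for cycle-timing
  noise: `n = 1` is a fully random (exponential) cycle, `n → ∞` a
  deterministic one. Successive cycles are independent (no mother–daughter
  correlation) except in the extended simulator.
* **Instantaneous bursts.** Each burst adds `B ≥ 0` molecules at a single
  time point. This is the short-lived-mRNA / short-lived-active-promoter
  limit; the extended simulator relaxes it.
* **Stable protein.** No degradation between divisions; dilution at
  division is the only loss. A first-order `degradation_rate` is accepted
  by the simulator only, and the analytics refuse such models loudly rather
  than silently ignoring the rate.
* **Single-lineage ensemble.** At each division exactly one daughter is
  followed. All statistics are long-run time averages along that lineage,
  which is the stationary ensemble the moment equations describe.
  Population-snapshot statistics (where fast-dividing subtrees are
  over-represented) are out of scope.
* **Partitioning.** Conditional on the mother's `x`, the inherited count
  has mean `x/2` and variance `αx/4`. All results hold for any `α ≥ 0`.

# Parameters that matter

| parameter | meaning | units | default |
|---|---|---|---|
| `n` | number of cell-cycle stages | — | 20 (reference set) |
| `T` / `λ_i` | mean cycle time / stage exit rates | h, 1/h | `T = 2`, equal rates |
| `k_i` | burst arrival rate in stage `i` | bursts/h | strategy-dependent |
| `⟨B⟩` | mean burst size | molecules | 4, geometric |
| `α` | partitioning-error magnitude | — | 1 (binomial) |

The reference parameter set (20 stages, 2 h cycle, geometric bursts of mean
4, binomial partitioning, mean calibrated to 150 molecules) corresponds to
slow-growing budding-yeast-like cells and is used across the tests and the
acceptance report.

Burst-size kinds: the default `geometric1` (support `{1, 2, …}`) makes
every burst productive; `geometric0` (support `{0, 1, …}`) is available
because the model admits `B = 0`. The choice is exposed rather than guessed
— the two differ in `⟨B²⟩` (`m(2m−1)` vs `m(2m+1)`) and hence in the
bursty-noise term, and published parameter sets rarely say which
convention they use.

# Closed forms, β, and the noise decomposition

The steady-state mean follows from closing the moment hierarchy over the
stage indicators `c_i(t)`: because exactly one indicator is 1 at any time,
products of distinct indicators vanish and the moment ODEs close *exactly*
(no approximation). The package evaluates the resulting double sums

* mean: `⟨x⟩ = ⟨B⟩/Σ_j(1/λ_j) · (Σ_iΣ_j k_j/(λ_iλ_j) + Σ_iΣ_{j≤i} k_j/(λ_iλ_j))`
* regulation parameter: `β = Σ_iΣ_j(k_j/λ_iλ_j) / Σ_iΣ_{j≤i}(k_j/λ_iλ_j)`

in O(`n`) via cumulative sums — algebraically identical to the direct
O(`n²`) evaluation (which the test suite keeps as an independent
brute-force oracle) but usable at `n = 10⁵`, where β for constant
expression reaches its deterministic-cycle limit `2n/(n+1) → 2`.

The intrinsic noise `η = var(z)/⟨x⟩²` (with `z = x − y` the deviation from
the deterministic counterpart) decomposes as

`η·⟨x⟩ = (1/3 + 2/(3(1+β)))·⟨B²⟩/⟨B⟩  +  (2α/3)·β/(1+β)`

All reported noise quantities are squared-CV-like (variance over squared
mean); the package never returns a square-root CV, to avoid convention
drift. `noise_coefficients()` accepts `β = Inf` as an explicit convenience
path for the deterministic-cycle end-expression limit (coefficients 1/3 and
2α/3).

A useful intuition for the β trade-off is the synthesis budget
(`molecules_per_cycle()`): at a fixed mean, end-of-cycle expression must
make `⟨x⟩` molecules per cycle, constant expression `2⟨x⟩/3`, start-only
expression just `⟨x⟩/2`. More bursts per cycle mean better averaging of
burst noise — paid for in synthesis cost and in more molecules exposed to
partitioning.

# The moment solver as an independent oracle

`build_moment_system()` assembles the 3`n`-state linear ODE over
`(⟨c_i⟩, ⟨xc_i⟩, ⟨z²c_i⟩)` exactly as the per-stage balance equations
dictate; the steady state is a direct linear solve with one redundant
stage row replaced by the normalization `Σ⟨c_i⟩ = 1` — exact and
deterministic, no eigen-iteration. Two structural checks are built into the
test suite: the stage-block columns sum to zero (probability conservation),
and the per-stage `z²` rows telescope to the aggregate equation including
the `−(3/4)λ_n⟨z²c_n⟩` division term, which pins down the printed-index
ambiguities in the flow rows.

**The `n = 1` case.** The wrap-around division terms (`λ_n/2` into
`⟨xc_1⟩`; `λ_n/4` and `αλ_n/4` into `⟨z²c_1⟩`) formally reference the same
state they leave when `n = 1`, and the indicator-orthogonality closure does
not apply (`c_1c_n = c_1`). Deriving the single-stage equations from first
principles gives `d⟨x⟩/dt = k⟨B⟩ − λ⟨x⟩/2` and
`d⟨z²⟩/dt = k⟨B²⟩ + αλ⟨x⟩/4 − (3/4)λ⟨z²⟩` — and the generic assembly, with
the wrap-around terms landing on the diagonal, reproduces exactly these
coefficients. The package therefore uses one uniform code path for all
`n ≥ 1`; the tests verify `n = 1` against the β = 1 closed form
(`η·⟨x⟩ = (2/3)⟨B²⟩/⟨B⟩ + α/3`).

The transient integrator uses the matrix exponential on the dense 3`n`
system (`Matrix::expm`); it exists for convergence diagnostics, and its
fixed point is the steady-state solve. The `⟨zc_i⟩` cross-moments decay to
zero and are therefore not tracked; this leaves steady states exact while
transients of `⟨z²⟩` are diagnostic-grade only.

# Simulator design

* **Exact event timing.** Within a stage, the next event is chosen by
  exponential competition between burst arrival (`k_i`), stage exit
  (`λ_i`) and, if enabled, decay (`d·x`). No time discretization anywhere.
* **Deterministic counterpart.** `y(t)` grows at `⟨B⟩k_i` (with decay, it
  relaxes exponentially toward `⟨B⟩k_i/d`) along the *same* random stage
  trajectory and is exactly halved at division. Its birth value is started
  at the cycle-invariant fixed point `⟨B⟩Σ_i k_i/λ_i` (iterated numerically
  when decay is on), and `x₀ = round(y₀)`, which shortens burn-in; the
  default burn-in of 50 cycles is conservative on top of that.
* **Exact time averages.** Statistics integrate the piecewise-constant `x`
  and piecewise-linear (or exponential) `y` in closed form per segment —
  `x, x², y, y², xy` and hence `z²` — removing snapshot-discretization
  bias entirely. Standard errors are batch means over blocks of whole
  cycles (~30 blocks by default).
* **Partitioning samplers.** `α = 1` is binomial (exact). `α = 0` halving
  is impossible on odd integers; floor/ceil randomized rounding keeps the
  conditional mean exact and adds variance only 1/4 on odd counts (tests
  assert exactness on even counts). `0 < α < 1` mixes binomial (probability
  `α`) with deterministic halving; `α > 1` partitions integer clusters
  binomially, randomizing the cluster size between `⌊α⌋` and `⌈α⌉` so
  non-integer `α` holds in expectation. All samplers are Monte Carlo
  verified against mean `x/2`, variance `αx/4`.
* **Two-colour mode.** The shared cell-cycle skeleton (stage sojourns,
  division times) is drawn once; each reporter then gets independent
  Poisson burst counts, burst sizes and partition draws on that skeleton.
  Sharing across colours holds by construction within a single seeded RNG
  stream, and `⟨(x₁−x₂)²⟩/(2⟨x⟩²)` reproduces the `z`-based η.

# The extended promoter/mRNA model

`simulate_extended()` adds per-stage promoter ON/OFF switching, explicit
mRNA with decay, translation, optional protein decay, binomial partitioning
of both species (promoter state persists through division), and optional
lag-1 lognormal autoregressive memory in cycle durations. Its purpose is
qualitative: checking that orderings derived from the reduced burst model
survive mechanistic detail. Three deliberate approximations keep it honest
but simple:

* the deterministic counterpart uses the *stationary* promoter occupancy
  `k_on/(k_on+k_off)` within each stage (not the transient occupancy), and
  the corrected noise uses the variance of `z = protein − y_p` about its
  time-averaged mean, so small mean-field offsets do not leak into η;
* `z²` is integrated by trapezoid over event times (events are dense), not
  in closed form as in the main simulator;
* matched-mean comparisons are made through the product `η·⟨protein⟩`,
  which is the matched-mean statistic because η scales as 1/mean under
  transcription-rate scaling.

In the fast-mRNA-decay limit each transcription event behaves as an
instantaneous geometric protein burst with `⟨B⟩ = k_tl/γ_m`, and the test
suite confirms the extended model approaches the reduced model's η there
(10–30% tolerance, documented: the mRNA lifetime is short but not zero).
The cycle-memory mechanism (a lognormal AR(1) factor scaling each
generation's stage rates, default off) is this package's own construction —
the detailed published mechanism is not available in the main text the
package is built from — so no quantitative claims are attached to it.

# Strategy comparison and the duplication scan

All comparisons are made at a fixed mean via `calibrate_rate()` (the mean
is homogeneous of degree 1 in the profile, so one scale factor suffices;
tolerance ≤ 10⁻⁹ relative across rows). "Deterministic cell-cycle duration"
in the scan is approximated by a large equal-rate stage count (`n = 200` in
the tests; convergence is O(1/n)) rather than a special-cased fixed-time
simulator, because the closed forms stay exact at any `n`. Continuous
switch times `T1/T` are mapped to the nearest stage boundary
(`round(n·T1/T)`), with a warning when rounding moves the boundary.

One subtlety found while validating the scan: the claim "the grid minimum
of the bursty-synthesis noise sits at the largest fold `f` with the switch
nearest the cycle end" is asymptotic in `f`. In the deterministic-cycle
continuum, a step profile switching at `u = T1/T` has
`β(u, f) = (u + f(1−u)) / (u − u²/2 + f(1−u)²/2)`, and for the corner
`u → 1` to dominate one needs `f ≫ u/(1−u)²` (e.g. `f ≳ 400` for
`u = 0.95`); at moderate `f` the optimum switch time is interior
(`β` peaks around `u ≈ 0.85–0.9` for `f = 50`). The monotone decrease of
noise with `f` at fixed `T1` holds on any grid; the corner-minimum tests
use fold grids satisfying the condition above, and users scanning small
`f` ranges should expect an interior optimum.

# What the synthetic world does and does not establish

The generator *is* the stated model: memoryless stages, instantaneous
bursts, stable protein, mean-`x/2`/variance-`αx/4` partitioning, a single
lineage. Green tests establish internal consistency of three independent
computational routes (closed forms, moment ODEs, exact simulation) under
these assumptions, at the reference parameter set and under randomized
model draws. They do **not** establish: behaviour under cell-size-coupled
expression or concentration homeostasis, feedback of protein on its own
burst rate, population-snapshot statistics, correlated mother–daughter
cycle times (beyond the qualitative extended model), or non-instantaneous
bursts. Those are the documented non-goals.

# Numerical choices and degenerate inputs

* Double sums via cumulative sums, O(n); brute-force O(n²) kept as test
  oracle only.
* Steady states by direct dense linear solve (`solve`), with a diagnostic
  error including the reciprocal condition number if the system were
  singular (impossible for valid positive rates).
* β is mathematically ≥ 1; round-off can produce values a few ulp below 1
  (e.g. start-only profiles, where numerator and denominator are equal
  sums accumulated in different orders), so downstream coefficient
  evaluation tolerates `β ≥ 1 − 10⁻⁶` rather than clamping silently.
* All-zero regulation profiles are rejected by every operation that divides
  by the mean; the moment solver accepts them (mean 0, variance 0, η NaN).
* Seeds: every stochastic entry point takes an explicit integer seed;
  identical seed + config is bit-identical, including CLI artifacts
  (floats serialized at 12 significant digits).
* Config files are JSON (the schema in `?parse_config`); unknown keys are
  rejected so typos cannot silently fall back to defaults.

# Known limitations

* The O(n) analytics still allocate length-`n` vectors; `n = 10⁵` is fine,
  `n = 10⁸` is not — use the closed-form limits instead.
* `estimate_stats` standard errors assume approximately equal-duration
  blocks; with extremely heterogeneous stage rates, block durations vary
  and the SE is itself noisy (3-SE test gates are calibrated for ~30
  blocks).
* The extended model's corrected noise inherits the stationary-promoter
  mean-field approximation; for very slow promoters relative to stage
  dwell times its η is biased and only orderings should be trusted.
* Non-integer `α > 1` cluster partitioning matches `αx/4` in expectation
  over the cluster-size randomization, not per draw.
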