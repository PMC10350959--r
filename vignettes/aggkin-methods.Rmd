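---
title: "Finite-system aggregation-fragmentation kinetics with aggkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-system aggregation-fragmentation kinetics with aggkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkin)
```

## The model

aggkin models a well-mixed system that starts with `N` free monomers in a
volume `V`. Clusters aggregate pairwise and may fragment; only binary events
are considered. The state is the vector of cluster counts
`n = (n_1, ..., n_N)` with the exact conservation law `sum(i * n_i) = N`, so
the largest possible cluster is an `N`-mer.

Two symmetric kernels define a kinetic model:

* the aggregation kernel `K(i, j)`: `K(i, j) / V` is the probability per
  unit time that one given i-mer/j-mer pair coalesces (units volume/time);
* the fragmentation kernel `F(i, j)`: the probability per unit time that one
  given `(i + j)`-mer splits into an i-mer and a j-mer (units 1/time).

Reaction channels are unordered pairs `(i, j)` with `i <= j` and
`i + j <= N`; swapping indices is not a new process. The propensity of an
aggregation channel is `K(i,j) n_i (n_j - d_ij) / ((1 + d_ij) V)` (the number
of distinct pairs times the per-pair rate, `d_ij` the Kronecker delta), and
of a fragmentation channel `F(i,j) n_{i+j}`. These propensities drive the
chemical master equation for `P(n, t)`, which the package treats three ways:

1. **Exact stochastic simulation** (`simulate_trajectory()`,
   `simulate_ensemble()`): the direct Gillespie method. Per event two
   uniforms are drawn, the waiting time `tau = ln(1/u1) / a_tot` and the
   channel as the smallest index whose cumulative propensity reaches
   `u2 * a_tot`. Mass is conserved exactly in integer arithmetic; states
   with zero total propensity (e.g. a single `N`-mer under irreversible
   kinetics) freeze the trajectory.
2. **Exact master-equation solution for small `N`** (`master_solution()`):
   the state space is the set of integer partitions of `N` (627 states at
   `N = 20`), enumerated explicitly; the generator matrix is sparse, its
   columns sum to zero, and the linear system `dp/dt = G p` is integrated
   with a stiff solver and an analytic Jacobian. This is the ground truth
   that the stochastic and mean-field codepaths are tested against. The
   module refuses `N > 30`, where partition counts make enumeration
   pointless -- that regime belongs to the simulator.
3. **The finite-size (modified) Smoluchowski equations**
   (`integrate_modified()`): taking means of the master equation yields a
   moment hierarchy whose first level couples `<n_i>` to pair moments
   `<n_i (n_j - d_ij)>`. The mean-field closure
   `<n_i (n_j - d_ij)> ~ <n_i><n_j>` gives a closed set of `N` rate
   equations for the average concentrations `cbar_i = <n_i>/V`, identical in
   form to the classical Smoluchowski equations but truncated at the
   physical size `N`, with aggregation coefficients `k_ij = K_ij` and
   fragmentation coefficients `f_ij = (1 + d_ij) F_ij` (the stoichiometric
   factor accounts for splits into equal fragments).

The classical, infinite-system theory is recovered by truncating at a large
unphysical size (`integrate_unmodified()`), which doubles the truncation
until the monomer/dimer/trimer curves are stable to 1e-8 relative.

Two derived observables matter throughout: the number-average aggregate size
`L = sum(i c_i) / sum(c_i)` and the total cluster count
`n_cluster = V sum(c_i)`, related by `L * n_cluster = N`. The finite-size
equations keep `L <= N` at all times; the infinite-system constant-kernel
solution has `L(T) = 1 + T/2` in scaled time `T = k_f c t`, which overshoots
any finite `N` -- the defect the modified equations remove.

## Kernel families and conventions

Five families are built in (all symmetric, non-negative, cached as dense
matrices up to `N`):

| family | K(i, j) | F(i, j) | parameters |
|---|---|---|---|
| `constant` | `k_f` | 0 | `k_f` |
| `additive` | `k_f (i + j)/2` | 0 | `k_f` |
| `diffusion` | `(k_f/4)(i^(1/3)+j^(1/3))(i^(-1/3)+j^(-1/3))` | 0 | `k_f` |
| `blatz_tobolsky` | `k_f` | `k_b/(1 + d_ij)` | `k_f`, `k_b` |
| `three_param` | Blatz-Tobolsky with monomer channels `x q` | same | `k_f`, `k_b`, `q` |

Conventions worth spelling out:

* **Normalisation.** The additive and diffusion kernels are normalised so
  `K(1,1) = k_f` (diffusion: `K(i,i) = k_f` for every `i`), making `k_f`
  comparable across families: all families then share the same monomer-pair
  rate at `t = 0`.
* **Blatz-Tobolsky fragmentation.** The model is "size independent" at the
  level of the *rate coefficient*: every admissible split channel of every
  cluster has the same adsorbed coefficient `f_ij = (1 + d_ij) F_ij = k_b`,
  i.e. `F(i, i) = k_b/2` on the diagonal. With this convention (and only
  with it) the model has an exact closed-form solution: the cluster-size
  distribution stays geometric, `c_i = c (1-p)^2 p^(i-1)`, with the extent
  of reaction solving the Riccati equation
  `dp/dt = (k_f c/2)(1-p)^2 - (k_b/2) p`, solved in closed form through its
  two fixed points. At `k_b = 0` this collapses, parameters and all, onto
  the constant-kernel solution `c_i = c tau^(i-1)/(1+tau)^(i+1)`,
  `tau = k_f c t/2`. Had we instead made the *kernel* uniform
  (`F(i,j) = k_b` including the diagonal), the geometric ansatz fails on the
  equal-split channels and no closed form survives; the package therefore
  uses the coefficient-uniform convention consistently in the simulator, the
  master generator, the rate equations and the analytic solution.
* **Monomer boost.** In the three-parameter family every channel whose
  smaller index is 1 -- a monomer attaching to any cluster, or any cluster
  shedding a monomer -- is faster by the factor `q`, on both `K` and `F`.
  `q = 1` reduces bit-exactly to Blatz-Tobolsky, which reduces at
  `k_b = 0` to the constant kernel; the fitting module exploits this nesting
  (`fixed = c(q = 1)` etc.).

One channel table per model is the single source of truth: the simulator,
the master-equation generator and the ODE right-hand side all read the same
`(i, j)` list, kernel values and stoichiometry matrix, so the three
codepaths cannot drift apart in their counting conventions.

## Units and the dimensionless mode

Native units are arbitrary but consistent: `K` in volume/time (for molecular
simulation work, nm^3/ps), `F` and `k_b` in 1/time, concentrations in
1/volume. All tests and examples use the dimensionless mode
`k_f = c = 1` (so `V = N`), in which the natural abscissa is the scaled time
`T = k_f c t` and concentrations are reported as `c_i / c`. Plots and fits
over `T` in `[0, 5]` cover the kinetically interesting window: by `T = 5`
the constant-kernel monomer fraction has dropped below 10%.

## Numerical choices

* **ODE integration**: `deSolve::lsoda` with an analytic Jacobian assembled
  from the channel table; defaults `rtol = 1e-8`, `atol = 1e-12 * c`.
  Fragmentation constants can be large relative to aggregation, so a
  stiff-capable method is the default. Mass drift beyond `1e-8 c` or
  negative concentrations beyond `-atol` abort the run (they indicate a
  convention error, not something to clip silently); harmless sub-`atol`
  negatives are clipped to zero for reporting.
* **Master propagation**: `lsoda` at `rtol = 1e-10`, `atol = 1e-14`, with
  the dense generator as Jacobian up to 1500 states; normalization is
  asserted to 1e-10 and tiny negative probabilities (> -1e-12) clipped.
* **Closed forms** are evaluated in log space so `c_i(t)` is finite and
  non-negative out to arbitrary sizes; series sums (mass checks, `L`)
  truncate adaptively once the running term `i c_i` falls below
  `1e-15 c`, justified by the geometric-type tails of all three solutions.
* **RNG streams**: one master seed seeds `sample.int()` to draw one
  sub-seed per trajectory, so ensembles are reproducible and could be
  parallelised without changing results. The compiled and pure-R simulator
  engines consume the identical `u1, u2` sequence per event and produce
  bit-identical trajectories from the same seed -- this is tested, and it
  pins the compiled hot loop to the readable reference implementation.
* **Grid sampling** of trajectories is left-continuous piecewise-constant
  (a jump process holds its state until the next event).

## Fitting and model discrimination

`fit_model()` fits the modified-ODE predictions of the four standard
observables -- mean numbers of monomers, dimers, trimers and total clusters
-- to an averaged dataset by minimizing the weighted sum of squared
residuals; the reported figure of merit is the reduced chi-square
`chi2_nu = chi2 / (n - m)`, with `chi2_nu` near 1 indicating a good fit.
Choices a user should know about:

* `t = 0` points carry zero SEM (every repeat starts identically) and are
  excluded from the objective by default; any remaining zero SEM is floored
  at `1e-6` of the observable's maximum. Infinite weights are meaningless.
* The default weighting is the plain pooled chi-square. An alternative that
  gives each observable equal total weight regardless of its number of
  points is available (`weighting = "per_observable"`); with a common time
  grid for all four observables the two coincide up to a constant factor.
* Parameters are fitted in log space (positivity for free), from five
  deterministic starting points spread log-uniformly across the bounds, by
  a simplex (or Brent, for one parameter) stage and a Levenberg-Marquardt
  polish; the best final chi-square wins. There is no randomness in the
  optimizer, so fits are exactly reproducible.
* Uncertainties come from the Gauss-Newton covariance at the optimum scaled
  by `chi2/nu`, delta-transformed back from log space. They are curvature
  estimates, not bootstrap intervals.

`model_discrimination()` ranks families by `chi2_nu` (ties: fewer
parameters). `validate_fit()` closes the loop: it re-simulates the
stochastic model at the recovered parameters and checks the Monte Carlo
means against the modified-ODE prediction (does the closure hold?) and
against the fitted data (do the recovered parameters regenerate them?),
passing when each comparison stays within 3 SEM at 95% of grid points.
`cross_concentration_check()` fits datasets at different concentrations
separately and jointly; concentration-independent kernels are the model's
core assumption, so a joint fit that is much worse than the single fits is
evidence against the model class, not against the optimizer.

## What the synthetic data emulate -- and what they do not

`generate_observables()` stands in for averaged molecular-simulation data:
a handful of repeats (default 3) of the exact stochastic process, sampled
on a fixed grid, averaged, with SEM error bars. The noise is thus *exactly*
the finite-repeat averaging noise of simulation studies -- correlated along
the time axis within a repeat, shrinking as `1/sqrt(n_repeats)` -- and no
additive observation noise is injected. What is deliberately not emulated:
spatial structure, diffusion limitation, cluster morphology and internal
restructuring, or any concentration dependence of the kernels (available
only through the explicit `kf_fun` hook, to reproduce the failure mode
where single-concentration fits succeed but a joint fit across
concentrations degrades). A recovery test passing on these data shows the
inference machinery is sound for the stochastic model; it cannot show that
any particular molecular system obeys that model.

The package-default recovery study uses `N = 72` monomers, 1000 repeats,
101 points over `T` in `[0, 5]`, and the truth
`(k_f, k_b, q) = (1, 0.05, 4)`. The truth point was chosen at design time
from an identifiability analysis: with strong fragmentation the four
observables constrain mainly the monomer-channel products `q k_f` and
`q k_b`, leaving a sloppy direction along which even sub-percent systematic
error in the fitted curves translates into tens of percent in individual
parameters. Near-irreversible truth makes the late-time cluster count
sensitive to the bare cluster-cluster rate `k_f`, pinning all three
parameters; it is also the regime of interest in practice, where reversible
two-parameter fits collapse to `k_b = 0` yet a monomer-specific rate
enhancement is required by the data.

## Known limitations

* The mean-field closure has an `O(1/N)` bias: the modified-ODE curves
  deviate from the exact master means visibly at `N = 5` and by roughly a
  percent of `c` at `N = 20` (the deviation halves again by `N = 40`). With
  very tightly averaged ensembles (1000+ repeats) this bias is *resolvable*
  -- the ODE can sit several SEM away from the stochastic mean even though
  the curves look superimposed -- so "within a few SEM everywhere" is not a
  criterion the closure can meet at small `N` and high repeat counts.
  The acceptance suite keeps this comparison at its face-value threshold
  and lets it fail for the `N = 20` constant kernel; the failure is the
  honest measurement of the closure bias, and the same suite verifies the
  bias shrinks strictly with `N`.
* At late times in irreversible systems the mean-field equations stall:
  clusters larger than `N/2` cannot pair with each other, so the ODE
  end state retains a spread of large clusters and `L` saturates below `N`,
  whereas the true process always absorbs into a single `N`-mer. The bound
  `L <= N` still holds -- it is the long-time mean that is approximate.
* Exact master solutions are capped at `N = 30` (partition-count growth);
  gelation-prone kernels (e.g. multiplicative) and ternary events are out
  of scope; no spatial resolution.
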