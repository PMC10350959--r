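## Synthetic MD-like datasets ----------------------------------------------
##
## Emulates the structure of averaged molecular-simulation data: a small
## number of long trajectories is repeated, cluster counts are extracted on
## a fixed grid, and means with SEM error bars are computed across repeats.
## The observation noise comes solely from finite-repeat averaging of the
## exact stochastic process -- no additive noise is injected -- which is
## precisely the noise structure of averaged simulation repeats.

#' Specification of a synthetic averaged dataset
#'
#' @param family Kernel family of the true model.
#' @param params Named list of true parameters.
#' @param N Number of monomers.
#' @param V System volume.
#' @param n_repeats Number of repeats to average (>= 2 so SEMs are nonzero;
#'   typical simulation studies use 3-6).
#' @param times Sampling grid starting at 0.
#' @param seed Integer seed.
#' @param kf_fun Optional concentration-dependence hook: a function
#'   `c -> k_f` overriding `params$k_f` per dataset concentration. The
#'   default (NULL) keeps `k_f` concentration-independent, which is the
#'   stochastic model's own assumption.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(family, params, N, V, n_repeats = 3,
                           times = seq(0, 5, length.out = 101), seed,
                           kf_fun = NULL) {
  stopifnot(n_repeats >= 2, times[1L] == 0, N >= 2, V > 0)
  structure(list(family = family, params = params, N = as.integer(N), V = V,
                 n_repeats = as.integer(n_repeats), times = times,
                 seed = as.integer(seed), kf_fun = kf_fun),
            class = "synthetic_spec")
}

spec_kernel <- function(spec, N = spec$N, V = spec$V) {
  params <- spec$params
  if (!is.null(spec$kf_fun)) params$k_f <- spec$kf_fun(N / V)
  make_kernel(spec$family, params, N)
}

#' Generate an averaged synthetic dataset
#'
#' Runs `n_repeats` exact stochastic trajectories of the spec's model,
#' samples them on the grid and returns the monomer/dimer/trimer/cluster
#' means with SEM error bars. Bit-identical when regenerated with the same
#' seed.
#'
#' @param spec A `synthetic_spec`.
#' @return An `observable_set` in mean-count units.
#' @export
generate_observables <- function(spec) {
  model <- spec_kernel(spec)
  ens <- simulate_ensemble(model, V = spec$V, t_max = max(spec$times),
                           n_repeats = spec$n_repeats, grid = spec$times,
                           seed = spec$seed)
  ensemble_to_observables(ens)
}

#' Generate a matched pair of datasets at two concentrations
#'
#' Produces two datasets differing only in concentration (the second volume
#' is `V / c_ratio`, so its concentration is `c_ratio` times the first).
#' With the default concentration-independent `k_f` the pair is consistent
#' under joint fitting; a `kf_fun` hook such as `function(c) k0 * c`
#' reproduces the failure mode where single-concentration fits succeed but
#' the joint fit degrades.
#'
#' @param spec A `synthetic_spec` (defines the first dataset).
#' @param c_ratio Positive concentration ratio of the second dataset to the
#'   first.
#' @return List of two `observable_set`s.
#' @export
generate_two_concentration_suite <- function(spec, c_ratio) {
  stopifnot(c_ratio > 0)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  make_one <- function(V, seed) {
    s <- spec
    s$V <- V
    s$seed <- seed
    generate_observables(s)
  }
  list(make_one(spec$V, seeds[1L]), make_one(spec$V / c_ratio, seeds[2L]))
}
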