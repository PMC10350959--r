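test_that("propensities implement the pair-counting formulas", {
  m <- constant_kernel(1, 5)
  k <- 1
  a <- propensities(c(5, 0, 0, 0, 0), m, V = 1)
  ch <- attr(a, "channels")
  agg11 <- which(ch$ii == 1 & ch$jj == 1)
  expect_equal(a[[agg11]], k * 5 * 4 / 2)  # n(n-1)/2 pairs
  expect_equal(sum(a), 10 * k)

  a2 <- propensities(c(2, 1, 0, 0, 0), m, V = 1)
  agg12 <- which(ch$ii == 1 & ch$jj == 2)
  expect_equal(a2[[agg12]], 2 * k)         # n_i n_j pairs, i != j

  # single monomer: nothing can happen under an irreversible kernel
  expect_true(all(propensities(c(1, 0, 0, 0, 0), m, V = 1) == 0))

  # fragmentation: two 4-mers, channel (1,3) fires at 2 F(1,3)
  bt <- blatz_tobolsky_kernel(1, 0.6, 5)
  a3 <- propensities(c(0, 0, 0, 2, 0), bt, V = 1)
  chb <- attr(a3, "channels")
  frag13 <- chb$n_channels + which(chb$ii == 1 & chb$jj == 3)
  expect_equal(a3[[frag13]], 2 * kernel_F(bt, 1, 3))

  # volume scaling: bimolecular rates carry 1/V, fragmentation does not
  a4 <- propensities(c(0, 0, 0, 2, 0), bt, V = 10)
  expect_equal(a4[[frag13]], a3[[frag13]])
  expect_equal(propensities(c(5, 0, 0, 0, 0), m, 10)[[agg11]], k * 10 / 10)
})

test_that("waiting times follow the exponential closed form", {
  expect_equal(draw_waiting_time(2, exp(-2)), 1)
  expect_equal(draw_waiting_time(1, 0.5), log(2))
  expect_identical(draw_waiting_time(0, 0.5), Inf)
  set.seed(42)
  tau <- log(1 / runif(1e5)) / 4
  se <- sd(tau) / sqrt(length(tau))
  expect_lt(abs(mean(tau) - 0.25), 3 * se)
})

test_that("reaction selection picks the smallest qualifying channel", {
  expect_identical(select_reaction(c(1, 3), 0.2), 1L)
  expect_identical(select_reaction(c(1, 3), 0.5), 2L)
  expect_error(select_reaction(c(0, 0), 0.5), "absorbing")
  set.seed(7)
  picks <- vapply(runif(1e5), function(u) select_reaction(c(1, 3), u), integer(1))
  phat <- mean(picks == 1L)
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(phat - 0.25), 3 * se)
})

test_that("trajectories conserve mass exactly and are seed reproducible", {
  m <- three_param_kernel(1, 1, 2, 10)
  tr <- simulate_trajectory(m, V = 10, t_max = 5, seed = 99)
  mass <- tr$states %*% (1:10)
  expect_true(all(mass == 10))
  expect_true(all(tr$states >= 0))
  tr2 <- simulate_trajectory(m, V = 10, t_max = 5, seed = 99)
  expect_identical(tr$states, tr2$states)
  expect_identical(tr$times, tr2$times)
})

test_that("compiled and reference engines produce identical trajectories", {
  for (fam in c("constant", "blatz_tobolsky")) {
    m <- dimensionless_model(fam, 8)
    trC <- simulate_trajectory(m, V = 8, t_max = 4, seed = 123, engine = "C")
    trR <- simulate_trajectory(m, V = 8, t_max = 4, seed = 123, engine = "R")
    expect_identical(trC$states, trR$states)
    expect_equal(trC$times, trR$times)
    expect_identical(trC$absorbed, trR$absorbed)
  }
})

test_that("irreversible aggregation loses one cluster per event and absorbs", {
  m <- constant_kernel(1, 12)
  tr <- simulate_trajectory(m, V = 12, t_max = 1000, seed = 5)
  n_clusters <- rowSums(tr$states)
  expect_equal(diff(n_clusters), rep(-1, tr$n_events))
  expect_true(tr$absorbed)
  expect_equal(tr$states[nrow(tr$states), 12], 1L)  # single N-mer endpoint
})

test_that("the waiting time of the smallest system matches the closed form", {
  # N = 2, constant K = k, V = 1: single event at rate k 2 1/2 = k
  k <- 2
  m <- constant_kernel(k, 2)
  set.seed(11)
  seeds <- sample.int(1e8, 1e4)
  waits <- vapply(seeds, function(s) {
    tr <- simulate_trajectory(m, V = 1, t_max = 1e6, seed = s)
    tr$times[2]
  }, numeric(1))
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 1 / k), 3 * se)
})

test_that("ensemble averages have the documented structure", {
  m <- blatz_tobolsky_kernel(1, 1, 6)
  grid <- seq(0, 3, length.out = 13)
  tr <- simulate_trajectory(m, V = 6, t_max = 3, seed = 31)
  one <- ensemble_average(list(tr), grid)
  expect_true(all(one$sem == 0))
  expect_equal(one$n_repeats, 1)
  # mass of the mean is N/V at every grid point
  ens <- ensemble_average(lapply(1:20, function(s)
    simulate_trajectory(m, V = 6, t_max = 3, seed = s)), grid)
  expect_equal(as.vector(ens$mean %*% (1:6)), rep(1, 13), tolerance = 1e-12)
  expect_true(all(ens$sem >= 0))
  expect_error(ensemble_average(list(), grid), "empty")
})

test_that("simulate_ensemble matches ensemble_average over explicit trajectories", {
  m <- constant_kernel(1, 6)
  grid <- seq(0, 2, length.out = 9)
  ens <- simulate_ensemble(m, V = 6, t_max = 2, n_repeats = 50, grid = grid, seed = 17)
  set.seed(17)
  seeds <- sample.int(.Machine$integer.max - 1L, 50)
  trajs <- lapply(seeds, function(s) simulate_trajectory(m, V = 6, t_max = 2, seed = s))
  ref <- ensemble_average(trajs, grid)
  expect_equal(ens$mean, ref$mean)
  expect_equal(ens$sem, ref$sem)
  expect_equal(ens$clusters_mean, ref$clusters_mean)
})

test_that("reversible ensembles relax to the exact stationary distribution", {
  N <- 5
  m <- blatz_tobolsky_kernel(1, 1, N)
  space <- enumerate_states(N)
  G <- build_generator(space, m, V = N)
  p_inf <- stationary_of(G)
  mean_inf <- as.vector(p_inf %*% space$states)
  ens <- simulate_ensemble(m, V = N, t_max = 30, n_repeats = 4000,
                           grid = c(0, 25, 30), seed = 13)
  for (g in 2:3) {
    z <- abs(ens$mean[g, ] * N - mean_inf) / pmax(ens$sem[g, ] * N, 1e-12)
    expect_true(all(z < 4))
  }
})
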