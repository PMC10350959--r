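## Direct-method stochastic simulation ------------------------------------

#' Reaction propensities of a state
#'
#' Propensity (instantaneous rate) of every reaction channel given the
#' current cluster counts. For an aggregation channel `(i, j)` the rate is
#' `K(i,j) n_i (n_j - delta_ij) / ((1 + delta_ij) V)` (the number of distinct
#' pairs times the per-pair rate); for a fragmentation channel `(i, j)` it is
#' `F(i,j) n_{i+j}`. Impossible events get rate 0 by the counting formula.
#'
#' @param state Integer vector of cluster counts `n_1 ... n_N`.
#' @param model A `kernel_model` with `max_size == length(state)`.
#' @param V System volume.
#' @return Numeric vector of rates, aggregation channels first, then
#'   fragmentation channels, with attribute `"channels"` holding the channel
#'   table.
#' @export
propensities <- function(state, model, V) {
  ch <- model$channels
  N <- model$max_size
  stopifnot(length(state) == N, all(state >= 0))
  a_agg <- ch$Kv * state[ch$ii] * (state[ch$jj] - as.numeric(ch$diag)) /
    (ch$pair_div * V)
  a_frag <- ch$Fv * state[ch$kk]
  structure(c(a_agg, a_frag), channels = ch)
}

#' Waiting time of the direct method
#'
#' Exponential waiting time to the next reaction, `tau = ln(1/u1) / a_tot`.
#'
#' @param a_tot Total propensity (sum over all channels).
#' @param u1 Uniform(0,1) variate.
#' @return The time increment; `Inf` when `a_tot = 0` (absorbing state, the
#'   caller freezes the trajectory).
#' @export
draw_waiting_time <- function(a_tot, u1) {
  stopifnot(a_tot >= 0, u1 > 0, u1 < 1)
  if (a_tot == 0) return(Inf)
  log(1 / u1) / a_tot
}

#' Channel selection of the direct method
#'
#' Returns the smallest channel index `j` whose cumulative rate sum reaches
#' `u2 * sum(rates)`.
#'
#' @param rates Channel propensity vector.
#' @param u2 Uniform(0,1) variate.
#' @return Integer channel index.
#' @export
select_reaction <- function(rates, u2) {
  a_tot <- sum(rates)
  if (a_tot <= 0) stop("all rates are zero: absorbing state", call. = FALSE)
  which(cumsum(rates) >= u2 * a_tot)[1L]
}

monodisperse_state <- function(N) c(N, integer(N - 1L))

apply_channel <- function(state, ch, index, kind = c("aggregation", "fragmentation")) {
  kind <- match.arg(kind)
  i <- ch$ii[index]; j <- ch$jj[index]; k <- ch$kk[index]
  d <- if (kind == "aggregation") 1L else -1L
  state[i] <- state[i] - d
  state[j] <- state[j] - d
  state[k] <- state[k] + d
  state
}

#' Simulate one stochastic aggregation-fragmentation trajectory
#'
#' Exact (direct-method) simulation of the master equation starting from the
#' monodisperse state `n_i = N delta_{1,i}`. The `"C"` engine and the pure-R
#' reference engine draw identical variate sequences, so both produce the
#' same event sequence from the same seed.
#'
#' @param model A `kernel_model`.
#' @param N Number of monomers (defaults to `model$max_size`).
#' @param V System volume.
#' @param t_max Simulated time span.
#' @param seed Integer seed (mandatory: stochastic runs are reproducible).
#' @param engine `"C"` (compiled) or `"R"` (reference implementation).
#' @return An `ssa_trajectory`: event times (starting at 0), the state after
#'   each event as a matrix, the frozen/absorbing flag and event count.
#' @export
simulate_trajectory <- function(model, N = model$max_size, V, t_max, seed,
                                engine = c("C", "R")) {
  engine <- match.arg(engine)
  stopifnot(N == model$max_size, N >= 2, V > 0, t_max > 0)
  ch <- model$channels
  set.seed(as.integer(seed))
  if (engine == "C") {
    res <- ssa_run(ch$ii, ch$jj, ch$kk, ch$Kv, ch$Fv, N, V, t_max,
                   numeric(0), monodisperse_state(N), TRUE, 5e7)
    times <- c(0, res$event_times)
    states <- matrix(0L, nrow = length(times), ncol = N)
    states[1L, ] <- monodisperse_state(N)
    st <- monodisperse_state(N)
    chan <- res$event_channel
    for (e in seq_along(chan)) {
      idx <- abs(chan[e])
      st <- apply_channel(st, ch, idx,
                          if (chan[e] > 0) "aggregation" else "fragmentation")
      states[e + 1L, ] <- st
    }
    absorbed <- res$absorbed
    t_end <- res$t_end
  } else {
    times <- 0
    st <- monodisperse_state(N)
    states_list <- list(st)
    t <- 0
    absorbed <- FALSE
    repeat {
      a <- propensities(st, model, V)
      a_tot <- sum(a)
      if (a_tot <= 0) { absorbed <- TRUE; break }
      tau <- draw_waiting_time(a_tot, stats::runif(1))
      if (t + tau > t_max) { t <- t_max; break }
      sel <- select_reaction(a, stats::runif(1))
      nch <- ch$n_channels
      kind <- if (sel <= nch) "aggregation" else "fragmentation"
      st <- apply_channel(st, ch, (sel - 1L) %% nch + 1L, kind)
      t <- t + tau
      times <- c(times, t)
      states_list[[length(states_list) + 1L]] <- st
    }
    states <- do.call(rbind, states_list)
    t_end <- t
  }
  structure(list(times = times, states = states, N = N, V = V,
                 t_max = t_max, t_end = t_end, absorbed = absorbed,
                 n_events = nrow(states) - 1L, seed = seed,
                 model = model$name),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory: %s>  N = %d, V = %g, %d events, t in [0, %g]%s\n",
              x$model, x$N, x$V, x$n_events, x$t_max,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

sample_trajectory <- function(traj, grid) {
  idx <- findInterval(grid, traj$times)
  idx[idx < 1L] <- 1L
  traj$states[idx, , drop = FALSE]
}

#' Average an ensemble of trajectories onto a time grid
#'
#' Each trajectory is sampled by left-continuous piecewise-constant
#' interpolation (the state holds until the next event), then the per-size
#' mean concentration and its standard error are computed across
#' trajectories.
#'
#' @param trajectories List of `ssa_trajectory` objects sharing `N` and `V`.
#' @param grid Ordered time grid.
#' @return A `trajectory_ensemble` with matrices `mean` and `sem`
#'   (grid x size, concentration units) plus `clusters_mean`/`clusters_sem`
#'   for the total cluster count.
#' @export
ensemble_average <- function(trajectories, grid) {
  if (length(trajectories) == 0L) stop("empty trajectory list", call. = FALSE)
  N <- trajectories[[1L]]$N
  V <- trajectories[[1L]]$V
  for (tr in trajectories) {
    if (tr$N != N || tr$V != V) stop("trajectories disagree on (N, V)", call. = FALSE)
  }
  R <- length(trajectories)
  G <- length(grid)
  s1 <- matrix(0, G, N); s2 <- matrix(0, G, N)
  c1 <- numeric(G); c2 <- numeric(G)
  for (tr in trajectories) {
    cnt <- sample_trajectory(tr, grid)
    s1 <- s1 + cnt
    s2 <- s2 + cnt^2
    tot <- rowSums(cnt)
    c1 <- c1 + tot
    c2 <- c2 + tot^2
  }
  build_ensemble(grid, s1, s2, c1, c2, R, N, V, seed = NA_integer_)
}

build_ensemble <- function(grid, s1, s2, c1, c2, R, N, V, seed) {
  mean_cnt <- s1 / R
  sem_cnt <- if (R > 1) {
    var_cnt <- pmax(s2 - R * mean_cnt^2, 0) / (R - 1)
    sqrt(var_cnt / R)
  } else matrix(0, nrow(s1), ncol(s1))
  cl_mean <- c1 / R
  cl_sem <- if (R > 1) sqrt(pmax(c2 - R * cl_mean^2, 0) / (R - 1) / R) else 0 * c1
  structure(list(times = grid, mean = mean_cnt / V, sem = sem_cnt / V,
                 clusters_mean = cl_mean, clusters_sem = cl_sem,
                 n_repeats = R, N = N, V = V, seed = seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble>  N = %d, V = %g, %d repeats, %d grid points in [%g, %g]\n",
              x$N, x$V, x$n_repeats, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate and average a stochastic ensemble
#'
#' Runs `n_repeats` independent direct-method trajectories and averages them
#' onto `grid`. One master seed spawns the per-trajectory streams: the
#' trajectory seeds are `sample.int(.Machine$integer.max - 1, n_repeats)`
#' drawn after `set.seed(seed)`, so ensembles are reproducible and
#' embarrassingly parallel.
#'
#' @inheritParams simulate_trajectory
#' @param n_repeats Number of trajectories.
#' @param grid Ordered time grid within `[0, t_max]`.
#' @return A `trajectory_ensemble`.
#' @export
simulate_ensemble <- function(model, N = model$max_size, V, t_max = max(grid),
                              n_repeats, grid, seed) {
  stopifnot(N == model$max_size, n_repeats >= 1, !is.unsorted(grid),
            max(grid) <= t_max)
  ch <- model$channels
  set.seed(as.integer(seed))
  traj_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  G <- length(grid)
  s1 <- matrix(0, G, N); s2 <- matrix(0, G, N)
  c1 <- numeric(G); c2 <- numeric(G)
  n0 <- monodisperse_state(N)
  for (r in seq_len(n_repeats)) {
    set.seed(traj_seeds[r])
    res <- ssa_run(ch$ii, ch$jj, ch$kk, ch$Kv, ch$Fv, N, V, t_max,
                   grid, n0, FALSE, 5e7)
    cnt <- res$counts
    s1 <- s1 + cnt
    s2 <- s2 + cnt^2
    tot <- rowSums(cnt)
    c1 <- c1 + tot
    c2 <- c2 + tot^2
  }
  build_ensemble(grid, s1, s2, c1, c2, n_repeats, N, V, seed)
}
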