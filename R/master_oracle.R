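## Exact master-equation solution by state-space enumeration ----------------

partition_count <- function(N) {
  ## Euler recurrence with generalized pentagonal numbers
  p <- numeric(N + 1L)
  p[1L] <- 1
  for (n in seq_len(N)) {
    k <- 1L; s <- 0
    repeat {
      g1 <- k * (3L * k - 1L) %/% 2L
      g2 <- k * (3L * k + 1L) %/% 2L
      if (g1 > n && g2 > n) break
      sgn <- if (k %% 2L == 1L) 1 else -1
      if (g1 <= n) s <- s + sgn * p[n - g1 + 1L]
      if (g2 <= n) s <- s + sgn * p[n - g2 + 1L]
      k <- k + 1L
    }
    p[n + 1L] <- s
  }
  p[N + 1L]
}

state_key <- function(n) paste(n, collapse = ",")

#' Enumerate all cluster-count states of fixed total mass
#'
#' Lists every integer vector `n = (n_1, ..., n_N)` with
#' `sum(i * n_i) = N` -- one state per integer partition of `N`.
#'
#' @param N Total monomer count, `1 <= N <= 30` (the state count is the
#'   partition number p(N), which explodes beyond that).
#' @return A `state_space`: integer matrix `states` (one row per state) and a
#'   key-to-row index.
#' @export
enumerate_states <- function(N) {
  stopifnot(N >= 1, N == round(N))
  if (N > 30) {
    stop(sprintf("N = %d is too large for exact enumeration: p(%d) = %s states",
                 N, N, format(partition_count(N), big.mark = ",")), call. = FALSE)
  }
  N <- as.integer(N)
  parts <- function(n, maxp) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (k in seq.int(min(n, maxp), 1L)) {
      for (rest in parts(n - k, k)) out[[length(out) + 1L]] <- c(k, rest)
    }
    out
  }
  plist <- parts(N, N)
  states <- t(vapply(plist, function(p) tabulate(p, nbins = N), integer(N)))
  keys <- apply(states, 1L, state_key)
  index <- seq_len(nrow(states))
  names(index) <- keys
  structure(list(states = states, index = index, N = N), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space>  N = %d, %d states (integer partitions)\n",
              x$N, nrow(x$states)))
  invisible(x)
}

#' Build the master-equation generator matrix
#'
#' Sparse rate matrix `G` such that the state probability vector evolves as
#' `dp/dt = G p`. Off-diagonal entries are the channel propensities taking
#' one enumerated state to another; diagonal entries make every column sum
#' to zero (probability conservation).
#'
#' @param space A `state_space` from [enumerate_states()].
#' @param model A `kernel_model` with `max_size == space$N`.
#' @param V System volume.
#' @return A sparse `dgCMatrix` generator.
#' @export
build_generator <- function(space, model, V) {
  stopifnot(model$max_size == space$N)
  ch <- model$channels
  n_states <- nrow(space$states)
  from <- to <- integer(0)
  rate <- numeric(0)
  for (s in seq_len(n_states)) {
    n <- space$states[s, ]
    a <- propensities(n, model, V)
    nz <- which(a > 0)
    if (!length(nz)) next
    nch <- ch$n_channels
    tgt <- vapply(nz, function(ci) {
      idx <- (ci - 1L) %% nch + 1L
      kind <- if (ci <= nch) "aggregation" else "fragmentation"
      m <- apply_channel(n, ch, idx, kind)
      space$index[[state_key(m)]]
    }, integer(1))
    from <- c(from, rep.int(s, length(nz)))
    to <- c(to, tgt)
    rate <- c(rate, a[nz])
  }
  G <- Matrix::sparseMatrix(i = to, j = from, x = rate,
                            dims = c(n_states, n_states))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::colSums(G)
  G
}

#' Propagate the master equation
#'
#' Integrates the linear system `dp/dt = G p` on a time grid with a
#' stiff-capable solver (analytic dense Jacobian for moderate state counts).
#'
#' @param generator Sparse generator from [build_generator()].
#' @param p0 Initial probability vector (default: all mass on the last
#'   enumerated state, which in the canonical ordering is the all-monomer
#'   state -- the monodisperse initial condition).
#' @param times Output time grid (must start at 0).
#' @return A `master_distribution`: `times` and matrix `p` (time x state).
#' @export
solve_master <- function(generator, p0 = NULL, times) {
  n_states <- nrow(generator)
  if (is.null(p0)) {
    p0 <- numeric(n_states)
    p0[n_states] <- 1
  }
  stopifnot(length(p0) == n_states, abs(sum(p0) - 1) < 1e-10, all(p0 >= 0))
  if (times[1L] != 0) stop("time grid must start at 0", call. = FALSE)
  rhs <- function(t, p, parms) list(as.vector(generator %*% p))
  if (n_states <= 1500) {
    Gd <- as.matrix(generator)
    out <- deSolve::lsoda(y = p0, times = times, func = rhs, parms = NULL,
                          jacfunc = function(t, p, parms) Gd,
                          jactype = "fullusr", rtol = 1e-10, atol = 1e-14)
  } else {
    out <- deSolve::lsoda(y = p0, times = times, func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-14)
  }
  if (attr(out, "istate")[1L] < 0) {
    stop("master-equation integration failed (rtol = 1e-10, atol = 1e-14); ",
         "try a shorter time span or coarser grid", call. = FALSE)
  }
  p <- unname(out[, -1L, drop = FALSE])
  norms <- rowSums(p)
  if (any(abs(norms - 1) > 1e-8)) {
    stop("probability normalization drifted beyond 1e-8", call. = FALSE)
  }
  p[p < 0 & p > -1e-12] <- 0
  structure(list(times = times, p = p), class = "master_distribution")
}

#' Exact mean cluster counts from a master distribution
#'
#' `<n_i>(t) = sum_n n_i P(n, t)` over the enumerated states.
#'
#' @param dist A `master_distribution`.
#' @param space The matching `state_space`.
#' @return Matrix (time x size) of exact mean counts.
#' @export
mean_counts <- function(dist, space) {
  dist$p %*% space$states
}

#' Exact ensemble-mean kinetics for small systems
#'
#' Convenience wrapper: enumerates the state space, builds the generator,
#' propagates the monodisperse initial condition and returns the exact mean
#' counts and concentrations.
#'
#' @param model A `kernel_model`.
#' @param V System volume.
#' @param times Output time grid starting at 0.
#' @return A `master_solution` with `counts` (time x size mean counts),
#'   `conc = counts / V`, the `state_space` and the full distribution.
#' @export
master_solution <- function(model, V, times) {
  N <- model$max_size
  space <- enumerate_states(N)
  ## put all initial mass on the all-monomer state
  mono <- space$index[[state_key(monodisperse_state(N))]]
  G <- build_generator(space, model, V)
  p0 <- numeric(nrow(space$states))
  p0[mono] <- 1
  dist <- solve_master(G, p0, times)
  counts <- mean_counts(dist, space)
  structure(list(times = times, counts = counts, conc = counts / V,
                 N = N, V = V, space = space, distribution = dist,
                 model = model$name),
            class = "master_solution")
}

#' @export
print.master_solution <- function(x, ...) {
  cat(sprintf("<master_solution: %s>  N = %d, V = %g, %d states, %d times\n",
              x$model, x$N, x$V, nrow(x$space$states), length(x$times)))
  invisible(x)
}
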