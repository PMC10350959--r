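# Dimensionless study conditions: k_f = 1, c = 1 (so V = N), scaled time
# T = k_f c t = t. Used throughout the suite.
dimensionless_model <- function(family, N, k_b = 1, q = 2) {
  params <- switch(family,
    constant = list(k_f = 1),
    additive = list(k_f = 1),
    diffusion = list(k_f = 1),
    blatz_tobolsky = list(k_f = 1, k_b = k_b),
    three_param = list(k_f = 1, k_b = k_b, q = q))
  make_kernel(family, params, N)
}

# brute-force partition counter, independent of the package's recurrence
count_partitions_brute <- function(n, maxp = n) {
  if (n == 0) return(1L)
  total <- 0L
  for (k in seq_len(min(n, maxp))) {
    total <- total + count_partitions_brute(n - k, k)
  }
  total
}

# stationary distribution of a generator (null space via eigen)
stationary_of <- function(G) {
  ev <- eigen(as.matrix(G))
  i <- which.min(abs(ev$values))
  p <- Re(ev$vectors[, i])
  p / sum(p)
}
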