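test_that("all kernel builders produce symmetric, non-negative kernels", {
  for (N in c(2, 7, 30)) {
    models <- list(
      constant_kernel(1.3, N),
      additive_kernel(0.7, N),
      diffusion_kernel(2.1, N),
      blatz_tobolsky_kernel(1, 0.4, N),
      three_param_kernel(1, 0.4, 3.5, N))
    for (m in models) {
      expect_equal(m$Kmat, t(m$Kmat))
      expect_equal(m$Fmat, t(m$Fmat))
      expect_true(all(m$Kmat >= 0))
      expect_true(all(m$Fmat >= 0))
    }
  }
})

test_that("constant kernel is constant and irreversible", {
  m <- constant_kernel(1, 5)
  expect_identical(kernel_K(m, 2, 3), 1)
  expect_identical(kernel_F(m, 1, 1), 0)
  expect_identical(kernel_K(m, 1, 2), kernel_K(m, 2, 1))
  # a fitted value on the physical nm^3/ps scale works unchanged
  m2 <- constant_kernel(2.73, 20)
  expect_identical(kernel_K(m2, 1, 1), 2.73)
})

test_that("additive kernel has the (i + j) size dependence", {
  m <- additive_kernel(1, 8)
  expect_equal(kernel_K(m, 1, 1) / kernel_K(m, 1, 3), 0.5)
  expect_equal(kernel_K(m, 2, 3), kernel_K(m, 3, 2))
  # normalization: K(1,1) equals the constant kernel with the same k_f,
  # so the monomer-only initial aggregation rates coincide
  expect_equal(kernel_K(m, 1, 1), kernel_K(constant_kernel(1, 8), 1, 1))
})

test_that("diffusion kernel diagonal is size independent", {
  m <- diffusion_kernel(3, 12)
  diag_vals <- vapply(1:12, function(i) kernel_K(m, i, i), numeric(1))
  expect_equal(diag_vals, rep(3, 12))
  expect_equal(kernel_K(m, 1, 2), kernel_K(m, 2, 1))
  # off-diagonal entries exceed the diagonal (Brownian form)
  expect_gt(kernel_K(m, 1, 8), 3)
})

test_that("Blatz-Tobolsky model degenerates to the constant kernel at k_b = 0", {
  bt <- blatz_tobolsky_kernel(1.7, 0, 10)
  cst <- constant_kernel(1.7, 10)
  expect_identical(bt$Kmat, cst$Kmat)
  expect_identical(bt$Fmat, cst$Fmat)
  bt2 <- blatz_tobolsky_kernel(1, 1, 6)
  expect_identical(kernel_F(bt2, 1, 3), kernel_F(bt2, 3, 1))
  # uniform fragmentation rate coefficient: f = (1 + delta) F = k_b everywhere
  rc <- kernels_to_rate_coefficients(bt2)
  expect_equal(unique(as.vector(rc$f)), 1)
})

test_that("three-parameter model boosts exactly the monomer channels by q", {
  q <- 4.2
  m <- three_param_kernel(1, 0.5, q, 8)
  bt <- blatz_tobolsky_kernel(1, 0.5, 8)
  expect_equal(kernel_K(m, 1, 5) / kernel_K(m, 2, 4), q)
  expect_equal(kernel_F(m, 1, 2) / kernel_F(bt, 1, 2), q)
  # q = 1 reduces exactly
  m1 <- three_param_kernel(1, 0.5, 1, 8)
  expect_identical(m1$Kmat, bt$Kmat)
  expect_identical(m1$Fmat, bt$Fmat)
  # non-monomer channels untouched
  expect_equal(kernel_K(m, 2, 4), kernel_K(bt, 2, 4))
  expect_equal(kernel_F(m, 2, 3), kernel_F(bt, 2, 3))
})

test_that("invalid parameters are rejected", {
  expect_error(constant_kernel(0, 5), "k_f")
  expect_error(constant_kernel(-1, 5), "k_f")
  expect_error(constant_kernel(1, 1), "N")
  expect_error(blatz_tobolsky_kernel(1, -0.1, 5), "k_b")
  expect_error(three_param_kernel(1, 0.1, 0, 5), "q")
})

test_that("rate coefficients carry the stoichiometric factor on the diagonal", {
  m <- blatz_tobolsky_kernel(2, 3, 6)
  rc <- kernels_to_rate_coefficients(m)
  expect_equal(rc$k, m$Kmat)
  # off-diagonal: f equals F; diagonal: f = 2 F
  expect_equal(rc$f[1, 2], m$Fmat[1, 2])
  expect_equal(rc$f[2, 2], 2 * m$Fmat[2, 2])
  expect_identical(rc$f, rc$f_prime)
  expect_equal(rc$f, t(rc$f))
})

test_that("rate coefficients reproduce the master-equation propensities on all states", {
  for (N in c(4, 6)) {
    m <- three_param_kernel(1.2, 0.7, 2.5, N)
    rc <- kernels_to_rate_coefficients(m)
    V <- 2.5
    ch <- m$channels
    space <- enumerate_states(N)
    for (s in seq_len(nrow(space$states))) {
      n <- space$states[s, ]
      a <- propensities(n, m, V)
      # event rates reconstructed from the deterministic coefficients:
      # aggregation k_ij n_i (n_j - delta) / ((1 + delta) V),
      # fragmentation (f_ij / (1 + delta)) n_{i+j}
      delta <- as.numeric(ch$diag)
      a_agg <- rc$k[cbind(ch$ii, ch$jj)] * n[ch$ii] * (n[ch$jj] - delta) /
        ((1 + delta) * V)
      a_frag <- rc$f[cbind(ch$ii, ch$jj)] / (1 + delta) * n[ch$kk]
      expect_equal(unname(as.vector(a)), c(a_agg, a_frag))
    }
  }
})
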