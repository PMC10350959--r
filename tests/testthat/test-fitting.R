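make_obs <- function(df, N, V) observable_set(df, N = N, V = V)

test_that("chi-square arithmetic is exact", {
  df <- data.frame(time = 1:5, observable = "monomers",
                   mean = c(10, 9, 8, 7, 6), sem = rep(1, 5))
  pred <- df[c("time", "observable", "mean")]
  expect_equal(chi_square(df, pred, 1)$chi2, 0)
  pred$mean <- pred$mean + 1   # every point off by exactly 1 SEM
  cs <- chi_square(df, pred, 1)
  expect_equal(cs$chi2, 5)
  expect_equal(cs$nu, 4)
  expect_equal(cs$chi2_reduced, 1.25)
  expect_error(chi_square(df, pred, 5), "degrees of freedom")
})

test_that("a noiseless self-fit recovers the parameter to high precision", {
  times <- seq(0, 5, length.out = 26)
  pred <- predict_observables("constant", list(k_f = 0.8), 10, 10, times)
  pred$sem <- 0.01 * pmax(abs(pred$mean), 1e-6)
  fit <- fit_model(make_obs(pred, 10, 10), "constant")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["k_f"]]), 0.8, tolerance = 1e-4)
  expect_lt(fit$chi2, 1e-6)
})

test_that("nested models reduce exactly to their special cases", {
  set.seed(2)
  spec <- synthetic_spec("three_param", list(k_f = 1, k_b = 0.3, q = 2),
                         N = 16, V = 16, n_repeats = 100,
                         times = seq(0, 4, length.out = 21), seed = 8)
  obs <- generate_observables(spec)
  f_bt <- fit_model(obs, "blatz_tobolsky")
  f_3q1 <- fit_model(obs, "three_param", fixed = c(q = 1))
  expect_equal(f_3q1$params, f_bt$params, tolerance = 1e-10)
  expect_equal(f_3q1$chi2, f_bt$chi2, tolerance = 1e-10)

  f_cst <- fit_model(obs, "constant")
  f_btk0 <- fit_model(obs, "blatz_tobolsky", fixed = c(k_b = 0))
  expect_equal(unname(f_btk0$params[["k_f"]]), unname(f_cst$params[["k_f"]]),
               tolerance = 1e-10)
  expect_equal(f_btk0$chi2, f_cst$chi2, tolerance = 1e-10)
})

test_that("a well-specified model fitted to averaged stochastic data is calibrated", {
  # 200 repeats at N = 20: the SEM dominates the O(1/N) closure bias, the
  # regime where the reduced chi-square is interpretable
  spec <- synthetic_spec("constant", list(k_f = 1), N = 20, V = 20,
                         n_repeats = 200, times = seq(0, 5, length.out = 51),
                         seed = 11)
  obs <- generate_observables(spec)
  fit <- fit_model(obs, "constant")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["k_f"]]), 1, tolerance = 0.05)
  expect_gt(fit$chi2_reduced, 0.5)
  expect_lt(fit$chi2_reduced, 2)
})

test_that("model discrimination ranks and breaks ties by parameter count", {
  spec <- synthetic_spec("constant", list(k_f = 1), N = 16, V = 16,
                         n_repeats = 300, times = seq(0, 4, length.out = 26),
                         seed = 23)
  obs <- generate_observables(spec)
  disc <- model_discrimination(obs, c("constant", "diffusion", "blatz_tobolsky"))
  expect_equal(nrow(disc$table), 3)
  expect_true(!is.unsorted(disc$table$chi2_reduced))
  # reversible fit collapses towards k_b = 0 on irreversible data and
  # reproduces the constant-kernel fit quality
  f_bt <- disc$fits$blatz_tobolsky
  f_c <- disc$fits$constant
  expect_lt(f_bt$params[["k_b"]], 0.01 * f_bt$params[["k_f"]] * 1)
  # the vestigial k_b can absorb a sliver of the closure bias, so the fits
  # agree in quality rather than to optimizer precision
  expect_lt(abs(f_bt$chi2 - f_c$chi2) / f_c$chi2, 0.05)
  expect_lt(abs(f_bt$params[["k_f"]] - f_c$params[["k_f"]]) / f_c$params[["k_f"]],
            0.02)
  # single family gives a single-row table
  one <- model_discrimination(obs, "constant")
  expect_equal(nrow(one$table), 1)
})

test_that("constant and diffusion kernels are hardly distinguishable on few-repeat data", {
  # the data structure of averaged simulation studies: 3 repeats, broad SEMs
  spec <- synthetic_spec("constant", list(k_f = 1), N = 72, V = 72,
                         n_repeats = 3, times = seq(0, 5, length.out = 101),
                         seed = 23)
  obs <- generate_observables(spec)
  fc <- fit_model(obs, "constant", sem_floor_frac = 0.01)
  fd <- fit_model(obs, "diffusion", sem_floor_frac = 0.01)
  expect_lt(abs(fd$chi2_reduced - fc$chi2_reduced) / fc$chi2_reduced, 0.1)
  expect_lt(abs(fd$params[["k_f"]] - fc$params[["k_f"]]) / fc$params[["k_f"]], 0.05)
})

test_that("validation flags corrupted parameters through the data comparison", {
  spec <- synthetic_spec("constant", list(k_f = 1), N = 20, V = 20,
                         n_repeats = 300, times = seq(0, 4, length.out = 21),
                         seed = 31)
  obs <- generate_observables(spec)
  fit <- fit_model(obs, "constant")
  bad <- fit
  bad$params["k_f"] <- 2 * fit$params[["k_f"]]
  v_bad <- validate_fit(bad, data = obs, n_repeats = 300, seed = 7)
  expect_false(v_bad$pass)
  expect_lt(v_bad$frac_within_by_comparison[["mc_vs_data"]], 0.95)
  # reproducible given seed
  v_bad2 <- validate_fit(bad, data = obs, n_repeats = 300, seed = 7)
  expect_identical(v_bad$z, v_bad2$z)
})

test_that("per-observable weighting changes the objective but not feasibility", {
  spec <- synthetic_spec("constant", list(k_f = 1), N = 12, V = 12,
                         n_repeats = 100, times = seq(0, 3, length.out = 16),
                         seed = 41)
  obs <- generate_observables(spec)
  f1 <- fit_model(obs, "constant", weighting = "pooled")
  f2 <- fit_model(obs, "constant", weighting = "per_observable")
  expect_true(f1$converged && f2$converged)
  expect_equal(unname(f1$params[["k_f"]]), unname(f2$params[["k_f"]]),
               tolerance = 0.1)
})

test_that("cross-concentration consistency separates the two generating models", {
  spec <- synthetic_spec("constant", list(k_f = 1), N = 20, V = 20,
                         n_repeats = 300, times = seq(0, 5, length.out = 41),
                         seed = 21)
  pair <- generate_two_concentration_suite(spec, c_ratio = 2)
  rep_null <- cross_concentration_check(pair)
  expect_true(rep_null$consistent)
  expect_lt(rep_null$spread[["k_f"]], 0.1)

  spec_dep <- spec
  spec_dep$kf_fun <- function(c) 1 * c    # concentration-dependent kernel
  pair_dep <- generate_two_concentration_suite(spec_dep, c_ratio = 2)
  rep_dep <- cross_concentration_check(pair_dep)
  expect_false(rep_dep$consistent)
  expect_gt(rep_dep$joint$chi2_reduced,
            2 * max(rep_dep$single_chi2_reduced))
  # single-concentration fits remain good in the failure mode
  expect_lt(max(rep_dep$single_chi2_reduced), 3)

  expect_error(cross_concentration_check(pair[1]), "at least 2")
})

test_that("identical datasets are perfectly consistent", {
  spec <- synthetic_spec("constant", list(k_f = 1), N = 12, V = 12,
                         n_repeats = 100, times = seq(0, 3, length.out = 16),
                         seed = 61)
  obs <- generate_observables(spec)
  rep2 <- cross_concentration_check(list(obs, obs))
  expect_equal(rep2$spread[["k_f"]], 0)
  expect_true(rep2$consistent)
})
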