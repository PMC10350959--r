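## Weighted least-squares fitting and model discrimination ------------------

OBSERVABLE_NAMES <- c("monomers", "dimers", "trimers", "clusters")

#' Construct an observable set
#'
#' A tidy container for averaged cluster-size time series: per time point,
#' the mean numbers of monomers, dimers and trimers and the total cluster
#' count, with standard errors of the mean.
#'
#' @param data Data frame with columns `time`, `observable` (from
#'   `monomers`, `dimers`, `trimers`, `clusters`), `mean`, `sem`.
#' @param N,V System size and volume the series refers to.
#' @param n_repeats,seed Optional provenance.
#' @return An `observable_set` (a data frame with attributes).
#' @export
observable_set <- function(data, N, V, n_repeats = NA_integer_, seed = NA_integer_) {
  req <- c("time", "observable", "mean", "sem")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(data$observable %in% OBSERVABLE_NAMES))
  if (length(bad)) {
    stop(sprintf("unknown observable '%s' at row %d", data$observable[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(data$sem < 0)
  if (length(bad)) {
    stop(sprintf("negative SEM at row %d (time = %g, %s)",
                 bad[1], data$time[bad[1]], data$observable[bad[1]]), call. = FALSE)
  }
  for (ob in unique(data$observable)) {
    tt <- data$time[data$observable == ob]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop(sprintf("non-monotone time grid for observable '%s'", ob), call. = FALSE)
    }
  }
  data <- data.frame(time = data$time, observable = data$observable,
                     mean = data$mean, sem = data$sem,
                     stringsAsFactors = FALSE)
  structure(data, class = c("observable_set", "data.frame"),
            N = N, V = V, n_repeats = n_repeats, seed = seed)
}

#' Extract monomer/dimer/trimer/cluster observables from an ensemble
#'
#' @param ens A `trajectory_ensemble`.
#' @return An `observable_set` in mean-count units.
#' @export
ensemble_to_observables <- function(ens) {
  V <- ens$V
  times <- ens$times
  df <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(time = times, observable = OBSERVABLE_NAMES[i],
               mean = ens$mean[, i] * V, sem = ens$sem[, i] * V,
               stringsAsFactors = FALSE)
  }))
  df <- rbind(df, data.frame(time = times, observable = "clusters",
                             mean = ens$clusters_mean, sem = ens$clusters_sem,
                             stringsAsFactors = FALSE))
  observable_set(df, N = ens$N, V = ens$V, n_repeats = ens$n_repeats,
                 seed = ens$seed)
}

#' Modified-Smoluchowski predictions for the fit observables
#'
#' Integrates the modified equations for a kernel family/parameter set and
#' returns the observables in mean-count units on the requested grid.
#'
#' @param family Kernel family name.
#' @param params Named list/vector of parameters (`k_f`, optionally `k_b`, `q`).
#' @param N,V System size and volume.
#' @param times Time grid (must start at 0).
#' @return Data frame `time, observable, mean`.
#' @export
predict_observables <- function(family, params, N, V, times) {
  model <- make_kernel(family, as.list(params), N)
  grid <- times
  if (grid[1L] != 0) grid <- c(0, grid)
  sol <- integrate_modified(model, V, grid)
  keep <- match(times, grid)
  counts <- sol$conc[keep, , drop = FALSE] * V
  df <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(time = times, observable = OBSERVABLE_NAMES[i],
               mean = counts[, i], stringsAsFactors = FALSE)
  }))
  rbind(df, data.frame(time = times, observable = "clusters",
                       mean = rowSums(counts), stringsAsFactors = FALSE))
}

#' Weighted chi-square of a prediction against data
#'
#' `chi2 = sum(((data - prediction) / sem)^2)` over all points and
#' observables on matching grids, and the reduced statistic
#' `chi2 / (n - m)`.
#'
#' @param data An `observable_set` (or plain data frame with the same
#'   columns); SEM values must be positive.
#' @param prediction Data frame `time, observable, mean` on the same grid.
#' @param m_params Number of fitted parameters `m`.
#' @return List with `chi2`, `nu` (degrees of freedom `n - m`) and
#'   `chi2_reduced`.
#' @export
chi_square <- function(data, prediction, m_params) {
  key_d <- paste(data$observable, format(data$time, digits = 15))
  key_p <- paste(prediction$observable, format(prediction$time, digits = 15))
  idx <- match(key_d, key_p)
  if (any(is.na(idx))) stop("data and prediction grids do not match", call. = FALSE)
  if (any(data$sem <= 0)) stop("all SEM values must be positive", call. = FALSE)
  n <- nrow(data)
  if (n <= m_params) {
    stop(sprintf("degrees of freedom error: n = %d observations <= m = %d parameters",
                 n, m_params), call. = FALSE)
  }
  chi2 <- sum(((data$mean - prediction$mean[idx]) / data$sem)^2)
  nu <- n - m_params
  list(chi2 = chi2, nu = nu, chi2_reduced = chi2 / nu)
}

## SEM floor and t = 0 handling: points where every repeat is identical
## (notably t = 0) have SEM 0 and would get infinite weight; they are
## excluded by default and any remaining zero SEM is floored at
## `sem_floor_frac * max(|mean|)` per observable.
prepare_fit_data <- function(data, drop_t0 = TRUE, sem_floor_frac = 1e-6) {
  df <- as.data.frame(data)
  if (drop_t0) df <- df[df$time != 0, ]
  for (ob in unique(df$observable)) {
    sel <- df$observable == ob
    floor_o <- sem_floor_frac * max(abs(df$mean[sel]), 1e-300)
    df$sem[sel] <- pmax(df$sem[sel], floor_o)
  }
  df
}

family_params <- function(family) {
  switch(family,
    constant = "k_f",
    diffusion = "k_f",
    blatz_tobolsky = c("k_f", "k_b"),
    three_param = c("k_f", "k_b", "q"),
    stop("unknown kernel family: ", family, call. = FALSE))
}

default_bounds <- function(pnames) {
  lo <- c(k_f = 1e-6, k_b = 1e-8, q = 1e-3)
  hi <- c(k_f = 1e+6, k_b = 1e+6, q = 1e+3)
  list(lower = lo[pnames], upper = hi[pnames])
}

## 5 deterministic starting points, log-uniform along the diagonal of the
## bounds box (15%..85% of the log range per parameter); a user-supplied
## `init` replaces the middle start.
multi_starts <- function(lower, upper, init = NULL) {
  frac <- seq(0.15, 0.85, length.out = 5)
  starts <- lapply(frac, function(f) exp(log(lower) + f * (log(upper) - log(lower))))
  if (!is.null(init)) starts[[3L]] <- init
  starts
}

obs_weights <- function(df, weighting) {
  if (weighting == "pooled") return(rep(1, nrow(df)))
  tab <- table(df$observable)
  n <- nrow(df); K <- length(tab)
  sqrt(n / (K * as.numeric(tab[df$observable])))
}

#' Fit a kernel model to averaged cluster-size data
#'
#' Global weighted least-squares fit of the modified Smoluchowski
#' predictions to the monomer/dimer/trimer/cluster time series, minimizing
#' the reduced chi-square. Parameters are log-transformed to enforce
#' positivity; five deterministic log-uniform starting points are tried
#' (bounded simplex or Brent line search, then a Levenberg-Marquardt
#' polish), and the best final chi-square wins. Deterministic given the data
#' and starts.
#'
#' @param data An `observable_set`.
#' @param family One of `"constant"`, `"diffusion"`, `"blatz_tobolsky"`,
#'   `"three_param"`.
#' @param N,V System size and volume (default: taken from `data`).
#' @param init Optional named starting values.
#' @param bounds Optional list with named vectors `lower`, `upper`.
#' @param fixed Optional named values to hold fixed (e.g. `c(q = 1)`).
#' @param weighting `"pooled"` (plain chi-square, default) or
#'   `"per_observable"` (each observable contributes equal total weight).
#' @param drop_t0 Exclude t = 0 points from the objective (default TRUE).
#' @param sem_floor_frac Relative SEM floor for zero-SEM points.
#' @return A `fit_result`.
#' @export
fit_model <- function(data, family, N = attr(data, "N"), V = attr(data, "V"),
                      init = NULL, bounds = NULL, fixed = NULL,
                      weighting = c("pooled", "per_observable"),
                      drop_t0 = TRUE, sem_floor_frac = 1e-6) {
  weighting <- match.arg(weighting)
  pnames <- family_params(family)
  free <- setdiff(pnames, names(fixed))
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)
  b <- default_bounds(free)
  if (!is.null(bounds)) {
    b$lower[names(bounds$lower)] <- bounds$lower
    b$upper[names(bounds$upper)] <- bounds$upper
    b$lower <- b$lower[free]; b$upper <- b$upper[free]
  }
  df <- prepare_fit_data(data, drop_t0 = drop_t0, sem_floor_frac = sem_floor_frac)
  times <- sort(unique(df$time))
  w <- obs_weights(df, weighting)
  n <- nrow(df); m <- length(free)
  if (n <= m) {
    stop(sprintf("degrees of freedom error: n = %d <= m = %d", n, m), call. = FALSE)
  }

  residuals_for <- function(theta_log) {
    params <- as.list(c(stats::setNames(exp(theta_log), free), unlist(fixed)))
    pred <- tryCatch(predict_observables(family, params, N, V, times),
                     error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, n))
    key_p <- paste(pred$observable, format(pred$time, digits = 15))
    key_d <- paste(df$observable, format(df$time, digits = 15))
    r <- (df$mean - pred$mean[match(key_d, key_p)]) / df$sem
    r * w
  }
  objective <- function(theta_log) sum(residuals_for(theta_log)^2)

  init_free <- if (!is.null(init)) unlist(init)[free] else NULL
  starts <- multi_starts(b$lower, b$upper, init_free)
  trace <- data.frame()
  best <- NULL
  for (s in seq_along(starts)) {
    th0 <- log(unlist(starts[[s]]))
    stage1 <- tryCatch({
      if (m == 1L) {
        ## bounded quasi-Newton from this start; a global Brent over the full
        ## (many-decade) bound interval can stall on flat plateaus
        stats::optim(th0, objective, method = "L-BFGS-B",
                     lower = log(b$lower), upper = log(b$upper),
                     control = list(maxit = 200))
      } else {
        stats::optim(th0, objective, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
      }
    }, error = function(e) list(par = th0, value = objective(th0)))
    polish <- tryCatch(
      minpack.lm::nls.lm(par = stage1$par, fn = residuals_for,
                         lower = log(b$lower), upper = log(b$upper),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(polish)) {
      final_par <- stage1$par; final_chi2 <- stage1$value
      info <- -1L; hess <- NULL
    } else {
      final_par <- polish$par; final_chi2 <- polish$deviance
      info <- polish$info; hess <- polish$hessian
    }
    trace <- rbind(trace, data.frame(
      start = s, chi2_start1 = stage1$value, chi2_final = final_chi2,
      info = info))
    if (is.null(best) || final_chi2 < best$chi2) {
      best <- list(par = final_par, chi2 = final_chi2, info = info, hess = hess)
    }
  }

  params <- stats::setNames(exp(unlist(best$par)), free)
  nu <- n - m
  stderr <- rep(NA_real_, m)
  if (!is.null(best$hess)) {
    cov_log <- tryCatch(solve(best$hess) * best$chi2 / nu, error = function(e) NULL)
    if (!is.null(cov_log)) stderr <- params * sqrt(pmax(diag(cov_log), 0))
  }
  names(stderr) <- free
  structure(list(family = family, params = params, stderr = stderr,
                 fixed = unlist(fixed), chi2 = best$chi2, nu = nu,
                 chi2_reduced = best$chi2 / nu,
                 converged = isTRUE(best$info %in% c(1, 2, 3)),
                 n_obs = n, m_params = m, weighting = weighting,
                 N = N, V = V, times = sort(unique(as.data.frame(data)$time)),
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s kernel>  chi2 = %.4g, nu = %d, chi2_nu = %.4g%s\n",
              x$family, x$chi2, x$nu, x$chi2_reduced,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (p in names(x$params)) {
    cat(sprintf("  %s = %.6g (+/- %.3g)\n", p, x$params[[p]], x$stderr[[p]]))
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank kernel families by reduced chi-square
#'
#' Fits each family to the same data and tabulates the results, sorted by
#' `chi2_reduced` with ties broken in favour of fewer parameters.
#'
#' @inheritParams fit_model
#' @param families Character vector of kernel families to try.
#' @param ... Passed to [fit_model()].
#' @return A `model_discrimination` object: `$table` (ranked summary) and
#'   `$fits` (named list of `fit_result`s).
#' @export
model_discrimination <- function(data, families, N = attr(data, "N"),
                                 V = attr(data, "V"), ...) {
  fits <- lapply(families, function(fam) fit_model(data, fam, N = N, V = V, ...))
  names(fits) <- families
  tab <- data.frame(
    family = families,
    m_params = vapply(fits, function(f) f$m_params, integer(1)),
    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
    nu = vapply(fits, function(f) f$nu, integer(1)),
    chi2_reduced = vapply(fits, function(f) f$chi2_reduced, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$chi2_reduced, tab$m_params)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "model_discrimination")
}

#' @export
print.model_discrimination <- function(x, ...) {
  cat("<model_discrimination> ranked by reduced chi-square:\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Monte Carlo validation of a fitted model
#'
#' Simulates a stochastic ensemble at the fitted parameters and averages it.
#' The Monte Carlo means are compared (a) with the modified-ODE predictions
#' at the same parameters, checking that the mean-field closure represents
#' the stochastic model, and (b) when `data` is supplied, with the fitted
#' data themselves -- the analogue of comparing simulation averages with the
#' Monte Carlo averages at the recovered parameters. Deviations are
#' expressed in SEM units (combined in quadrature for the data comparison);
#' the validation passes when every comparison stays within 3 SEM at >= 95%
#' of the grid points.
#'
#' @param fit A converged `fit_result`.
#' @param data Optional `observable_set` the model was fitted to.
#' @param n_repeats Number of validation trajectories.
#' @param seed Integer seed.
#' @param sem_floor_frac Relative SEM floor (as in fitting).
#' @return A `fit_validation` report.
#' @export
validate_fit <- function(fit, data = NULL, n_repeats = 1000, seed,
                         sem_floor_frac = 1e-6) {
  params <- as.list(c(fit$params, fit$fixed))
  model <- make_kernel(fit$family, params, fit$N)
  grid <- fit$times
  ens <- simulate_ensemble(model, V = fit$V, t_max = max(grid),
                           n_repeats = n_repeats, grid = grid, seed = seed)
  mc <- prepare_fit_data(ensemble_to_observables(ens), drop_t0 = TRUE,
                         sem_floor_frac = sem_floor_frac)
  pred <- predict_observables(fit$family, params, fit$N, fit$V,
                              sort(unique(mc$time)))
  key_p <- paste(pred$observable, format(pred$time, digits = 15))
  key_d <- paste(mc$observable, format(mc$time, digits = 15))
  z_ode <- abs(mc$mean - pred$mean[match(key_d, key_p)]) / mc$sem
  z <- data.frame(time = mc$time, observable = mc$observable,
                  comparison = "mc_vs_ode", z = z_ode,
                  stringsAsFactors = FALSE)
  if (!is.null(data)) {
    dd <- prepare_fit_data(data, drop_t0 = TRUE, sem_floor_frac = sem_floor_frac)
    key_dd <- paste(dd$observable, format(dd$time, digits = 15))
    key_mc <- paste(mc$observable, format(mc$time, digits = 15))
    idx <- match(key_dd, key_mc)
    if (any(is.na(idx))) stop("data grid does not match the fit grid", call. = FALSE)
    z_dat <- abs(mc$mean[idx] - dd$mean) / sqrt(mc$sem[idx]^2 + dd$sem^2)
    z <- rbind(z, data.frame(time = dd$time, observable = dd$observable,
                             comparison = "mc_vs_data", z = z_dat,
                             stringsAsFactors = FALSE))
  }
  frac_by_cmp <- tapply(z$z, z$comparison, function(v) mean(v <= 3))
  by_obs <- tapply(z$z, z$observable, max)
  structure(list(z = z,
                 max_z_by_observable = by_obs,
                 frac_within_by_comparison = frac_by_cmp,
                 frac_within = mean(z$z <= 3),
                 pass = all(frac_by_cmp >= 0.95),
                 n_repeats = n_repeats, seed = seed),
            class = "fit_validation")
}

#' @export
print.fit_validation <- function(x, ...) {
  cat(sprintf("<fit_validation>  %s: %.1f%% of points within 3 SEM (%d repeats)\n",
              if (x$pass) "PASS" else "FAIL", 100 * x$frac_within, x$n_repeats))
  print(round(x$frac_within_by_comparison, 3))
  print(round(x$max_z_by_observable, 2))
  invisible(x)
}

#' Cross-concentration consistency of a kernel model
#'
#' Fits each dataset separately and jointly with shared parameters. When the
#' stochastic model holds, the kernels are concentration-independent: the
#' single-dataset parameters agree and the joint fit is as good as the
#' single fits. It also returns scaled-time curves (`mean/N` against
#' `k_f c t`, using the joint `k_f`) for the master-curve collapse
#' diagnostic.
#'
#' @param datasets List (length >= 2) of `observable_set`s at different
#'   initial concentrations.
#' @param family Kernel family to fit.
#' @param ... Passed to [fit_model()].
#' @return A `cross_concentration_report`.
#' @export
cross_concentration_check <- function(datasets, family = "constant", ...) {
  if (length(datasets) < 2L) stop("need at least 2 datasets", call. = FALSE)
  single <- lapply(datasets, fit_model, family = family, ...)
  pnames <- family_params(family)

  ## joint fit: shared parameters across all datasets
  prep <- lapply(datasets, prepare_fit_data)
  joint_resid <- function(theta_log) {
    params <- as.list(stats::setNames(exp(theta_log), pnames))
    unlist(lapply(seq_along(prep), function(d) {
      df <- prep[[d]]
      N <- attr(datasets[[d]], "N"); V <- attr(datasets[[d]], "V")
      times <- sort(unique(df$time))
      pred <- tryCatch(predict_observables(family, params, N, V, times),
                       error = function(e) NULL)
      if (is.null(pred)) return(rep(1e6, nrow(df)))
      key_p <- paste(pred$observable, format(pred$time, digits = 15))
      key_d <- paste(df$observable, format(df$time, digits = 15))
      (df$mean - pred$mean[match(key_d, key_p)]) / df$sem
    }))
  }
  b <- default_bounds(pnames)
  th0 <- log(vapply(pnames, function(p) {
    mean(vapply(single, function(f) f$params[[p]], numeric(1)))
  }, numeric(1)))
  jfit <- minpack.lm::nls.lm(par = th0, fn = joint_resid,
                             lower = log(b$lower), upper = log(b$upper),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  n_tot <- sum(vapply(prep, nrow, integer(1)))
  m <- length(pnames)
  joint <- list(params = stats::setNames(exp(jfit$par), pnames),
                chi2 = jfit$deviance, nu = n_tot - m,
                chi2_reduced = jfit$deviance / (n_tot - m),
                converged = jfit$info %in% c(1, 2, 3))

  spread <- vapply(pnames, function(p) {
    v <- vapply(single, function(f) f$params[[p]], numeric(1))
    (max(v) - min(v)) / mean(v)
  }, numeric(1))

  kf_joint <- joint$params[["k_f"]]
  scaled <- do.call(rbind, lapply(seq_along(datasets), function(d) {
    df <- as.data.frame(datasets[[d]])
    N <- attr(datasets[[d]], "N"); V <- attr(datasets[[d]], "V")
    cc <- N / V
    data.frame(dataset = d, concentration = cc, observable = df$observable,
               T_scaled = kf_joint * cc * df$time,
               scaled_mean = df$mean / N, scaled_sem = df$sem / N,
               stringsAsFactors = FALSE)
  }))

  structure(list(single = single, joint = joint, spread = spread,
                 scaled_curves = scaled,
                 single_chi2_reduced = vapply(single, function(f) f$chi2_reduced,
                                              numeric(1)),
                 consistent = joint$chi2_reduced <=
                   2 * max(vapply(single, function(f) f$chi2_reduced, numeric(1)))),
            class = "cross_concentration_report")
}

#' @export
print.cross_concentration_report <- function(x, ...) {
  kf <- vapply(x$single, function(f) f$params[["k_f"]], numeric(1))
  cat("<cross_concentration_report>\n")
  cat("  single-fit k_f:", paste(signif(kf, 5), collapse = ", "), "\n")
  cat(sprintf("  joint chi2_nu = %.4g vs single %s\n", x$joint$chi2_reduced,
              paste(signif(x$single_chi2_reduced, 4), collapse = ", ")))
  cat(sprintf("  relative k_f spread = %.3g; %s\n", x$spread[["k_f"]],
              if (x$consistent) "consistent" else "INCONSISTENT across concentrations"))
  invisible(x)
}
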