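## Finite-size (modified) and truncated classical Smoluchowski equations ----
##
## Both variants share one channel-based right-hand side: per unordered
## channel (i, j) the aggregation event rate per unit volume is
## K_ij c_i c_j / (1 + delta_ij) and the fragmentation event rate per unit
## volume is F_ij c_{i+j}; the stoichiometry matrix of the channel table
## turns event rates into concentration derivatives. This is algebraically
## identical to the conventional rate-equation form with coefficients
## k_ij = K_ij and f_ij = (1 + delta_ij) F_ij, with all sums restricted to
## sizes <= N. Mass conservation is built into the pairwise bookkeeping.

#' Right-hand side of the modified Smoluchowski equations
#'
#' Time derivative of the mean concentrations for a finite system of `N`
#' monomers. No channel creates sizes above `N`.
#'
#' @param conc Concentration vector of length `model$max_size`.
#' @param model A `kernel_model`.
#' @param N System size; must equal `model$max_size`.
#' @return The derivative vector `d conc / dt`.
#' @export
modified_rhs <- function(conc, model, N = model$max_size) {
  ch <- model$channels
  stopifnot(length(conc) == N, N == model$max_size)
  r_agg <- ch$Kv * conc[ch$ii] * conc[ch$jj] / ch$pair_div
  r_frag <- ch$Fv * conc[ch$kk]
  as.vector(ch$S %*% (r_agg - r_frag))
}

ode_jacobian <- function(conc, model) {
  ch <- model$channels
  N <- model$max_size
  nch <- ch$n_channels
  ## d(r_agg - r_frag)/dc as a sparse (nch x N) matrix
  dR <- Matrix::sparseMatrix(
    i = c(seq_len(nch), seq_len(nch), seq_len(nch)),
    j = c(ch$ii, ch$jj, ch$kk),
    x = c(ch$Kv * conc[ch$jj] / ch$pair_div,
          ch$Kv * conc[ch$ii] / ch$pair_div,
          -ch$Fv),
    dims = c(nch, N))
  as.matrix(ch$S %*% dR)
}

integrate_channels <- function(model, conc0, times, rtol, atol, variant, V = NA_real_) {
  N <- model$max_size
  if (times[1L] != 0) stop("time grid must start at 0", call. = FALSE)
  rhs <- function(t, y, parms) list(modified_rhs(y, model))
  jac <- function(t, y, parms) ode_jacobian(y, model)
  out <- deSolve::lsoda(y = conc0, times = times, func = rhs, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0) {
    stop(sprintf(paste0("Smoluchowski integration failed (rtol = %g, atol = %g); ",
                        "consider loosening rtol or refining the grid"),
                 rtol, atol), call. = FALSE)
  }
  conc <- unname(out[, -1L, drop = FALSE])
  if (min(conc) < -atol) {
    stop(sprintf("negative concentration %.3e beyond -atol: convention error",
                 min(conc)), call. = FALSE)
  }
  conc[conc < 0] <- 0
  c0 <- sum(seq_len(N) * conc0)
  drift <- max(abs(conc %*% seq_len(N) - c0))
  if (drift > 1e-8 * c0) {
    stop(sprintf("mass drift %.3e exceeds 1e-8 * c", drift), call. = FALSE)
  }
  structure(list(times = times, conc = conc, variant = variant,
                 model = model$name, params = model$params,
                 N = N, c = c0, V = V),
            class = "deterministic_solution")
}

#' @export
print.deterministic_solution <- function(x, ...) {
  cat(sprintf("<deterministic_solution: %s, %s>  N = %d, c = %g, %d times in [%g, %g]\n",
              x$model, x$variant, x$N, x$c, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Integrate the modified Smoluchowski equations
#'
#' Stiff-capable adaptive integration of the finite-size mean-concentration
#' rate equations from the monodisperse start `c_i(0) = (N/V) delta_{1,i}`.
#'
#' @param model A `kernel_model`; its `max_size` is the system size `N`.
#' @param V System volume (the initial concentration is `c = N/V`).
#' @param times Output time grid starting at 0.
#' @param rtol,atol Solver tolerances (defaults `1e-8` and `1e-12 * c`).
#' @return A `deterministic_solution` (`variant = "modified"`).
#' @export
integrate_modified <- function(model, V, times, rtol = 1e-8, atol = NULL) {
  N <- model$max_size
  c0 <- N / V
  if (is.null(atol)) atol <- 1e-12 * c0
  conc0 <- c(c0, numeric(N - 1L))
  integrate_channels(model, conc0, times, rtol, atol, "modified", V = V)
}

#' Integrate the truncated classical Smoluchowski equations
#'
#' The deterministic (infinite-system) kinetics approximated by truncation at
#' a large `N_max`. `N_max` is doubled automatically until the
#' monomer/dimer/trimer curves change by less than `1e-8` relative, so the
#' result represents the `N = Inf` limit over the requested time span.
#'
#' @param model A `kernel_model` (its `max_size` is ignored; only the family
#'   and parameters are used).
#' @param c Initial monomer concentration.
#' @param times Output time grid starting at 0.
#' @param N_max Starting truncation size.
#' @param rtol,atol Solver tolerances.
#' @return A `deterministic_solution` (`variant = "unmodified"`).
#' @export
integrate_unmodified <- function(model, c, times, N_max = 400,
                                 rtol = 1e-10, atol = NULL) {
  if (is.null(atol)) atol <- 1e-14 * c
  prev <- NULL
  Nm <- N_max
  repeat {
    big <- make_kernel(model$name, model$params, Nm)
    conc0 <- c(c, numeric(Nm - 1L))
    sol <- integrate_channels(big, conc0, times, rtol, atol, "unmodified")
    if (!is.null(prev)) {
      rel <- abs(sol$conc[, 1:3] - prev$conc[, 1:3]) /
        pmax(abs(sol$conc[, 1:3]), 1e-300)
      rel[sol$conc[, 1:3] < 1e-12 * c] <- 0
      if (max(rel) < 1e-8) return(sol)
    }
    prev <- sol
    Nm <- Nm * 2L
    if (Nm > 12800) {
      stop(sprintf("truncation did not converge up to N_max = %d", Nm %/% 2L),
           call. = FALSE)
    }
  }
}

concentrations_at <- function(x, t) {
  UseMethod("concentrations_at")
}

#' @export
concentrations_at.deterministic_solution <- function(x, t) {
  idx <- match(t, x$times)
  if (any(is.na(idx))) stop("time not on the stored grid", call. = FALSE)
  x$conc[idx, , drop = FALSE]
}

#' @export
concentrations_at.trajectory_ensemble <- function(x, t) {
  idx <- match(t, x$times)
  if (any(is.na(idx))) stop("time not on the stored grid", call. = FALSE)
  x$mean[idx, , drop = FALSE]
}

#' @export
concentrations_at.master_solution <- function(x, t) {
  idx <- match(t, x$times)
  if (any(is.na(idx))) stop("time not on the stored grid", call. = FALSE)
  x$conc[idx, , drop = FALSE]
}

#' Number-average aggregate size
#'
#' `L = sum_i i c_i / sum_i c_i`: total monomer mass over total cluster
#' count. For mass-conserving solutions this equals `c / sum_i c_i`.
#'
#' @param x A `deterministic_solution`, `trajectory_ensemble`,
#'   `master_solution` or `analytic_solution`.
#' @param t Times at which to evaluate (default: the stored grid; mandatory
#'   for analytic solutions).
#' @return Numeric vector of `L` values.
#' @export
number_average_size <- function(x, t = NULL) {
  if (inherits(x, "analytic_solution")) {
    if (is.null(t)) stop("'t' is required for analytic solutions", call. = FALSE)
    return(vapply(t, function(tt) {
      m1 <- analytic_moment(x, tt, order = 1)
      m0 <- analytic_moment(x, tt, order = 0)
      m1 / m0
    }, numeric(1)))
  }
  if (is.null(t)) t <- x$times
  conc <- concentrations_at(x, t)
  m0 <- rowSums(conc)
  if (any(m0 <= 0)) stop("all-zero concentrations: L undefined", call. = FALSE)
  as.vector(conc %*% seq_len(ncol(conc))) / m0
}

#' Total cluster count
#'
#' `n_cluster = V sum_i c_i`, the number of clusters of any size (monomers
#' included). For irreversible kernels it decreases monotonically from `N`
#' to 1.
#'
#' @param x A solution or ensemble object carrying concentrations.
#' @param V System volume; taken from `x` when present.
#' @param t Times at which to evaluate (default: the stored grid).
#' @return Numeric vector of cluster counts.
#' @export
total_clusters <- function(x, V = NULL, t = NULL) {
  if (is.null(V)) V <- x$V
  if (is.null(V) || is.na(V)) stop("volume 'V' must be supplied", call. = FALSE)
  if (is.null(t)) t <- x$times
  conc <- concentrations_at(x, t)
  V * rowSums(conc)
}
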