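## Closed-form cluster-size distributions -----------------------------------
##
## Deterministic-limit (infinite system) solutions under monodisperse initial
## conditions c_i(0) = c * delta_{1,i}. All evaluation is done in log space so
## that large cluster sizes do not underflow prematurely.

new_analytic_solution <- function(model, c, params, log_ci) {
  evaluate <- function(i, t) {
    if (any(i < 1) || any(i != round(i))) {
      stop("cluster size 'i' must be a positive integer", call. = FALSE)
    }
    if (any(t < 0)) stop("time 't' must be non-negative", call. = FALSE)
    n <- max(length(i), length(t))
    i <- rep_len(as.numeric(i), n)
    t <- rep_len(as.numeric(t), n)
    exp(log_ci(i, t))
  }
  structure(list(model = model, c = c, params = params, evaluate = evaluate),
            class = "analytic_solution")
}

#' @export
print.analytic_solution <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("<analytic_solution: %s kernel>  c = %g; %s\n", x$model, x$c,
              paste(names(p), signif(p, 6), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Closed-form kinetics for the constant aggregation kernel
#'
#' Deterministic-limit cluster-size distribution for irreversible aggregation
#' with `K(i,j) = k_f` and monodisperse start:
#' `c_i(t) = c * tau^(i-1) / (1 + tau)^(i+1)` with `tau = k_f c t / 2`.
#'
#' @param c Initial monomer concentration (1/volume), `> 0`.
#' @param k_f Aggregation kernel value (volume/time), `> 0`.
#' @return An `analytic_solution` whose `$evaluate(i, t)` returns `c_i(t)`.
#' @export
constant_kernel_solution <- function(c, k_f) {
  c <- check_rate(c, "c"); k_f <- check_rate(k_f, "k_f")
  log_ci <- function(i, t) {
    tau <- k_f * c * t / 2
    out <- ifelse(i == 1, log(c) - 2 * log1p(tau),
                  log(c) + (i - 1) * log(tau) - (i + 1) * log1p(tau))
    ifelse(tau == 0 & i > 1, -Inf, out)
  }
  new_analytic_solution("constant", c, list(k_f = k_f), log_ci)
}

#' Closed-form kinetics for the additive aggregation kernel
#'
#' Deterministic-limit solution for `K(i,j) = k_f (i + j) / 2` and
#' monodisperse start (the Golovin solution): with
#' `T = 1 - exp(-k_f c t / 2)`,
#' `c_i(t) = c (1 - T) (i T)^(i-1) exp(-i T) / i!` -- a Borel distribution in
#' the cluster size.
#'
#' @inheritParams constant_kernel_solution
#' @return An `analytic_solution`.
#' @export
additive_kernel_solution <- function(c, k_f) {
  c <- check_rate(c, "c"); k_f <- check_rate(k_f, "k_f")
  log_ci <- function(i, t) {
    Tb <- -expm1(-k_f * c * t / 2)
    out <- ifelse(i == 1, log(c) + log1p(-Tb) - Tb,
                  log(c) + log1p(-Tb) + (i - 1) * (log(i) + log(Tb)) -
                    i * Tb - lgamma(i + 1))
    ifelse(Tb == 0 & i > 1, -Inf, out)
  }
  new_analytic_solution("additive", c, list(k_f = k_f), log_ci)
}

#' Closed-form kinetics for the Blatz-Tobolsky reversible model
#'
#' Exact solution of the size-independent reversible model
#' ([blatz_tobolsky_kernel()]) under monodisperse initial conditions. The
#' distribution stays geometric, `c_i(t) = c (1 - p)^2 p^(i-1)`, where the
#' extent of reaction `p(t)` solves the Riccati equation
#' `dp/dt = (k_f c / 2) (1 - p)^2 - (k_b / 2) p`, `p(0) = 0`, with closed
#' form `p(t) = p_lo (1 - exp(-lambda t)) / (1 - (p_lo/p_hi) exp(-lambda t))`
#' where `p_lo <= p_hi` are the Riccati roots and
#' `lambda = sqrt((k_b/2) (2 k_f c + k_b/2))`. `k_b = 0` reduces exactly to
#' [constant_kernel_solution()].
#'
#' @inheritParams constant_kernel_solution
#' @param k_b Fragmentation rate coefficient (1/time), `>= 0`.
#' @return An `analytic_solution`.
#' @export
blatz_tobolsky_solution <- function(c, k_f, k_b) {
  c <- check_rate(c, "c"); k_f <- check_rate(k_f, "k_f")
  k_b <- check_rate(k_b, "k_b", allow_zero = TRUE)
  a <- k_f * c / 2
  b <- k_b / 2
  p_of_t <- function(t) {
    if (b == 0) {
      a * t / (1 + a * t)
    } else {
      disc <- sqrt(b * (4 * a + b))
      p_lo <- ((2 * a + b) - disc) / (2 * a)
      p_hi <- ((2 * a + b) + disc) / (2 * a)
      lambda <- a * (p_hi - p_lo)   # = sqrt(b (4 a + b))
      em <- exp(-lambda * t)
      p_lo * (1 - em) / (1 - (p_lo / p_hi) * em)
    }
  }
  log_ci <- function(i, t) {
    p <- p_of_t(t)
    out <- ifelse(i == 1, log(c) + 2 * log1p(-p),
                  log(c) + 2 * log1p(-p) + (i - 1) * log(p))
    ifelse(p == 0 & i > 1, -Inf, out)
  }
  sol <- new_analytic_solution("blatz_tobolsky", c, list(k_f = k_f, k_b = k_b), log_ci)
  sol$extent <- p_of_t
  sol
}

#' Summed moments of an analytic solution with adaptive tail truncation
#'
#' Sums `i^order * c_i(t)` over `i = 1, 2, ...`, stopping once the running
#' tail terms `i * c_i` fall below `tol * c` (the closed forms all have
#' geometric-type tails).
#'
#' @param sol An `analytic_solution`.
#' @param t Scalar time.
#' @param order Moment order (0 for total cluster concentration, 1 for mass).
#' @param tol Relative tail cutoff.
#' @param max_terms Hard cap on the number of terms.
#' @return The truncated moment sum.
#' @export
analytic_moment <- function(sol, t, order = 1, tol = 1e-15, max_terms = 1e6) {
  stopifnot(length(t) == 1L, t >= 0)
  total <- 0
  i0 <- 1
  chunk <- 512
  repeat {
    i <- i0:(i0 + chunk - 1)
    ci <- sol$evaluate(i, t)
    total <- total + sum(i^order * ci)
    if (max(i * ci) < tol * sol$c || i0 + chunk > max_terms) break
    i0 <- i0 + chunk
  }
  total
}
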