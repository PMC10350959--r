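#' @useDynLib aggkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Aggregation / fragmentation kernel models -------------------------------
##
## A kernel model holds the symmetric aggregation kernel K(i,j) (volume/time)
## and fragmentation kernel F(i,j) (1/time) together with a dense cache up to
## max_size and the channel table shared by the stochastic and deterministic
## codepaths. Channels are unordered pairs (i, j) with i <= j and i + j <= N;
## a permutation of cluster indices is not a new process.

new_kernel_model <- function(name, params, Kfun, Ffun, N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N)) {
    stop("invalid parameter: 'N' must be a single integer >= 2", call. = FALSE)
  }
  N <- as.integer(N)
  idx <- seq_len(N)
  Kmat <- outer(idx, idx, Kfun)
  Fmat <- outer(idx, idx, Ffun)
  if (any(!is.finite(Kmat)) || any(!is.finite(Fmat))) {
    stop("kernel evaluation produced non-finite values", call. = FALSE)
  }
  if (any(Kmat < 0) || any(Fmat < 0)) {
    stop("kernels must be non-negative", call. = FALSE)
  }
  if (max(abs(Kmat - t(Kmat))) > 0 || max(abs(Fmat - t(Fmat))) > 0) {
    stop("kernels must be symmetric in (i, j)", call. = FALSE)
  }
  model <- structure(
    list(name = name, params = params, K = Kfun, F = Ffun, max_size = N,
         Kmat = Kmat, Fmat = Fmat),
    class = "kernel_model")
  model$channels <- build_channels(model)
  model
}

## Channel table: one row per unordered reaction pair (i <= j, i + j <= N).
## Kv/Fv are the kernel values, `pair_div` the 1 + delta_{i,j} pair-counting
## divisor, and S the N x n_channels stoichiometry matrix of one aggregation
## event (fragmentation is its negation).
build_channels <- function(model) {
  N <- model$max_size
  ii <- jj <- integer(0)
  for (i in seq_len(N %/% 2)) {
    j <- i:(N - i)              # j >= i and i + j <= N, never empty here
    ii <- c(ii, rep.int(i, length(j)))
    jj <- c(jj, j)
  }
  kk <- ii + jj
  diag <- ii == jj
  nch <- length(ii)
  ## stoichiometry of aggregation (i, j) -> (i + j)
  rows <- c(ii, jj[!diag], kk)
  cols <- c(seq_len(nch), which(!diag), seq_len(nch))
  vals <- c(ifelse(diag, -2, -1), rep.int(-1, sum(!diag)), rep.int(1, nch))
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, nch))
  list(ii = ii, jj = jj, kk = kk, diag = diag,
       Kv = model$Kmat[cbind(ii, jj)],
       Fv = model$Fmat[cbind(ii, jj)],
       pair_div = 1 + as.numeric(diag),
       S = S, n_channels = nch)
}

check_rate <- function(x, nm, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) {
    stop(sprintf("invalid parameter: '%s' must be a %s finite number",
                 nm, if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Size-independent irreversible aggregation kernel
#'
#' The classical Smoluchowski model with a constant aggregation kernel,
#' `K(i,j) = k_f`, and no fragmentation.
#'
#' @param k_f Aggregation rate kernel (volume/time units; dimensionless runs
#'   use `k_f = 1`). Must be positive.
#' @param N Total number of monomers; the largest possible cluster size.
#' @return A `kernel_model` object.
#' @examples
#' m <- constant_kernel(k_f = 1, N = 5)
#' kernel_K(m, 2, 3)
#' @export
constant_kernel <- function(k_f, N) {
  k_f <- check_rate(k_f, "k_f")
  new_kernel_model("constant", list(k_f = k_f),
                   function(i, j) k_f + 0 * i,
                   function(i, j) 0 * i, N)
}

#' Additive (sum) aggregation kernel
#'
#' Irreversible aggregation with `K(i,j) = k_f (i + j) / 2`, normalized so
#' that `K(1,1) = k_f` and the monomer-monomer rate matches the constant
#' kernel with the same `k_f`.
#'
#' @inheritParams constant_kernel
#' @return A `kernel_model` object.
#' @export
additive_kernel <- function(k_f, N) {
  k_f <- check_rate(k_f, "k_f")
  new_kernel_model("additive", list(k_f = k_f),
                   function(i, j) k_f * (i + j) / 2,
                   function(i, j) 0 * i, N)
}

#' Brownian coalescence (diffusion) kernel
#'
#' The aggregation kernel for diffusing, coalescing spheres,
#' `K(i,j) = (k_f/4) (i^(1/3) + j^(1/3)) (i^(-1/3) + j^(-1/3))`,
#' with the composite physical constants collected in `k_f` and normalized so
#' the diagonal `K(i,i) = k_f` for every size.
#'
#' @inheritParams constant_kernel
#' @return A `kernel_model` object.
#' @export
diffusion_kernel <- function(k_f, N) {
  k_f <- check_rate(k_f, "k_f")
  new_kernel_model("diffusion", list(k_f = k_f),
                   function(i, j) (k_f / 4) * (i^(1/3) + j^(1/3)) * (i^(-1/3) + j^(-1/3)),
                   function(i, j) 0 * i, N)
}

#' Blatz-Tobolsky reversible aggregation-fragmentation kernel
#'
#' Size-independent reversible kinetics: every pair of clusters aggregates
#' with kernel `K(i,j) = k_f` and every cluster splits into any admissible
#' pair with a uniform fragmentation rate *coefficient* `k_b`, i.e.
#' `F(i,j) = k_b / (1 + delta_ij)`. With this convention the adsorbed
#' coefficient `f_ij = (1 + delta_ij) F_ij = k_b` is the same for every split
#' channel and the model admits the exact geometric closed-form solution of
#' [blatz_tobolsky_solution()]. `k_b = 0` reduces exactly to
#' [constant_kernel()].
#'
#' @inheritParams constant_kernel
#' @param k_b Fragmentation rate coefficient (1/time), `>= 0`.
#' @return A `kernel_model` object.
#' @export
blatz_tobolsky_kernel <- function(k_f, k_b, N) {
  k_f <- check_rate(k_f, "k_f")
  k_b <- check_rate(k_b, "k_b", allow_zero = TRUE)
  new_kernel_model("blatz_tobolsky", list(k_f = k_f, k_b = k_b),
                   function(i, j) k_f + 0 * i,
                   function(i, j) k_b / (1 + (i == j)), N)
}

#' Three-parameter kernel with boosted monomer channels
#'
#' The Blatz-Tobolsky reversible model in which every channel that involves a
#' monomer -- a monomer aggregating with any cluster, or a cluster splitting
#' off a monomer -- is faster by a factor `q`, on both the aggregation and
#' the fragmentation side. `q = 1` reduces exactly to
#' [blatz_tobolsky_kernel()].
#'
#' @inheritParams blatz_tobolsky_kernel
#' @param q Dimensionless monomer boost factor, `> 0`.
#' @return A `kernel_model` object.
#' @export
three_param_kernel <- function(k_f, k_b, q, N) {
  k_f <- check_rate(k_f, "k_f")
  k_b <- check_rate(k_b, "k_b", allow_zero = TRUE)
  q <- check_rate(q, "q")
  boost <- function(i, j) ifelse(pmin(i, j) == 1, q, 1)
  new_kernel_model("three_param", list(k_f = k_f, k_b = k_b, q = q),
                   function(i, j) k_f * boost(i, j),
                   function(i, j) boost(i, j) * k_b / (1 + (i == j)), N)
}

#' Build a kernel model by family name
#'
#' @param family One of `"constant"`, `"additive"`, `"diffusion"`,
#'   `"blatz_tobolsky"`, `"three_param"`.
#' @param params Named list with `k_f` and, where applicable, `k_b`, `q`.
#' @param N Total monomer count.
#' @return A `kernel_model` object.
#' @export
make_kernel <- function(family, params, N) {
  family <- match.arg(family, c("constant", "additive", "diffusion",
                                "blatz_tobolsky", "three_param"))
  switch(family,
    constant = constant_kernel(params$k_f, N),
    additive = additive_kernel(params$k_f, N),
    diffusion = diffusion_kernel(params$k_f, N),
    blatz_tobolsky = blatz_tobolsky_kernel(params$k_f, params$k_b, N),
    three_param = three_param_kernel(params$k_f, params$k_b, params$q, N))
}

#' Evaluate the aggregation kernel of a model
#' @param model A `kernel_model`.
#' @param i,j Cluster sizes (vectors recycle).
#' @return Kernel values `K(i,j)`.
#' @export
kernel_K <- function(model, i, j) model$Kmat[cbind(i, j)]

#' Evaluate the fragmentation kernel of a model
#' @inheritParams kernel_K
#' @return Kernel values `F(i,j)`.
#' @export
kernel_F <- function(model, i, j) model$Fmat[cbind(i, j)]

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("<kernel_model: %s>  N = %d\n", x$name, x$max_size))
  p <- unlist(x$params)
  cat("  params:", paste(names(p), signif(p, 6), sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  channels: %d (pairs i <= j, i + j <= N)\n", x$channels$n_channels))
  if (all(x$Fmat == 0)) cat("  irreversible (F == 0)\n")
  invisible(x)
}

#' Deterministic rate coefficients of a kernel model
#'
#' Converts the stochastic kernels to the rate coefficients of the
#' concentration rate equations. The aggregation coefficients equal the
#' kernel, `k_ij = K_ij`; the fragmentation coefficients adsorb the
#' stoichiometric factor for splits into equal fragments,
#' `f_ij = (1 + delta_ij) F_ij`. The modified fragmentation coefficient
#' `f'_ij` entering the finite-size rate equations coincides with `f_ij`.
#'
#' With these coefficients the rate of aggregation events per unit volume is
#' `K_ij c_i c_j / (1 + delta_ij)` and the rate of fragmentation events per
#' unit volume is `F_ij c_{i+j}`, matching the master-equation propensities.
#'
#' @param model A `kernel_model`.
#' @return List with symmetric matrices `k`, `f` and `f_prime`.
#' @export
kernels_to_rate_coefficients <- function(model) {
  N <- model$max_size
  delta <- diag(N)
  f <- (1 + delta) * model$Fmat
  list(k = model$Kmat, f = f, f_prime = f)
}
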