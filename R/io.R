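## Readers/writers for the delimited-text artifacts ------------------------
##
## One long-form CSV schema is shared by all kinetic outputs:
##   time, size-or-observable, mean, sem
## with a machine-readable provenance header in '#' comment lines.

aggkin_version <- function() {
  as.character(utils::packageVersion("aggkin"))
}

## 32-bit FNV-1a over a string, for config provenance hashes
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                       # xor touches the low byte only
    h <- h - low + bitwXor(low, b)
    ## 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_header <- function(fields) {
  fields <- c(list(tool = paste0("aggkin ", aggkin_version())), fields)
  fields$hash <- fnv1a(paste(names(fields), unlist(fields), collapse = ";"))
  paste0("# ", names(fields), "=", vapply(fields, as.character, character(1)))
}

parse_header <- function(lines) {
  lines <- sub("^# *", "", lines)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1L], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Write an observable set to CSV
#'
#' Long-form schema `time, observable, mean, sem` with a provenance header.
#'
#' @param obs An `observable_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observables <- function(obs, path) {
  header <- provenance_header(list(
    type = "observables", N = attr(obs, "N"), V = attr(obs, "V"),
    n_repeats = attr(obs, "n_repeats"), seed = attr(obs, "seed")))
  write_csv_with_header(as.data.frame(obs), path, header)
  invisible(path)
}

#' Read an observable set from CSV
#'
#' Validates the schema and reports offending rows: missing columns,
#' negative SEMs and non-monotone time grids are rejected.
#'
#' @param path CSV file written by [write_observables()] (or following the
#'   same schema).
#' @return An `observable_set`.
#' @export
read_observables <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  all_lines <- readLines(path)
  meta <- parse_header(grep("^#", all_lines, value = TRUE))
  df <- utils::read.csv(text = all_lines[!grepl("^#", all_lines)],
                        stringsAsFactors = FALSE)
  num <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  observable_set(df, N = num(meta$N), V = num(meta$V),
                 n_repeats = num(meta$n_repeats), seed = num(meta$seed))
}

kinetics_frame <- function(x) {
  if (inherits(x, "trajectory_ensemble")) {
    N <- x$N
    data.frame(time = rep(x$times, N), size = rep(seq_len(N), each = length(x$times)),
               mean = as.vector(x$mean), sem = as.vector(x$sem))
  } else if (inherits(x, "deterministic_solution")) {
    N <- x$N
    data.frame(time = rep(x$times, N), size = rep(seq_len(N), each = length(x$times)),
               mean = as.vector(x$conc), sem = 0)
  } else if (inherits(x, "master_solution")) {
    N <- x$N
    data.frame(time = rep(x$times, N), size = rep(seq_len(N), each = length(x$times)),
               mean = as.vector(x$conc), sem = 0)
  } else {
    stop("cannot serialize object of class ", class(x)[1L], call. = FALSE)
  }
}

#' Write per-size kinetics (ensemble, ODE or master solution) to CSV
#'
#' Long form `time, size, mean, sem` in concentration units; deterministic
#' sources get `sem = 0`.
#'
#' @param x A `trajectory_ensemble`, `deterministic_solution` or
#'   `master_solution`.
#' @param path Output file.
#' @param seed Seed to record in the provenance header (if any).
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(x, path, seed = x$seed) {
  if (is.null(seed)) seed <- NA
  header <- provenance_header(list(
    type = "kinetics", class = class(x)[1L], N = x$N,
    V = if (!is.null(x$V)) x$V else NA,
    n_repeats = if (!is.null(x$n_repeats)) x$n_repeats else NA,
    seed = seed))
  write_csv_with_header(kinetics_frame(x), path, header)
  invisible(path)
}

#' Read per-size kinetics from CSV
#'
#' @param path File written by [write_kinetics()].
#' @return List with `times`, matrices `mean` and `sem` (time x size), and
#'   the provenance metadata.
#' @export
read_kinetics <- function(path) {
  all_lines <- readLines(path)
  meta <- parse_header(grep("^#", all_lines, value = TRUE))
  df <- utils::read.csv(text = all_lines[!grepl("^#", all_lines)])
  times <- sort(unique(df$time))
  N <- max(df$size)
  shape <- function(col) {
    m <- matrix(NA_real_, length(times), N)
    m[cbind(match(df$time, times), df$size)] <- col
    m
  }
  list(times = times, mean = shape(df$mean), sem = shape(df$sem), meta = meta)
}

#' Write a fit result to JSON
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    tool = paste0("aggkin ", aggkin_version()),
    family = fit$family,
    params = as.list(fit$params),
    stderr = as.list(fit$stderr),
    fixed = as.list(fit$fixed),
    chi2 = fit$chi2, nu = fit$nu, chi2_reduced = fit$chi2_reduced,
    converged = fit$converged, n_obs = fit$n_obs, m_params = fit$m_params,
    weighting = fit$weighting, N = fit$N, V = fit$V, times = fit$times)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fit result from JSON
#' @param path File written by [write_fit_json()].
#' @return A `fit_result`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family = x$family, params = unlist(x$params),
                 stderr = unlist(x$stderr), fixed = unlist(x$fixed),
                 chi2 = x$chi2, nu = x$nu, chi2_reduced = x$chi2_reduced,
                 converged = x$converged, n_obs = x$n_obs,
                 m_params = x$m_params, weighting = x$weighting,
                 N = x$N, V = x$V, times = x$times, trace = NULL),
            class = "fit_result")
}

#' Read a kernel configuration file
#'
#' YAML or JSON with fields `family`, `k_f` and optionally `k_b`, `q`, `N`,
#' `V`.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return List with `family`, `params`, and optional `N`, `V`.
#' @export
read_kernel_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$family)) stop("kernel config lacks 'family'", call. = FALSE)
  params <- cfg[intersect(c("k_f", "k_b", "q"), names(cfg))]
  list(family = cfg$family, params = params, N = cfg$N, V = cfg$V)
}

#' Write a kernel configuration file
#' @param config List with `family`, `params` and optional `N`, `V` (or a
#'   `kernel_model`).
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_kernel_config <- function(config, path) {
  if (inherits(config, "kernel_model")) {
    config <- list(family = config$name, params = config$params,
                   N = config$max_size)
  }
  flat <- c(list(family = config$family), config$params,
            list(N = config$N, V = config$V))
  flat <- flat[!vapply(flat, is.null, logical(1))]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}
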