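#' Derive a reproducible sub-stream seed
#'
#' Deterministic counter-based derivation of per-subject (or per-stage) seeds
#' from a single master seed, so that cohorts are reproducible and subject
#' streams do not overlap by construction of distinct counters.
#'
#' @param master_seed Integer master seed.
#' @param ... Integers or strings identifying the stream (e.g. group label,
#'   subject index, condition).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "old", 3, "AP")
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  m <- 2147483647 # 2^31 - 1, Lehmer modulus; keeps arithmetic exact in doubles
  h <- as.double(master_seed) %% m
  for (x in list(...)) {
    v <- if (is.character(x)) {
      codes <- utf8ToInt(x)
      sum(codes * seq_along(codes))
    } else {
      as.double(x)
    }
    h <- (h * 48271 + v + 1) %% m
  }
  as.integer(h)
}

# FNV-style rolling hash of a config object; stable across sessions, used to
# stamp output tables so runs can be matched to their configuration.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared validators -----------------------------------------------------------

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      (positive && x < 1) || (!positive && x < 0)) {
    stop(sprintf("`%s` must be a %s integer, got: %s", name,
                 if (positive) "positive" else "non-negative",
                 paste(x, collapse = ", ")), call. = FALSE)
  }
  as.integer(x)
}

assert_symmetric <- function(m, tol = 1e-12, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be square", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` is not symmetric (tolerance %g)", name, tol),
         call. = FALSE)
  }
  invisible(m)
}
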