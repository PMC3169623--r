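# Internal helpers: RNG scoping, seed derivation, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded routines do not disturb
#' the caller's RNG stream. A \code{NULL} seed leaves the stream untouched.
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic stream of sub-seeds from a master seed, kept < 2^31 so they
# are valid R integer seeds. Lehmer-style multiplicative congruence.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  as.integer((s * 48271 + as.numeric(i) * 69621 + 1) %% m)
}

# Lower-triangle pair indices (i > j) for an n x n symmetric matrix, in the
# same order as stats::dist / lower.tri.
pair_indices <- function(n) {
  jj <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ii <- unlist(lapply(seq_len(n - 1L), function(j) (j + 1L):n), use.names = FALSE)
  list(i = ii, j = jj)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
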