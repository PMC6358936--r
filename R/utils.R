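#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, then
#' restores the caller's RNG state so that seeded simulations never disturb
#' the global random stream. With `seed = NULL` the expression runs against
#' the current stream unchanged.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed, so that
# independent simulation components consume independent streams.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) {
    return(rep(list(NULL), k))
  }
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

assert_fs <- function(hz) {
  if (!is.numeric(hz) || length(hz) != 1L || !is.finite(hz) || hz <= 0) {
    stop("sampling rate `fs` must be a single positive finite number", call. = FALSE)
  }
  as.numeric(hz)
}

# Sample standard deviation (n - 1 denominator), with the package-wide
# convention that a single observation has sd 0 (not NA).
sd0 <- function(x) {
  if (length(x) <= 1L) return(0)
  stats::sd(x)
}

# Number of samples in a span of `seconds` at rate `fs`, guarded against
# representation error (5 * 10.2 must give 51, not 50).
samples_in <- function(seconds, fs) {
  as.integer(floor(seconds * fs + 1e-9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
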