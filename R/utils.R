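# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with a local, restored RNG state seeded at `seed`.
# All stochastic operations in the package go through this so that a
# caller-supplied seed fully determines the result without clobbering
# the global RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-stream seed for a named stage, kept inside 32-bit
# integer range. Different labels give different, reproducible streams
# from one master seed, so toggling one stage never perturbs another.
#' @noRd
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% (.Machine$integer.max - 1)) + 1L
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Sample standard deviation z-score with the zero-variance convention:
# a constant vector maps to all zeros rather than NaN.
#' @noRd
zscore <- function(x) {
  if (all(is.na(x))) return(x)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

# All permutations of 1..n as a list (n! entries); used by the exhaustive
# permutation null for small dendrograms.
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}
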