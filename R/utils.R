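# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed; each stage
#' (simulation, bootstrap replicate, restart, ...) draws its own sub-seed
#' deterministically so stages can be re-run in isolation.  The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed non-negative integer root seed.
#' @param salt integer stage/replicate index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(salt), length(salt) == 1L)
  # affine mixing mod the Mersenne prime 2^31 - 1; doubles hold these exactly
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(salt) * 104729 + 1
  as.integer(s %% 2147483647)
}

# stopifnot() with a readable message
abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
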