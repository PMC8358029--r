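#' Derive a child seed from a master seed
#'
#' A single master seed fans out to per-stage child seeds so that pipeline
#' stages are independently reproducible: re-running one stage with its child
#' seed gives the same stream as running the whole pipeline.  The map is a
#' fixed affine hash into the positive 31-bit integers (R's `set.seed` range).
#'
#' @param seed Master seed (single integer).
#' @param index Non-negative stage counter.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m)
  ## two rounds of a multiplicative congruential step keep child streams
  ## well separated for adjacent (seed, index) pairs
  x <- (x * 48271 + index + 1) %% m
  x <- (x * 69621 + 11) %% m
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

NUCS <- c("A", "C", "G", "T")
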