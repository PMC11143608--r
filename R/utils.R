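# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the R random-number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded simulation never disturbs the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic derived seed (Lehmer-style mix), kept within 32-bit range.
derive_seed <- function(seed, index) {
  s <- abs(as.double(seed)) %% 2147483647
  as.integer((s * 48271 + 104729 * abs(as.double(index))) %% 2147483647)
}
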