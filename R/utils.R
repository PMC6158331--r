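# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions taking an
#' explicit `seed` argument never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' A single run seed fans out to reproducible per-stage / per-block seeds.
#' Kept below 2^31 so the result is a valid R integer.
#' @noRd
derive_seed <- function(seed, stage) {
  # deterministic integer hash of (seed, stage label)
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
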