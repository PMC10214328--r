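# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

#' Derive a per-day (or per-stage) seed from a master seed
#'
#' Deterministic integer hash of `(seed, date)` so each simulated day is
#' independently reproducible. Arithmetic stays below 2^53 so the double
#' computation is exact; the result is always in \[0, 2^31).
#'
#' @param seed master integer seed.
#' @param date a `Date` (or anything coercible); alternatively an integer
#'   stage offset.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, date) {
  key <- if (inherits(date, "Date") || is.character(date)) {
    as.numeric(as.Date(date))
  } else {
    as.numeric(date)
  }
  s <- (as.numeric(seed) %% 1000003) * 69069 + (key %% 1000003) * 7919 + 12345
  as.integer(s %% 2147483647)
}

# stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_date_scalar <- function(x) inherits(x, "Date") && length(x) == 1L && !is.na(x)

as_date1 <- function(x) {
  d <- as.Date(x)
  if (length(d) != 1L || is.na(d)) abort("expected a single valid date, got '%s'", paste(x, collapse = ","))
  d
}
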