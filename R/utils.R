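# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Greatest common divisor of a vector of nonnegative integers.
#' @noRd
vec_gcd <- function(x) {
  g2 <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }
  x <- abs(x[x != 0])
  if (length(x) == 0) return(1)
  Reduce(g2, x)
}

# case-insensitive, whitespace-trimmed identifier normalisation used by
# mapping-table and data-mapping matching (strict mode skips it)
norm_id <- function(x, strict = FALSE) {
  x <- trimws(as.character(x))
  if (strict) x else tolower(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
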