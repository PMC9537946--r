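#' @keywords internal
"_PACKAGE"

## NULL coalescing, used throughout config handling
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## Derive a 32-bit-safe stage seed from a master seed and a stream name, so
## that toggling one analysis off does not shift another analysis' random
## numbers.  Cheap string hash (polynomial, mod a prime below 2^31).
derive_seed <- function(master_seed, stream) {
  stopifnot(is_count(master_seed + 1))  # allow 0
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483587
  as.integer((master_seed %% 2147483587 + h) %% 2147483587)
}

## Run expr with a local RNG state seeded from `seed`; restores global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop_("a seed is required (reproducibility contract)")
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

## Population (n-denominator) and sample (n-1) standardisation helpers.
zscore <- function(x, population = FALSE) {
  n <- length(x)
  s <- if (population) sqrt(sum((x - mean(x))^2) / n) else stats::sd(x)
  if (!is.finite(s) || s == 0) stop_("standardization undefined: zero variance")
  (x - mean(x)) / s
}
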