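# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded stages (Delta calibration, simulation) do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Each pipeline stage consumes its own deterministic seed so that stages can
#' be re-run independently. Values stay below 2^31 - 1.
#' @noRd
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  offs <- c(simulate = 11L, sampling = 23L, calibrate = 37L,
            cascade = 53L, sibship = 71L, estimate = 89L)
  off <- offs[[stream]]
  as.integer((as.numeric(seed) * 977L + off * 9973L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Treat NA-tolerant equality: TRUE only when both known and equal.
known_equal <- function(a, b) !is.na(a) & !is.na(b) & a == b

# TRUE when the pair is compatible: unknown values pass the filter.
compatible_or_unknown <- function(a, b) is.na(a) | is.na(b) | a == b
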