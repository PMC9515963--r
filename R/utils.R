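## Internal helpers shared across modules.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores `.Random.seed` so randomized operations never leak
#' global random state. Every randomized function in the package routes its
#' draws through this helper with an explicit caller-supplied seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

## Derive a stream-specific seed from a master seed; keeps derived seeds
## inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with sprintf-style formatting, without the call in the message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

GRAM_LEVELS   <- c("GramPos", "GramNeg", "Various", "Unknown")
OXYGEN_LEVELS <- c("Anaerobe", "NonAnaerobe", "Various", "Unknown")
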