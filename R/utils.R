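#' Derive a child seed from a global seed and a stream name
#'
#' Every stochastic component of the package draws its own child seed from the
#' user's single global seed plus a fixed stream label. Adding a new generator
#' therefore never shifts the random streams of existing ones. The rule is
#' `(seed + 10007 * hash(name)) mod (2^31 - 1)` with `hash` the sum of the
#' UTF-8 code points of the label.
#'
#' @param seed integer global seed.
#' @param stream character stream label, e.g. `"weather"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream))
  as.integer((as.numeric(seed) + 10007 * h) %% (2^31 - 1))
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so package internals never disturb the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stop() with a classed condition so callers can test error types
edfm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "edfm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable softmax
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Xavier-uniform random array
#'
#' @param dim integer dimensions.
#' @param fan_in,fan_out fan counts used for the uniform limit
#'   `sqrt(6 / (fan_in + fan_out))`.
#' @return Array of the requested dimension.
#' @keywords internal
xavier_uniform <- function(dim, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}
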