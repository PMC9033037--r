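#' Round half away from zero
#'
#' Deterministic half-up rounding, used for all reported percentages so that
#' e.g. 35/234 genes prints as 14.96. Base [round()] applies banker's
#' rounding (round-half-even), which disagrees with the convention used for
#' the published summary tables on exact halves.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' roundHalfUp(100 * 35 / 234, 2) # 14.96
#' roundHalfUp(0.125, 2)          # 0.13 (round() would give 0.12)
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All randomness in the package flows through this helper so that a single
## seed in a config makes a run bit-reproducible.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Structured log line, gated by level ("quiet" < "info" < "debug").
pipeLog <- function(level, stage, ..., logLevel = "info") {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[logLevel %||% "info"]] >= ranks[[level]]) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
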