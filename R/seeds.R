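#' Derive a deterministic child seed for a named pipeline component
#'
#' One global seed is expanded into per-component seeds so that any stage can
#' be regenerated independently of the others. The derivation is a documented
#' integer hash: starting from `seed mod (2^31 - 1)`, the UTF-8 code of each
#' character of `component` is folded in as `h <- (31 * h + code) mod
#' (2^31 - 1)`. The result is a strictly positive integer below 2^31, safe
#' for [set.seed()] on every platform.
#'
#' @param seed Integer scalar, the global seed.
#' @param component Character scalar naming the component (e.g.
#'   `"expression"`, `"library"`).
#' @return A positive integer scalar.
#' @examples
#' child_seed(1, "expression")
#' child_seed(1, "library")
#' @export
child_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(component), length(component) == 1L)
  m <- 2147483647 # 2^31 - 1, kept in double arithmetic (exact below 2^53)
  h <- abs(as.double(seed)) %% m
  for (code in utf8ToInt(component)) h <- (31 * h + code) %% m
  as.integer(h %% (m - 2) + 1)
}

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
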