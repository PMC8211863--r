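#' Derive a stage-specific RNG seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from a single
#' master seed plus a stage label, so that re-running any stage (or the whole
#' pipeline) with the same master seed is bit-reproducible while stages stay
#' decoupled from each other's stream consumption.
#'
#' @param seed master integer seed
#' @param stage character label of the stage
#' @return an integer seed in [1, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h
  as.integer(s %% 2147483646 + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package version string used in output file headers
#' @keywords internal
tiilnc_version <- function() {
  as.character(utils::packageVersion("tiilnc"))
}
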