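# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding with ties resolved away from zero (so 0.5 -> 1 and
#' -0.5 -> -1), the convention used when tabulating helix percentages.
#' Base `round()` uses round-half-to-even, which is unsuitable for
#' reproducing printed tables.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with a classed condition so callers/tests can distinguish error kinds
ps_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pepstruct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ps_warn <- function(msg, class = "pepstruct_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
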