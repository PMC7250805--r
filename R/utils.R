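#' Round half away from zero
#'
#' Standard commercial rounding: ties at .5 move away from zero rather than to
#' the even digit (which is what [base::round()] does). Required so the hidden
#' node heuristics reproduce the reference architecture table for every
#' superset size.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Truncate to a fixed number of decimal places
#'
#' Truncation (toward zero), not rounding: 1/6 truncated to three decimals is
#' 0.166. Used when reporting the mapping probability tau, which is
#' conventionally quoted truncated.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector.
#' @examples
#' truncate_decimal(1 / 3, 2) # 0.33
#' truncate_decimal(1 / 6, 3) # 0.166
#' @export
truncate_decimal <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a local RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
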