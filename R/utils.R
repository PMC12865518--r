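#' Round half away from zero
#'
#' Base \code{round()} rounds half to even ("banker's rounding"); published
#' clinical tables round half up. A tiny epsilon guards against values such
#' as 0.8349999999 that are exactly representable a hair below a half.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format a proportion as a percentage string at 1 decimal, half-up
#' @param p proportion in [0, 1] (NA allowed).
#' @param digits decimal places (default 1).
#' @return character vector.
#' @export
fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA",
         formatC(round_half_up(100 * p, digits), format = "f", digits = digits))
}

# Evaluate `expr` under a private RNG stream; the caller's global RNG state
# is untouched. All stochastic package code routes through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
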