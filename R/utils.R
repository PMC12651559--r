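#' @importFrom stats density dnbinom dpois dt lm loess mad median optimize
#'   p.adjust pnorm predict qnorm rbinom rnbinom rnorm rpois runif rstudent
#'   sd coef qt setNames var weighted.mean
#' @importFrom utils head read.table tail write.table
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x <= 1 && (if (open_left) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single value in %s", name,
                 if (open_left) "(0, 1]" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

# Circular helpers: coordinates are 0-based, in [0, length).
wrap_coord <- function(x, length) ((x %% length) + length) %% length

circ_dist <- function(a, b, length) {
  d <- abs(wrap_coord(a, length) - wrap_coord(b, length))
  pmin(d, length - d)
}
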