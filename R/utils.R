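# Internal helpers shared across modules.

#' Wrap angles into [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Circular root-mean-square difference between two phase series
#'
#' Differences are wrapped into `[-pi, pi)` before squaring, so a constant
#' offset of `2*pi` counts as zero error.
#'
#' @param a,b numeric vectors of phases in radians (same length).
#' @param na.rm drop positions where either input is `NA`.
#' @return circular RMS difference in radians.
#' @export
circular_rms <- function(a, b, na.rm = TRUE) {
  stopifnot(length(a) == length(b))
  d <- wrap_angle(a - b)
  sqrt(mean(d^2, na.rm = na.rm))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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

# stopifnot() with a formatted message.
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
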