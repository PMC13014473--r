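#' @keywords internal
"_PACKAGE"

## Numerically stable log(exp(x) + exp(y)), vectorized over both arguments.
## Both -Inf yields -Inf (not NaN).
logaddexp <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(-abs(x - y)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## log(sum(exp(x))) for a vector, -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

## Round half away from zero -- the convention used when printing scores,
## so that e.g. 9.625 prints as 9.63 rather than IEEE round-half-even 9.62.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Structured condition helper: all package errors carry a subclass so that
## callers (and tests) can dispatch on the failure mode.
squigseg_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "squigseg_error")))
}

## Median absolute deviation WITHOUT the 1.4826 normal-consistency factor.
## Used consistently for signal normalization and the border-contrast metric.
raw_mad <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
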