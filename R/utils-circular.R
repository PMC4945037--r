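# Circular helpers.  All phases are in cycles; [0,1) for positions on the
# circle, (-0.5, 0.5] for signed differences.

#' Wrap a phase to the unit circle
#'
#' @param x numeric, phase in cycles.
#' @return `x` modulo 1, in `[0, 1)`.
#' @export
wrap_phase <- function(x) x - floor(x)

#' Wrap a phase difference to a signed half cycle
#'
#' @param x numeric, phase difference in cycles.
#' @return `x` mapped to `(-0.5, 0.5]`.
#' @export
wrap_signed <- function(x) {
  y <- x - round(x)
  y[y == -0.5] <- 0.5
  y
}

#' Circular mean of phases
#' @param x phases in cycles.
#' @param positive return in `[0, 1)` instead of `(-0.5, 0.5]`.
#' @export
circ_mean <- function(x, positive = FALSE) {
  z <- mean(exp(2i * pi * x))
  m <- Arg(z) / (2 * pi)
  if (positive) wrap_phase(m) else wrap_signed(m)
}

#' Wrapped-normal circular dispersion
#'
#' `sqrt(-2 log R)` of the mean resultant length `R`, in cycles: the maximum
#' likelihood dispersion of a wrapped normal distribution.
#' @param x phases in cycles.
#' @export
circ_sd <- function(x) {
  r <- Mod(mean(exp(2i * pi * x)))
  if (r <= 0) return(Inf)
  sqrt(pmax(-2 * log(r), 0)) / (2 * pi)
}

#' Circular correlation of two phase series
#'
#' Fisher & Lee (1983) T-linear circular correlation.
#' @param a,b phases in cycles (equal length).
#' @export
circ_corr <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- 2 * pi * a[ok]; b <- 2 * pi * b[ok]
  if (length(a) > 2000) { i <- seq(1, length(a), length.out = 2000)
    a <- a[i]; b <- b[i] }
  sa <- sin(outer(a, a, "-")); sb <- sin(outer(b, b, "-"))
  up <- upper.tri(sa)
  sum(sa[up] * sb[up]) / sqrt(sum(sa[up]^2) * sum(sb[up]^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
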