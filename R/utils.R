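# Internal numeric helpers shared across modules.

# Population (divide-by-N) standard deviation. Used consistently for every
# z-transformation in the pipeline, including the PAGE denominator.
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

scale_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
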