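# internal helpers shared across modules

expit <- function(x) 1 / (1 + exp(-x))

# inverse-CDF sampler for a truncated normal: deterministic in u, which keeps
# common-random-number coupling between observational and perfect datasets
qtruncnorm <- function(u, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a message assembled from sprintf-style parts
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

first_or <- function(x, default) if (length(x)) x[[1L]] else default
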