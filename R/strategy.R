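#' Static deterministic treatment strategies
#'
#' A strategy is a fixed treatment sequence \eqn{\bar a_0 = (a_0, a_1, \ldots)}
#' that does not respond to evolving covariates. It is represented by a finite
#' 0/1 vector whose last element repeats indefinitely, so "never treated" is
#' `strategy(0, "never")` and "always treated" is `strategy(1, "always")`.
#'
#' @param sequence a vector of 0/1 treatment values; the last value repeats
#'   for visits beyond its length.
#' @param label a short text label used to match predictions.
#' @return an object of class `cf_strategy`.
#' @examples
#' s <- strategy(c(0, 1), "start-at-1")
#' strategy_actions(s, 0:4)  # 0 1 1 1 1
#' @export
strategy <- function(sequence, label) {
  sequence <- as.numeric(sequence)
  if (!length(sequence) || !all(sequence %in% c(0, 1)))
    abort_fmt("strategy sequence must be a non-empty vector of 0/1 values")
  structure(list(label = as.character(label), sequence = sequence),
            class = "cf_strategy")
}

#' @rdname strategy
#' @export
never_treated <- function() strategy(0, "never")

#' @rdname strategy
#' @export
always_treated <- function() strategy(1, "always")

#' @rdname strategy
#' @param x a `cf_strategy`.
#' @param k vector of non-negative visit indices.
#' @return `strategy_actions`: the treatment values \eqn{a_k} at visits `k`.
#' @export
strategy_actions <- function(x, k) {
  stopifnot(inherits(x, "cf_strategy"), all(k >= 0))
  x$sequence[pmin(k + 1, length(x$sequence))]
}

#' @export
print.cf_strategy <- function(x, ...) {
  cat(sprintf("<cf_strategy '%s'> sequence: %s, last value repeats\n",
              x$label, paste(x$sequence, collapse = " ")))
  invisible(x)
}
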