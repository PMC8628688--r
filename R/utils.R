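#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median sd quantile rnorm runif rpois rbeta rbinom
#'   setNames wilcox.test cor predict glm binomial plogis complete.cases
#' @importFrom utils head
NULL

# Internal: stop with a classed condition so callers/tests can target it.
stop_nucleograde <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "nucleograde_error"), ...)
}

# Internal: derive a bounded 32-bit substream seed from a base seed and a
# counter, so that entity i's draws do not depend on how many entities
# precede it. Plain multiplicative hash; collisions are astronomically
# unlikely at cohort scale.
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(counter) * 69621) %% 2147483647
  as.integer(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

assert_probability <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_nucleograde(
      sprintf("`%s` must contain probabilities in [0, 1].", what),
      "nucleograde_parameter_error"
    )
  }
  invisible(x)
}
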