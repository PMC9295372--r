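# internal helpers shared across modules

logsig <- function(z) 1 / (1 + exp(-z))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# linear trapezoid; x must be increasing
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shallow merge of a named override list onto defaults, dropping NULLs
merge_config <- function(defaults, override) {
  if (is.null(override) || !length(override)) return(defaults)
  stopifnot(is.list(override))
  utils::modifyList(defaults, override)
}

assert_increasing <- function(times) {
  if (length(times) >= 2L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}
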