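# internal argument checks shared by the flux laws and constructors

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(sprintf("`%s` must be non-negative and finite", what), call. = FALSE)
  invisible(x)
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop(sprintf("`%s` must be strictly positive", what), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
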