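## Internal argument checks shared across the package.

check_xi <- function(xi, arg = "xi") {
  if (!is.numeric(xi) || length(xi) < 1L || anyNA(xi) ||
      any(!is.finite(xi)) || any(xi <= 0)) {
    stop("`", arg, "` must be positive and finite.", call. = FALSE)
  }
  invisible(xi)
}

check_nonneg <- function(z, arg = "x") {
  if (!is.numeric(z) || anyNA(z) || any(z < 0)) {
    stop("`", arg, "` must be non-negative (support is [0, Inf)).",
         call. = FALSE)
  }
  invisible(z)
}

## Extract a validated positive sample from a numeric vector or a data frame
## (first numeric column, or a column named `value` if present).
as_sample <- function(x, min_n = 2L, arg = "x") {
  if (is.data.frame(x)) {
    if ("value" %in% names(x)) {
      x <- x[["value"]]
    } else {
      num <- vapply(x, is.numeric, logical(1))
      if (!any(num)) stop("`", arg, "` has no numeric column.", call. = FALSE)
      x <- x[[which(num)[1L]]]
    }
  }
  if (!is.numeric(x)) stop("`", arg, "` must be numeric.", call. = FALSE)
  x <- as.double(x)
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", arg, "` must contain strictly positive finite values.",
         call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("`", arg, "` needs at least ", min_n, " observations.", call. = FALSE)
  }
  x
}
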