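#' Truncation control for series evaluations
#'
#' The analytic summaries in this package are computed by adaptive
#' quadrature; an independent route evaluates them as double sums obtained
#' by expanding the exponentiated baseline CDF,
#' \eqn{e^{-c(z)} = \sum_l (-1)^l c(z)^l / l!} with
#' \eqn{c(z) = (1 + \xi z/(1+\xi)) e^{-\xi z}}, followed by a binomial
#' expansion of \eqn{c(z)^l}. `series_control()` bounds those sums.
#'
#' The outer sum alternates in sign, so for large `xi` (roughly
#' \eqn{\xi \gtrsim 10}) double-precision cancellation degrades the series
#' route; quadrature remains the source of truth and the series is a
#' cross-check only.
#'
#' @param max_terms maximum outer index `l` (and inner indices bounded by
#'   it); at least 1.
#' @param tol relative magnitude at which the outer term is deemed
#'   negligible and summation stops; in (0, 1).
#' @return a list of class `"series_control"`.
#' @export
series_control <- function(max_terms = 60L, tol = 1e-12) {
  if (!is.numeric(max_terms) || length(max_terms) != 1L || max_terms < 1) {
    stop("`max_terms` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol >= 1) {
    stop("`tol` must lie in (0, 1).", call. = FALSE)
  }
  structure(list(max_terms = as.integer(max_terms), tol = tol),
            class = "series_control")
}

## exp(a) * Gamma(s, a * z) / a^s computed stably in log space; with z = 0
## this is exp(a) * Gamma(s) / a^s.  `lower` selects the lower incomplete
## gamma instead.  Returns the value WITHOUT the exp(a) factor when
## shift = 0 (shift is the additive log offset, usually 0 here).
log_incgamma_over_pow <- function(s, a, z, lower = FALSE) {
  if (z <= 0) {
    if (lower) return(-Inf)
    return(lgamma(s) - s * log(a))
  }
  lgamma(s) + pgamma(a * z, s, lower.tail = lower, log.p = TRUE) - s * log(a)
}

## Partial raw moment of the DUS Lindley law by series:
##   upper: integral over (z, Inf) of w^r g(w) dw
##   lower: integral over (0, z)  of w^r g(w) dw
## Derivation: g = e/(e-1) f(z) e^{-c(z)}; expand e^{-c} in powers of c,
## c^l = sum_m C(l,m) (xi/(1+xi))^m z^m e^{-l xi z}; the (1+z) factor of f
## splits each term into two gamma integrals with rate a = (l+1) xi.
## Returns list(value, converged, terms).
dus_partial_moment_series <- function(r, xi, z = 0, tail = c("upper", "lower"),
                                      control = series_control()) {
  tail <- match.arg(tail)
  lower <- tail == "lower"
  lpref <- 1 - log(.E - 1) + 2 * log(xi) - log1p(xi)
  lratio <- log(xi) - log1p(xi)    # log(xi/(1+xi))
  S <- 0
  converged <- FALSE
  l_used <- control$max_terms
  for (l in 0:control$max_terms) {
    a <- (l + 1) * xi
    m <- 0:l
    lcoef <- lchoose(l, m) + m * lratio - lgamma(l + 1)
    t1 <- exp(lcoef + vapply(m, function(mm)
      log_incgamma_over_pow(r + mm + 1, a, z, lower), numeric(1)))
    t2 <- exp(lcoef + vapply(m, function(mm)
      log_incgamma_over_pow(r + mm + 2, a, z, lower), numeric(1)))
    term <- (-1)^l * sum(t1 + t2)
    S <- S + term
    if (l >= 4L && abs(term) <= control$tol * abs(S)) {
      converged <- TRUE
      l_used <- l
      break
    }
  }
  list(value = exp(lpref) * S, converged = converged, terms = l_used)
}

## integral over (0, Inf) of g(z)^s dz by series, s > 0.  Uses the same
## expansion of e^{-s c(z)} plus (1+z)^s written, after u = 1+z, as a
## finite binomial sum in upper incomplete gammas of non-integer order.
dus_entropy_integral_series <- function(s, xi, control = series_control()) {
  lpref <- s * (1 - log(.E - 1) + 2 * log(xi) - log1p(xi))
  lratio <- log(xi) - log1p(xi)
  Ims <- function(m, b) {
    ## integral over (0, Inf) of z^m (1+z)^s e^{-b z} dz
    k <- 0:m
    sgn <- (-1)^(m - k)
    lv <- lchoose(m, k) + b + lgamma(k + s + 1) +
      pgamma(b, k + s + 1, lower.tail = FALSE, log.p = TRUE) -
      (k + s + 1) * log(b)
    sum(sgn * exp(lv))
  }
  S <- 0
  converged <- FALSE
  for (l in 0:control$max_terms) {
    b <- (l + s) * xi
    m <- 0:l
    inner <- sum(exp(lchoose(l, m) + m * lratio) *
                   vapply(m, Ims, numeric(1), b = b))
    term <- (-1)^l * exp(l * log(s) - lgamma(l + 1)) * inner
    S <- S + term
    if (l >= 4L && abs(term) <= control$tol * abs(S)) {
      converged <- TRUE
      break
    }
  }
  list(value = exp(lpref) * S, converged = converged)
}
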