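#' Lambert W function, branch -1
#'
#' Vectorised evaluation of the lower real branch \eqn{W_{-1}} on
#' \eqn{(-1/e, 0)}, used to invert the Lindley distribution function in
#' closed form. Halley iteration from a branch-point / asymptotic initial
#' guess; converges to machine precision in a handful of steps.
#'
#' @param x numeric vector in \eqn{(-1/e, 0)}.
#' @return numeric vector `w` with `w * exp(w) == x` and `w <= -1`.
#' @keywords internal
#' @noRd
lambert_wm1 <- function(x) {
  if (any(x <= -exp(-1) - 1e-300 | x >= 0)) {
    bad <- x[x <= -exp(-1) - 1e-300 | x >= 0]
    ## allow tiny numeric undershoot of the branch point
    if (any(bad < -exp(-1) * (1 + 1e-12) | bad >= 0)) {
      stop("lambert_wm1() requires x in (-1/e, 0).", call. = FALSE)
    }
    x <- pmax(x, -exp(-1))
  }
  ## initial guess: series in p = -sqrt(2(1 + e x)) near the branch point,
  ## L1 - L2 + L2/L1 asymptotics as x -> 0-
  p <- -sqrt(pmax(0, 2 * (1 + exp(1) * x)))
  w_branch <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  L1 <- log(-x)
  L2 <- log(-L1)
  w <- ifelse(x > -0.27, L1 - L2 + L2 / L1, w_branch)
  for (i in seq_len(50L)) {
    ew <- exp(w)
    f <- w * ew - x
    wn <- w - f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    if (all(abs(wn - w) <= 1e-15 * abs(wn))) {
      w <- wn
      break
    }
    w <- wn
  }
  w
}
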