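## Analytic summaries of the DUS Lindley law.  Adaptive quadrature
## (stats::integrate on the half line) is the primary route everywhere;
## the series forms in series.R are an independent cross-check.

quad <- function(f, lower, upper, rel.tol = 1e-10, ...) {
  stats::integrate(f, lower, upper, rel.tol = rel.tol,
                   subdivisions = 400L, ...)$value
}

#' Raw moments of the DUS Lindley distribution
#'
#' \eqn{\mu'_r = E(Z^r)} for integer order `r >= 1`, by adaptive
#' quadrature of \eqn{z^r g(z)} (`method = "quadrature"`, the default) or
#' by the exponential-series expansion of the density
#' (`method = "series"`). The two routes agree to at least
#' `max(1e-6, 1e-4 * mu_r)` for moderate `xi`; a warning carrying both
#' values is raised when the truncated series has not met `control$tol`
#' within `control$max_terms` outer terms.
#'
#' @param xi positive shape parameter.
#' @param r positive integer moment order (vectorised).
#' @param method `"quadrature"` or `"series"`.
#' @param control a [series_control()] object (series route only).
#' @return numeric vector of raw moments, one per element of `r`.
#' @examples
#' dus_moment(xi = 2, r = 1:2)
#' @export
dus_moment <- function(xi, r = 1L, method = c("quadrature", "series"),
                       control = series_control()) {
  check_xi(xi)
  method <- match.arg(method)
  if (any(r < 1) || any(r != round(r))) {
    stop("`r` must be a positive integer.", call. = FALSE)
  }
  vapply(r, function(rr) {
    if (method == "quadrature") {
      quad(function(z) z^rr * ddus(z, xi), 0, Inf)
    } else {
      res <- dus_partial_moment_series(rr, xi, control = control)
      if (!res$converged) {
        warning("series for moment r = ", rr, " not converged at max_terms; ",
                "series value ", format(res$value), ", quadrature value ",
                format(quad(function(z) z^rr * ddus(z, xi), 0, Inf)),
                call. = FALSE)
      }
      res$value
    }
  }, numeric(1))
}

#' Mean, variance, skewness and kurtosis of the DUS Lindley distribution
#'
#' Central summaries assembled from the first four raw moments. Skewness
#' is \eqn{m_3/m_2^{3/2}} and kurtosis the non-excess ratio
#' \eqn{m_4/m_2^2} (so the normal law has kurtosis 3), matching the
#' conventions used by [descriptive_stats()] for data.
#'
#' @inheritParams dus_moment
#' @return a one-row tibble with columns `mean`, `variance`, `skewness`,
#'   `kurtosis`.
#' @export
dus_stats <- function(xi, method = c("quadrature", "series"),
                      control = series_control()) {
  method <- match.arg(method)
  mu <- dus_moment(xi, 1:4, method = method, control = control)
  m2 <- mu[2] - mu[1]^2
  m3 <- mu[3] - 3 * mu[1] * mu[2] + 2 * mu[1]^3
  m4 <- mu[4] - 4 * mu[1] * mu[3] + 6 * mu[1]^2 * mu[2] - 3 * mu[1]^4
  tibble::tibble(mean = mu[1], variance = m2,
                 skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Conditional moments of the DUS Lindley distribution
#'
#' \eqn{E(Z^r \mid Z > t)}, the r-th moment of the residual distribution,
#' by quadrature on \eqn{(t, \infty)} divided by the survival probability,
#' or by the upper-incomplete-gamma series.
#'
#' @inheritParams dus_moment
#' @param t non-negative conditioning time with `pdus(t, xi) < 1`.
#' @return numeric scalar.
#' @export
dus_conditional_moment <- function(xi, r = 1L, t = 0,
                                   method = c("quadrature", "series"),
                                   control = series_control()) {
  check_xi(xi)
  check_nonneg(t, "t")
  method <- match.arg(method)
  if (length(r) != 1L || r < 1 || r != round(r)) {
    stop("`r` must be a single positive integer.", call. = FALSE)
  }
  S <- pdus(t, xi, lower.tail = FALSE)
  if (S < 1e-12) {
    stop("survival at `t` is below 1e-12; conditioning is degenerate.",
         call. = FALSE)
  }
  num <- if (method == "quadrature") {
    quad(function(z) z^r * ddus(z, xi), t, Inf)
  } else {
    dus_partial_moment_series(r, xi, z = t, tail = "upper",
                              control = control)$value
  }
  num / S
}

#' Mean residual life and mean past life
#'
#' `dus_mrl()` is the expected remaining lifetime \eqn{E(T - t \mid T > t)}
#' and `dus_mpl()` the expected elapsed lifetime \eqn{E(t - T \mid T \le t)}
#' of a DUS Lindley lifetime, by partial-moment quadrature (default) or
#' the incomplete-gamma series route.
#'
#' @inheritParams dus_conditional_moment
#' @param t conditioning time; `dus_mpl` requires `pdus(t, xi) > 0`,
#'   `dus_mrl` requires positive survival (both vectorised over `t`).
#' @return numeric vector.
#' @examples
#' dus_mrl(0, xi = 1)   # equals the mean
#' @export
dus_mrl <- function(t, xi, method = c("quadrature", "series"),
                    control = series_control()) {
  check_xi(xi)
  check_nonneg(t, "t")
  method <- match.arg(method)
  vapply(t, function(tt) {
    dus_conditional_moment(xi, 1L, tt, method = method, control = control) - tt
  }, numeric(1))
}

#' @rdname dus_mrl
#' @export
dus_mpl <- function(t, xi, method = c("quadrature", "series"),
                    control = series_control()) {
  check_xi(xi)
  method <- match.arg(method)
  if (any(t <= 0)) stop("`t` must be positive for the mean past life.",
                        call. = FALSE)
  vapply(t, function(tt) {
    G <- pdus(tt, xi)
    if (G < 1e-300) stop("pdus(t) is zero; conditioning is degenerate.",
                         call. = FALSE)
    num <- if (method == "quadrature") {
      quad(function(z) z * ddus(z, xi), 0, tt)
    } else {
      dus_partial_moment_series(1L, xi, z = tt, tail = "lower",
                                control = control)$value
    }
    tt - num / G
  }, numeric(1))
}

#' Moment, characteristic and cumulant generating functions
#'
#' Evaluates \eqn{M(t) = E(e^{tZ})}, the characteristic function
#' \eqn{\varphi(t) = E(e^{itZ})} (returned as real and imaginary parts)
#' and the cumulant generating function \eqn{\log M(t)} of the DUS Lindley
#' law by adaptive quadrature. The density has an \eqn{e^{-\xi z}} tail,
#' so `mgf`/`cgf` exist only for `t < xi`; the characteristic function is
#' defined for all real `t`.
#'
#' @param t numeric vector of transform arguments.
#' @param xi positive shape parameter.
#' @return a tibble with columns `t`, `mgf`, `cgf`, `cf_re`, `cf_im`.
#' @examples
#' dus_generating(0, xi = 1)   # mgf 1, cgf 0, cf (1, 0)
#' @export
dus_generating <- function(t, xi) {
  check_xi(xi)
  if (any(t >= xi)) {
    stop("mgf/cgf diverge for t >= xi; use t < xi.", call. = FALSE)
  }
  ## integrand in log space: exp(t z) g(z) can hit Inf * 0 otherwise
  mgf <- vapply(t, function(tt)
    quad(function(z) exp(tt * z + ddus(z, xi, log = TRUE)), 0, Inf),
    numeric(1))
  cf_re <- vapply(t, function(tt)
    quad(function(z) cos(tt * z) * ddus(z, xi), 0, Inf, rel.tol = 1e-9),
    numeric(1))
  cf_im <- vapply(t, function(tt)
    quad(function(z) sin(tt * z) * ddus(z, xi), 0, Inf, rel.tol = 1e-9),
    numeric(1))
  tibble::tibble(t = t, mgf = mgf, cgf = log(mgf),
                 cf_re = cf_re, cf_im = cf_im)
}

#' Order statistics of a DUS Lindley sample
#'
#' Density and distribution function of the r-th order statistic of `n`
#' i.i.d. DUS Lindley draws:
#' \deqn{g_{(r)}(z) = \frac{n!}{(n-r)!(r-1)!} g(z) G(z)^{r-1}
#'       \{1-G(z)\}^{n-r},\qquad
#'       G_{(r)}(z) = \sum_{j=r}^n \binom{n}{j} G^j (1-G)^{n-j},}
#' the latter evaluated as a binomial upper tail via [stats::pbinom()].
#'
#' @inheritParams ddus
#' @param r rank of the order statistic, `1 <= r <= n`.
#' @param n sample size.
#' @return numeric vector.
#' @export
ddus_order <- function(x, xi, r, n) {
  check_xi(xi)
  check_nonneg(x)
  if (r < 1 || r > n || r != round(r) || n != round(n)) {
    stop("`r` must be an integer with 1 <= r <= n.", call. = FALSE)
  }
  G <- pdus(x, xi)
  S <- pdus(x, xi, lower.tail = FALSE)
  exp(lgamma(n + 1) - lgamma(n - r + 1) - lgamma(r) +
        ddus(x, xi, log = TRUE) +
        (r - 1) * log(pmax(G, 1e-300)) + (n - r) * log(pmax(S, 1e-300)))
}

#' @rdname ddus_order
#' @export
pdus_order <- function(x, xi, r, n) {
  check_xi(xi)
  check_nonneg(x)
  if (r < 1 || r > n || r != round(r) || n != round(n)) {
    stop("`r` must be an integer with 1 <= r <= n.", call. = FALSE)
  }
  pbinom(r - 1, n, pdus(x, xi), lower.tail = FALSE)
}

#' Renyi and Tsallis entropies of the DUS Lindley distribution
#'
#' \deqn{\Lambda(\varsigma) = \frac{1}{1-\varsigma}
#'       \log \int_0^\infty g(z)^\varsigma dz, \qquad
#'       \Delta(\vartheta) = \frac{1}{\vartheta-1}
#'       \left(1 - \int_0^\infty g(z)^\vartheta dz\right),}
#' for order \eqn{> 0}, \eqn{\neq 1}. Both converge to the Shannon entropy
#' \eqn{-\int g \log g} as the order approaches 1. Quadrature is primary;
#' `method = "series"` evaluates the same integral by the exponential
#' series expansion as a cross-check.
#'
#' @inheritParams dus_moment
#' @param order entropy order, positive and different from 1.
#' @param kind `"renyi"` or `"tsallis"`.
#' @return numeric scalar.
#' @export
dus_entropy <- function(xi, order, kind = c("renyi", "tsallis"),
                        method = c("quadrature", "series"),
                        control = series_control()) {
  check_xi(xi)
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (length(order) != 1L || order <= 0) {
    stop("`order` must be a positive scalar.", call. = FALSE)
  }
  if (order == 1) {
    stop("order = 1 is the Shannon limit -integral(g log g); ",
         "evaluate at order = 1 +/- eps.", call. = FALSE)
  }
  I <- if (method == "quadrature") {
    quad(function(z) ddus(z, xi)^order, 0, Inf)
  } else {
    dus_entropy_integral_series(order, xi, control = control)$value
  }
  switch(kind,
         renyi = log(I) / (1 - order),
         tsallis = (1 - I) / (order - 1))
}

#' Lorenz and Bonferroni curves of the DUS Lindley distribution
#'
#' Scaled partial expectations against the quantile level:
#' \deqn{L(\eta) = \frac{1}{\mu'_1}\int_0^{\Psi} z\, g(z)\, dz,\qquad
#'       B(\eta) = L(\eta)/\eta,\qquad \Psi = G^{-1}(\eta).}
#'
#' @param eta vector of levels in (0, 1).
#' @param xi positive shape parameter.
#' @return a tibble with columns `eta`, `psi` (the level quantile),
#'   `lorenz`, `bonferroni`.
#' @export
dus_inequality <- function(eta, xi) {
  check_xi(xi)
  if (any(eta <= 0) || any(eta >= 1)) {
    stop("`eta` must lie strictly inside (0, 1).", call. = FALSE)
  }
  mu1 <- dus_moment(xi, 1L)
  psi <- qdus(eta, xi)
  lorenz <- vapply(psi, function(up)
    quad(function(z) z * ddus(z, xi), 0, up) / mu1, numeric(1))
  tibble::tibble(eta = eta, psi = psi, lorenz = lorenz,
                 bonferroni = lorenz / eta)
}
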