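#' Penalised information criteria
#'
#' AIC, corrected AIC, Hannan-Quinn and Bayesian information criteria from
#' a `-2 log L` value, number of parameters `k` and sample size `n`:
#' `aic = m2l + 2k`, `aicc = aic + 2k(k+1)/(n-k-1)`,
#' `hqic = m2l + 2k log(log n)`, `bic = m2l + k log(n)`.
#'
#' @param minus2logl `-2` times the maximised log-likelihood.
#' @param k number of estimated parameters (`k = 0` gives all criteria
#'   equal to `minus2logl`).
#' @param n sample size; must exceed `k + 1` for the AICc correction.
#' @return a one-row tibble with columns `aic`, `aicc`, `hqic`, `bic`.
#' @examples
#' information_criteria(82.9530, k = 1, n = 30)
#' @export
information_criteria <- function(minus2logl, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1.", call. = FALSE)
  aic <- minus2logl + 2 * k
  tibble::tibble(aic = aic,
                 aicc = aic + 2 * k * (k + 1) / (n - k - 1),
                 hqic = minus2logl + 2 * k * log(log(n)),
                 bic = minus2logl + k * log(n))
}

## Asymptotic Kolmogorov tail probability P(sup|B| > lambda).
kolmogorov_pvalue <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' One-sample Kolmogorov-Smirnov statistic against a fitted CDF
#'
#' The supremum distance between the empirical CDF of a sample and a
#' continuous CDF,
#' \eqn{D = \max_i \max\{|i/n - G(z_{(i)})|, |G(z_{(i)}) - (i-1)/n|\}},
#' with a p-value from the asymptotic Kolmogorov distribution evaluated at
#' \eqn{\sqrt{n} D}. The parameters of `cdf` are treated as known, so the
#' p-value is approximate when `cdf` was itself fitted to the data (the
#' usual stock-test convention).
#'
#' @param x positive sample (numeric vector or data frame).
#' @param cdf a vectorised CDF, e.g. `function(q) pdus(q, xi = 1.1188)`.
#' @return a list with elements `statistic` and `p.value`.
#' @examples
#' precip <- load_dataset("precipitation_hinkley")
#' dus_ks_test(precip, function(q) pdus(q, 1.1188))
#' @export
dus_ks_test <- function(x, cdf) {
  x <- as_sample(x, min_n = 1L)
  n <- length(x)
  xs <- sort(x)
  Gi <- cdf(xs)
  i <- seq_len(n)
  stat <- max(pmax(i / n - Gi, Gi - (i - 1) / n))
  list(statistic = stat, p.value = kolmogorov_pvalue(sqrt(n) * stat))
}

#' Descriptive statistics of a positive sample
#'
#' Minimum, quartiles (linear interpolation of order statistics,
#' [stats::quantile()] type 7), mean, maximum, and the population moment
#' ratios: skewness \eqn{m_3/m_2^{3/2}} and non-excess kurtosis
#' \eqn{m_4/m_2^2}, with \eqn{m_j} the central sample moments divided
#' by `n`.
#'
#' @param x positive sample (numeric vector or data frame), at least two
#'   distinct values for the moment ratios.
#' @return a one-row tibble with columns `min`, `q1`, `median`, `mean`,
#'   `q3`, `max`, `skewness`, `kurtosis`.
#' @examples
#' descriptive_stats(load_dataset("precipitation_hinkley"))
#' @export
descriptive_stats <- function(x) {
  x <- as_sample(x)
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("constant sample: skewness/kurtosis undefined.",
                    call. = FALSE)
  tibble::tibble(min = min(x), q1 = qs[1], median = qs[2], mean = m,
                 q3 = qs[3], max = max(x),
                 skewness = mean(d^3) / m2^1.5,
                 kurtosis = mean(d^4) / m2^2)
}

#' Compare candidate lifetime models on a sample
#'
#' Fits each candidate family by maximum likelihood and reports
#' `-2 log L`, the four information criteria and the Kolmogorov-Smirnov
#' statistic and p-value, one row per model, sorted by AIC (smaller is
#' better). A model whose fit fails is kept as a row of `NA`s with
#' `converged = FALSE`; the other rows are unaffected.
#'
#' @param x positive sample (numeric vector or data frame).
#' @param models subset of `"dus_lindley"`, `"lindley"`,
#'   `"dus_exponential"`, `"exponential"`.
#' @return a tibble of class `"dus_model_comparison"` with columns
#'   `model`, `xi`, `std_error`, `minus2logl`, `aic`, `aicc`, `hqic`,
#'   `bic`, `ks_stat`, `ks_pvalue`, `converged`.
#' @examples
#' compare_models(load_dataset("precipitation_hinkley"))
#' @export
compare_models <- function(x, models = c("dus_lindley", "lindley",
                                         "dus_exponential", "exponential")) {
  models <- match.arg(models, .models, several.ok = TRUE)
  x <- as_sample(x)
  n <- length(x)
  rows <- lapply(models, function(m) {
    fit <- tryCatch(fit_dus(x, method = "mle", model = m),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(model = m, xi = NA_real_, std_error = NA_real_,
                            minus2logl = NA_real_, aic = NA_real_,
                            aicc = NA_real_, hqic = NA_real_, bic = NA_real_,
                            ks_stat = NA_real_, ks_pvalue = NA_real_,
                            converged = FALSE))
    }
    m2l <- -2 * fit$loglik
    ic <- information_criteria(m2l, k = 1L, n = n)
    cdf <- model_cdf(m)
    ks <- dus_ks_test(x, function(q) cdf(q, fit$estimate))
    tibble::tibble(model = m, xi = fit$estimate, std_error = fit$std_error,
                   minus2logl = m2l, aic = ic$aic, aicc = ic$aicc,
                   hqic = ic$hqic, bic = ic$bic, ks_stat = ks$statistic,
                   ks_pvalue = ks$p.value, converged = TRUE)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$aic)
  class(out) <- c("dus_model_comparison", class(out))
  out
}

#' Write a model comparison as delimiter-separated text
#'
#' Emits the comparison table with a fixed column order
#' (model, -2logL, AIC, AICc, HQIC, BIC, K-S statistic, p-value) as
#' tab-separated text.
#'
#' @param comparison a tibble from [compare_models()].
#' @param path output file path (or `""` for stdout).
#' @return `comparison`, invisibly.
#' @export
write_comparison <- function(comparison, path = "") {
  cols <- c("model", "minus2logl", "aic", "aicc", "hqic", "bic",
            "ks_stat", "ks_pvalue")
  utils::write.table(as.data.frame(comparison)[, cols], file = path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(comparison)
}
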