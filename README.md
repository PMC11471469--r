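# duslindley

An R package for modelling positive lifetime data — times to failure,
survival times, event durations — with the **DUS Lindley distribution**,
aimed at reliability engineers and biostatisticians who need a flexible
one-parameter lifetime law with a full inferential toolkit around it.

## The model

The Lindley distribution has density

```
f(z; ξ) = ξ²/(1+ξ) · (1+z) · exp(−ξz),   z > 0, ξ > 0,
```

a mixture of exponential(ξ) and gamma(2, ξ) components. The DUS
transform maps any baseline CDF `F` to

```
G(z) = (exp(F(z)) − 1)/(e − 1),     g(z) = f(z)·exp(F(z))/(e − 1),
```

adding no parameters while re-weighting mass towards earlier failures.
The package implements the resulting DUS Lindley law end to end:

* `dlindley/plindley/qlindley/rlindley` and `ddus/pdus/qdus/rdus`
  (Lindley and exponential baselines), with closed-form Lambert-W
  quantile inversion and inverse-CDF sampling;
* `dus_reliability()` — survival, hazard, reverse hazard, Mills ratio;
* analytic summaries with independent series cross-checks:
  `dus_moment()`, `dus_stats()`, `dus_conditional_moment()`,
  `dus_mrl()`/`dus_mpl()`, `dus_generating()`, `ddus_order()`/
  `pdus_order()`, `dus_entropy()` (Rényi/Tsallis), `dus_inequality()`
  (Lorenz/Bonferroni);
* five estimators via `fit_dus()` (MLE, LSE, WLSE, CVME, ADE) with
  broom-style `tidy()`/`glance()` and `autoplot()`;
* `dus_lrt()` — a bootstrap-calibrated likelihood-ratio test of the
  Lindley baseline against its DUS transform;
* `dus_system_reliability()` — series / parallel / series-parallel
  systems of independent components;
* `run_mc_study()` — Monte-Carlo bias/variance/MSE study of the MLE;
* `compare_models()` — information-criterion and Kolmogorov–Smirnov
  comparison of DUS Lindley, Lindley, DUS exponential and exponential
  fits;
* two embedded benchmark datasets (`load_dataset()`): 30 daily March
  precipitation totals and 40 leukaemia survival times.

## Worked example

```r
library(duslindley)

precip <- load_dataset("precipitation_hinkley")
fit <- fit_dus(precip)     # maximum likelihood, DUS Lindley
fit
#> <dus_fit> MLE fit of the dus_lindley model (n = 30)
#>   xi = 1.118798 (SE 0.135999)
#>   log-likelihood = -41.4765
```

The fitted rate ξ̂ = 1.1188 (standard error 0.1360) implies a model
mean lifetime `dus_moment(1.1188, 1)` ≈ 1.63 inches, close to the
sample mean 1.675. Comparing candidate families:

```r
compare_models(precip)
#> # A tibble: 4 × 11
#>   model              xi std_error minus2logl   aic  aicc  hqic   bic ks_stat ks_pvalue
#> 1 dus_lindley     1.12      0.136       83.0  85.0  85.1  85.4  86.4   0.158    0.444
#> 2 dus_exponential 0.780     0.122       86.2  88.2  88.3  88.7  89.6   0.199    0.187
#> 3 lindley         0.910     0.125       86.3  88.3  88.4  88.7  89.7   0.188    0.238
#> 4 exponential     0.597     0.109       90.9  92.9  93.1  93.4  94.3   0.235    0.0724
```

The DUS Lindley row attains the smallest value of every criterion
(−2logL 82.95, AIC 84.95, AICc 85.10, HQIC 85.40, BIC 86.35) and the
smallest K-S distance (0.158, p = 0.44): the transform improves on its
own baseline by about 3.3 AIC units here. Component and system
reliability at a 300-hour mission with ξ = 0.001:

```r
dus_component_reliability(300, 0.001)
#> [1] 0.9779679
dus_system_reliability(tibble::tibble(t = rep(300, 3), xi = 0.001), "series")
#> [1] 0.9353493
```

— a single component survives the mission with probability 0.978; three
of them in series, 0.935.

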