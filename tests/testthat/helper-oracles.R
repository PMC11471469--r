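# Shared oracles and small utilities for the test suite.

# Brute-force system reliability: enumerate all 2^n component up/down
# states of independent Bernoulli(r_j) components and sum the probability
# of the states in which the system works.
enumeration_oracle <- function(r, topology, subsystem = NULL) {
  n <- length(r)
  stopifnot(n <= 14)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  works <- apply(states, 1L, function(up) {
    switch(topology,
           series = all(up),
           parallel = any(up),
           series_parallel = {
             any(vapply(split(up, subsystem), all, logical(1)))
           })
  })
  probs <- apply(states, 1L, function(up) prod(ifelse(up, r, 1 - r)))
  sum(probs[works])
}

# Riemann-sum expectation of h(Z) for the DUS Lindley law on a fine grid
# (midpoint rule), an oracle independent of stats::integrate.
riemann_expectation <- function(h, xi, upper, step = 1e-3) {
  z <- seq(step / 2, upper, by = step)
  sum(h(z) * ddus(z, xi)) * step
}

# Directly coded closed-form DUS Lindley density (the specific formula,
# no shared code with ddus's generic transform route).
ddus_direct <- function(z, xi) {
  e <- exp(1)
  (1 / (e - 1)) * (xi^2 / (1 + xi)) * (1 + z) * exp(-xi * z) *
    exp(1 - (1 + xi * z / (1 + xi)) * exp(-xi * z))
}

# Directly coded DUS exponential density.
ddusexp_direct <- function(z, xi) {
  e <- exp(1)
  (1 / (e - 1)) * xi * exp(-xi * z) * exp(1 - exp(-xi * z))
}
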