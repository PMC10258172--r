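# Programmatic fixtures: small random competing-risks samples, with and
# without ties / delayed entry, plus a brute-force hazard-based
# Aalen-Johansen oracle kept deliberately naive.

random_sample <- function(n = 40, seed = 1, ties = FALSE, truncated = FALSE,
                          p_cens = 0.3) {
  set.seed(seed)
  tt <- stats::rexp(n, 1)
  if (ties) tt <- ceiling(tt * 4) / 4          # cluster onto a coarse grid
  status <- ifelse(stats::runif(n) < p_cens, 0L,
                   ifelse(stats::runif(n) < 0.6, 1L, 2L))
  entry <- if (truncated) pmin(stats::runif(n, 0, 0.8), tt) else NULL
  event_sample(tt, status, entry = entry, n_causes = 2L)
}

# Naive Aalen-Johansen F_cause(t): explicit loop over unique times.
aj_oracle <- function(sample, t, cause) {
  u <- sort(unique(sample$time))
  S <- 1
  F1 <- 0
  for (v in u) {
    if (v > t) break
    atrisk <- sum(sample$entry <= v & sample$time >= v)
    dall <- sum(sample$time == v & sample$status > 0)
    d1 <- sum(sample$time == v & sample$status == cause)
    if (atrisk > 0) {
      F1 <- F1 + S * d1 / atrisk
      S <- S * (1 - dall / atrisk)
    }
  }
  F1
}

scenario1_sample <- function(n = 500, seed = 1) {
  simulate_cohort(scenario_config(n = n, p_Z = 0.5, beta0 = 0.2,
                                  beta1 = 0.2, eta = 0.2, p_oc = 0.2),
                  seed = seed)
}
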