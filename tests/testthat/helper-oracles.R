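# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Concordance probability P(rating_present > rating_absent) + 0.5 P(tie)
# by exhaustive enumeration of all 16 count-weighted rating pairs.
concordance_oracle <- function(present_counts, absent_counts) {
  total <- 0
  for (rp in 1:4) {
    for (ra in 1:4) {
      w <- present_counts[rp] * absent_counts[ra]
      if (rp > ra) total <- total + w
      if (rp == ra) total <- total + 0.5 * w
    }
  }
  total / (sum(present_counts) * sum(absent_counts))
}

# JZS Bayes factor by direct integration over the Cauchy effect-size prior
# using the noncentral-t likelihood of the t statistic (a different
# formulation than the package's inverse-gamma mixture integral).
jzs_bf_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  # dt(ncp = ...) emits precision notes far out in the tails; harmless here
  alt <- suppressWarnings(integrate(function(delta) {
    dt(t, df = nu, ncp = delta * sqrt(n)) * dcauchy(delta, scale = r)
  }, -Inf, Inf, rel.tol = 1e-9)$value)
  alt / dt(t, df = nu)
}

# random 2 x 4 rating-count table with both class totals positive
random_rating_counts <- function() {
  repeat {
    p <- rpois(4, lambda = sample(1:5, 1))
    a <- rpois(4, lambda = sample(1:5, 1))
    if (sum(p) > 0 && sum(a) > 0) {
      return(list(present_counts = p, absent_counts = a))
    }
  }
}

# standard study conditions: ~80% single-task accuracy
study_observer <- function(regime, ...) {
  observer_params(regime, dprime_top = dprime_for_pc(0.8), ...)
}
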