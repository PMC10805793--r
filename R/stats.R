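# Inference: percentile bootstrap CIs, one-sample/paired t tests, JZS
# Bayes factors, and a repeated-measures interaction test.

#' Percentile bootstrap CI of the mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' 2.5th and 97.5th percentiles of the resampled means.
#'
#' @param values numeric vector of per-subject effects, length >= 2.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, seed = 1) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  set.seed(seed)
  n <- length(values)
  means <- colMeans(matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                           nrow = n))
  unname(stats::quantile(means, c(0.025, 0.975), type = 7))
}

#' One-sample t test on per-subject effects
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @param mu0 null value.
#' @return a list with `mean_diff`, `sem`, `t`, `df` (= n - 1), `p`
#'   (two-sided).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (sd(values) == 0) stop("zero variance", call. = FALSE)
  ht <- t.test(values, mu = mu0)
  list(mean_diff = mean(values) - mu0,
       sem = sd(values) / sqrt(length(values)),
       t = unname(ht$statistic),
       df = length(values) - 1L,
       p = ht$p.value)
}

#' JZS Bayes factor for a one-sample or paired t test
#'
#' Default Bayes factor of Rouder, Speckman, Sun, Morey & Iverson (2009):
#' the standardized effect size has a Cauchy(0, r) prior under the
#' alternative, equivalently a normal prior with variance g scaled by an
#' inverse-gamma(1/2, r^2/2) mixing distribution; the Bayes factor is the
#' ratio of the marginal likelihood of the observed t statistic under the
#' alternative (integrated over g by adaptive quadrature) to its likelihood
#' under the null. Values above 1 favor the alternative.
#'
#' @param t observed t statistic.
#' @param n sample size (number of subjects / pairs); df = n - 1.
#' @param r Cauchy prior scale; the default sqrt(2)/2 is the common
#'   "medium" default.
#' @return the Bayes factor (alternative over null).
#' @export
#' @examples
#' jzs_bf(6.51, 11)
jzs_bf <- function(t, n, r = sqrt(2) / 2) {
  stopifnot(is.finite(t), n >= 2, r > 0)
  nu <- n - 1
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    a <- 1 + n * r^2 * g
    a^(-1 / 2) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_lik <- integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 0)
  if (alt_lik$message != "OK") {
    stop("Bayes factor integral did not converge: ", alt_lik$message,
         call. = FALSE)
  }
  alt_lik$value / null_lik
}

#' Full inference bundle for a per-subject effect
#'
#' One-sample t test against `mu0`, percentile bootstrap CI of the mean,
#' and the JZS Bayes factor computed from the t statistic.
#'
#' @inheritParams one_sample_t
#' @inheritParams bootstrap_ci
#' @param r JZS prior scale, see [jzs_bf()].
#' @return a list of class `stat_result`: `mean_diff`, `sem`, `t`, `df`,
#'   `p`, `ci_low`, `ci_high`, `bf`, `n`.
#' @export
effect_test <- function(values, mu0 = 0, n_boot = 1000, seed = 1,
                        r = sqrt(2) / 2) {
  tt <- one_sample_t(values, mu0)
  ci <- bootstrap_ci(values, n_boot = n_boot, seed = seed)
  structure(
    c(tt, list(ci_low = ci[1], ci_high = ci[2],
               bf = jzs_bf(tt$t, length(values), r),
               n = length(values))),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "mean = %.4g (SEM %.4g), t(%d) = %.3g, p = %.3g, 95%% CI [%.4g, %.4g], BF = %.3g\n",
    x$mean_diff, x$sem, x$df, x$t, x$p, x$ci_low, x$ci_high, x$bf))
  invisible(x)
}

#' Repeated-measures interaction test
#'
#' Two-factor repeated-measures ANOVA on a complete subject x factor1 x
#' factor2 table (one value per cell), reporting the interaction F test.
#'
#' @param data data frame in long format.
#' @param value,subject,f1,f2 column names (strings) of the response, the
#'   subject identifier, and the two within-subject factors.
#' @return a list with `F`, `df1`, `df2`, `p`.
#' @export
rm_interaction_test <- function(data, value = "value", subject = "subject",
                                f1 = "f1", f2 = "f2") {
  d <- data.frame(
    y = data[[value]],
    subject = factor(data[[subject]]),
    a = factor(data[[f1]]),
    b = factor(data[[f2]])
  )
  cells <- table(d$subject, d$a, d$b)
  if (any(cells != 1L)) {
    stop("incomplete repeated-measures table: every subject needs exactly ",
         "one value per factor combination", call. = FALSE)
  }
  fit <- aov(y ~ a * b + Error(subject / (a * b)), data = d)
  strata <- summary(fit)
  tab <- NULL
  for (s in strata) {
    sm <- s[[1]]
    if (any(grepl("a:b", rownames(sm)))) tab <- sm
  }
  if (is.null(tab)) stop("interaction stratum not found", call. = FALSE)
  i <- grep("a:b", rownames(tab))
  res <- grep("Residuals", rownames(tab))
  list(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[res, "Df"],
       p = tab[i, "Pr(>F)"])
}
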