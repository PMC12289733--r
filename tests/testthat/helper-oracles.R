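# Independent numeric-integration oracles for the Bayesian observer.
# These integrate the generative model directly and never touch the
# closed-form implementations. Finite integration windows centred on the
# region where the integrand has mass keep the quadrature accurate even
# for extreme parameter draws.

oracle_window <- function(xs, p) {
  s <- max(p$sigma_a, p$sigma_v, p$sigma_p)
  c(min(xs, p$mu_p) - 12 * s, max(xs, p$mu_p) + 12 * s)
}

oracle_lik_common <- function(x_v, x_a, p) {
  w <- oracle_window(c(x_v, x_a), p)
  stats::integrate(function(s) {
    stats::dnorm(x_v, s, p$sigma_v) * stats::dnorm(x_a, s, p$sigma_a) *
      stats::dnorm(s, p$mu_p, p$sigma_p)
  }, w[1], w[2], rel.tol = 1e-10, abs.tol = 0,
  subdivisions = 2000L)$value
}

oracle_lik_independent <- function(x_v, x_a, p) {
  w <- oracle_window(c(x_v, x_a), p)
  iv <- stats::integrate(function(s) {
    stats::dnorm(x_v, s, p$sigma_v) * stats::dnorm(s, p$mu_p, p$sigma_p)
  }, w[1], w[2], rel.tol = 1e-10, abs.tol = 0,
  subdivisions = 2000L)$value
  ia <- stats::integrate(function(s) {
    stats::dnorm(x_a, s, p$sigma_a) * stats::dnorm(s, p$mu_p, p$sigma_p)
  }, w[1], w[2], rel.tol = 1e-10, abs.tol = 0,
  subdivisions = 2000L)$value
  iv * ia
}

oracle_posterior <- function(x_v, x_a, p) {
  l1 <- oracle_lik_common(x_v, x_a, p)
  l2 <- oracle_lik_independent(x_v, x_a, p)
  l1 * p$p_common / (l1 * p$p_common + l2 * (1 - p$p_common))
}

# posterior mean of s given both measurements under C = 1 by quadrature
oracle_c1_mean <- function(x_v, x_a, p) {
  w <- oracle_window(c(x_v, x_a), p)
  num <- stats::integrate(function(s) {
    s * stats::dnorm(x_v, s, p$sigma_v) * stats::dnorm(x_a, s, p$sigma_a) *
      stats::dnorm(s, p$mu_p, p$sigma_p)
  }, w[1], w[2], rel.tol = 1e-10, abs.tol = 0,
  subdivisions = 2000L)$value
  num / oracle_lik_common(x_v, x_a, p)
}
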