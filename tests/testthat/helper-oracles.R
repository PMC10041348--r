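# Independent oracles used to validate the likelihood and samplers.
# None of these call the package's lbeta/log-sum-exp evaluation path.

# E[t^k (1-t)^l] under Beta(a, b) by adaptive quadrature.  The unnormalized
# integral int t^(alpha-1) (1-t)^(beta-1) dt is split at 1/2 and each half
# substituted (v = t^alpha, w = (1-t)^beta) so the integrand is bounded even
# when the density is U-shaped (alpha, beta < 1); no Beta/Gamma functions
# are involved anywhere.
beta_unnorm_int <- function(alpha, beta) {
  integrate(function(v) (1 - v^(1 / alpha))^(beta - 1), 0, 0.5^alpha,
            rel.tol = 1e-12, subdivisions = 500L)$value / alpha +
    integrate(function(w) (1 - w^(1 / beta))^(alpha - 1), 0, 0.5^beta,
              rel.tol = 1e-12, subdivisions = 500L)$value / beta
}

beta_moment_quad <- function(k, l, a, b) {
  beta_unnorm_int(k + a, l + b) / beta_unnorm_int(a, b)
}

# marginal likelihood of one examiner's observed data (J, R, E) under the
# non-ignorable model, summing the missing-error count z with each mixed
# binomial moment computed by quadrature
marginal_oracle_one <- function(J, R, E, hp) {
  ap <- hp$mu_p * hp$tau_p;     bp <- (1 - hp$mu_p) * hp$tau_p
  a1 <- hp$mu_pi1 * hp$tau_pi1; b1 <- (1 - hp$mu_pi1) * hp$tau_pi1
  a2 <- hp$mu_pi2 * hp$tau_pi2; b2 <- (1 - hp$mu_pi2) * hp$tau_pi2
  total <- 0
  for (z in 0:(J - R)) {
    total <- total + choose(J, R) * choose(R, E) * choose(J - R, z) *
      beta_moment_quad(E + z, J - E - z, ap, bp) *
      beta_moment_quad(R - E, J - R - z, a1, b1) *
      beta_moment_quad(E, z, a2, b2)
  }
  total
}

log_marginal_oracle <- function(panel, hp) {
  sum(log(mapply(marginal_oracle_one, panel$J, panel$R, panel$E_obs,
                 MoreArgs = list(hp = hp))))
}

# observed-data likelihood by exhaustive enumeration of every completion of
# the missing error indicators (2^(J-R) binary vectors)
loglik_completion_oracle <- function(J, R, E, p, pi1, pi2) {
  obs <- choose(J, R) * choose(R, E) * (p * pi2)^E * ((1 - p) * pi1)^(R - E)
  m <- J - R
  if (m == 0) return(log(obs))
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  miss_sum <- sum(apply(combos, 1, function(y)
    prod(ifelse(y == 1, p * (1 - pi2), (1 - p) * (1 - pi1)))))
  log(obs * miss_sum)
}

# posterior mean of p[j] under the naive model with sampled hyperparameters,
# by 2-D grid integration over (mu_p, tau_p); uses the conjugacy
# E[p_j | mu, tau, data] = (mu tau + E_j) / (tau + R_j)
naive_grid_mean_p <- function(R, E, j, n_mu = 400, n_tau = 400, tau_max = 60) {
  mu <- seq(0.001, 0.999, length.out = n_mu)
  tau <- seq(0.005, tau_max, length.out = n_tau)
  g <- expand.grid(mu = mu, tau = tau)
  a <- g$mu * g$tau
  b <- (1 - g$mu) * g$tau
  ll <- dgamma(g$tau, 2, rate = 0.5, log = TRUE)  # Beta(1,1) on mu is flat
  for (i in seq_along(R))
    ll <- ll + lbeta(a + E[i], b + R[i] - E[i]) - lbeta(a, b)
  w <- exp(ll - max(ll))
  sum(w * (a + E[j]) / (g$tau + R[j])) / sum(w)
}

# Clopper-Pearson bounds by direct inversion of the binomial tail equations
cp_tail_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# posterior mean of p[1] for a non-ignorable toy with fixed hyperparameters
# (examiners are a posteriori independent given fixed hyperparameters)
noni_oracle_mean_p <- function(J, R, E, hp) {
  ap <- hp$mu_p * hp$tau_p;     bp <- (1 - hp$mu_p) * hp$tau_p
  a1 <- hp$mu_pi1 * hp$tau_pi1; b1 <- (1 - hp$mu_pi1) * hp$tau_pi1
  a2 <- hp$mu_pi2 * hp$tau_pi2; b2 <- (1 - hp$mu_pi2) * hp$tau_pi2
  num <- den <- 0
  for (z in 0:(J - R)) {
    w <- choose(J - R, z) *
      beta_moment_quad(R - E, J - R - z, a1, b1) *
      beta_moment_quad(E, z, a2, b2)
    num <- num + w * beta_moment_quad(E + z + 1, J - E - z, ap, bp)
    den <- den + w * beta_moment_quad(E + z, J - E - z, ap, bp)
  }
  num / den
}

pooled_p <- function(draws, j = NULL) {
  unlist(lapply(draws$chains, function(ch)
    if (is.null(j)) ch$p else ch$p[, j]))
}
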