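#' Observed-data log likelihood of the non-ignorable selection model
#'
#' For examiner i with `J[i]` assigned items, `R[i]` observed binary
#' decisions and `E_obs[i]` observed errors, given examiner-level error
#' probability `p[i]` and response probabilities `pi1[i]` (no error) and
#' `pi2[i]` (error), the observed-data likelihood marginalizes the unknown
#' error status of the `J[i] - R[i]` unanswered items:
#'
#' \deqn{\prod_i \binom{J_i}{R_i}\binom{R_i}{E_i}
#'   (p_i \pi_{2i})^{E_i} ((1-p_i)\pi_{1i})^{R_i - E_i}
#'   [p_i(1-\pi_{2i}) + (1-p_i)(1-\pi_{1i})]^{J_i - R_i}.}
#'
#' Computed entirely in log space.
#'
#' @param panel a `study_panel`.
#' @param p,pi1,pi2 probability vectors in (0,1), one entry per panel row.
#' @return Scalar log likelihood.
#' @export
loglik_observed_nonignorable <- function(panel, p, pi1, pi2) {
  J <- panel$J; R <- panel$R; E <- panel$E_obs
  n <- nrow(panel)
  if (length(p) != n || length(pi1) != n || length(pi2) != n)
    stop_bbmiss("probability vectors must match the panel dimension",
                "bbmiss_input_error")
  if (any(!is.finite(p) | !is.finite(pi1) | !is.finite(pi2)) ||
      any(p <= 0 | p >= 1 | pi1 <= 0 | pi1 >= 1 | pi2 <= 0 | pi2 >= 1))
    stop_bbmiss("probabilities must be finite and strictly inside (0, 1)",
                "bbmiss_input_error")
  if (any(E > R)) stop_bbmiss("E_obs > R in panel", "bbmiss_input_error")
  miss <- J - R
  sum(lchoose(J, R) + lchoose(R, E) +
        E * log(p * pi2) + (R - E) * log((1 - p) * pi1) +
        miss * log(p * (1 - pi2) + (1 - p) * (1 - pi1)))
}

# aggregate a panel to unique (J, R, E) triples with multiplicities;
# the marginal likelihood depends on the data only through these
panel_suffstats <- function(panel) {
  if (inherits(panel, "suffstat_panel"))
    return(data.frame(J = panel$J, R = panel$R, E = panel$E_obs, w = panel$.w))
  key <- paste(panel$J, panel$R, panel$E_obs)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  data.frame(J = as.integer(parts[, 1]), R = as.integer(parts[, 2]),
             E = as.integer(parts[, 3]), w = as.integer(tab))
}

#' Log marginal likelihood of the non-ignorable model
#'
#' The observed-data likelihood with all examiner-level probabilities
#' integrated against their `Beta(mu * tau, (1 - mu) * tau)` population
#' distributions.  For each examiner the integral is a finite sum over the
#' unknown number `z` of errors among unanswered items:
#'
#' \deqn{\sum_{z=0}^{J_i-R_i} \binom{J_i}{R_i}\binom{R_i}{E_i}
#'   \binom{J_i-R_i}{z}
#'   \frac{B(E_i + z + a_p,\, J_i - E_i - z + b_p)}{B(a_p, b_p)}
#'   \frac{B(R_i - E_i + a_1,\, J_i - R_i - z + b_1)}{B(a_1, b_1)}
#'   \frac{B(E_i + a_2,\, z + b_2)}{B(a_2, b_2)},}
#'
#' with `(a, b)` the Beta shapes of each block.  The inner sum is evaluated
#' exactly via log-sum-exp; Beta functions via log-gamma.  This is the
#' objective maximized by [fit_eb_mle()].
#'
#' @param panel a `study_panel` (or anything with columns `J`, `R`, `E_obs`).
#' @param hyper a [hyperparams()] object with blocks `p`, `pi1`, `pi2`.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_nonignorable <- function(panel, hyper) {
  require_blocks(hyper, c("p", "pi1", "pi2"))
  st <- panel_suffstats(panel)
  ap <- hyper$mu_p * hyper$tau_p;    bp <- (1 - hyper$mu_p) * hyper$tau_p
  a1 <- hyper$mu_pi1 * hyper$tau_pi1; b1 <- (1 - hyper$mu_pi1) * hyper$tau_pi1
  a2 <- hyper$mu_pi2 * hyper$tau_pi2; b2 <- (1 - hyper$mu_pi2) * hyper$tau_pi2
  lnorm <- lbeta(ap, bp) + lbeta(a1, b1) + lbeta(a2, b2)
  total <- 0
  for (k in seq_len(nrow(st))) {
    J <- st$J[k]; R <- st$R[k]; E <- st$E[k]
    z <- 0:(J - R)
    lt <- lchoose(J, R) + lchoose(R, E) + lchoose(J - R, z) +
      lbeta(E + z + ap, J - E - z + bp) +
      lbeta(R - E + a1, J - R - z + b1) +
      lbeta(E + a2, z + b2)
    total <- total + st$w[k] * (logsumexp(lt) - lnorm)
  }
  total
}

#' Log marginal likelihood of the ignorable model
#'
#' Under ignorable missingness the response and error processes separate:
#' the marginal likelihood is a product of beta-binomial terms for the
#' response counts `R | J` and the observed error counts `E_obs | R`,
#'
#' \deqn{\sum_i \log \mathrm{BetaBin}(R_i; J_i, \mu_\pi, \tau_\pi)
#'   + \log \mathrm{BetaBin}(E_i; R_i, \mu_p, \tau_p).}
#'
#' @inheritParams log_marginal_nonignorable
#' @param hyper a [hyperparams()] object with blocks `p` and `pi`.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_ignorable <- function(panel, hyper) {
  require_blocks(hyper, c("p", "pi"))
  sum(dbetabinom_mutau(panel$R, panel$J, hyper$mu_pi, hyper$tau_pi)) +
    sum(dbetabinom_mutau(panel$E_obs, panel$R, hyper$mu_p, hyper$tau_p))
}
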