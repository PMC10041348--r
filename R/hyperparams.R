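#' Hyperparameters on the mean/concentration scale
#'
#' All examiner-level probabilities are modelled as draws from Beta
#' distributions parameterized by mean `mu` and concentration `tau`,
#' `Beta(mu * tau, (1 - mu) * tau)`.  A `hyperparams` object carries the
#' error block `(mu_p, tau_p)` and, depending on the model, either a single
#' response block `(mu_pi, tau_pi)` (ignorable missingness) or two blocks
#' `(mu_pi1, tau_pi1)` for response given no error and `(mu_pi2, tau_pi2)`
#' for response given an error (non-ignorable selection model).
#'
#' @param mu_p,tau_p mean and concentration of the error-probability
#'   distribution; `mu_p` in (0,1), `tau_p > 0`.
#' @param mu_pi,tau_pi response block for the ignorable model.
#' @param mu_pi1,tau_pi1,mu_pi2,tau_pi2 response blocks for the
#'   non-ignorable model.
#' @return A list of class `hyperparams` containing the supplied blocks.
#' @examples
#' hyperparams(mu_p = 0.2, tau_p = 7.1, mu_pi1 = 0.6, tau_pi1 = 0.4,
#'             mu_pi2 = 0.01, tau_pi2 = 3.5)
#' @export
hyperparams <- function(mu_p, tau_p, mu_pi = NULL, tau_pi = NULL,
                        mu_pi1 = NULL, tau_pi1 = NULL,
                        mu_pi2 = NULL, tau_pi2 = NULL) {
  hp <- list(mu_p = mu_p, tau_p = tau_p, mu_pi = mu_pi, tau_pi = tau_pi,
             mu_pi1 = mu_pi1, tau_pi1 = tau_pi1,
             mu_pi2 = mu_pi2, tau_pi2 = tau_pi2)
  hp <- hp[!vapply(hp, is.null, logical(1))]
  for (nm in names(hp)) {
    v <- hp[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_bbmiss(paste(nm, "must be a finite scalar"), "bbmiss_input_error")
    if (startsWith(nm, "mu") && (v <= 0 || v >= 1))
      stop_bbmiss(paste(nm, "must lie in (0, 1)"), "bbmiss_input_error")
    if (startsWith(nm, "tau") && v <= 0)
      stop_bbmiss(paste(nm, "must be positive"), "bbmiss_input_error")
  }
  structure(hp, class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("hyperparameters (Beta mean/concentration):\n")
  for (nm in names(x)) cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# (mu, tau) -> (shape1, shape2)
beta_shapes <- function(mu, tau) c(mu * tau, (1 - mu) * tau)

require_blocks <- function(hp, blocks) {
  need <- unlist(lapply(blocks, function(b) paste0(c("mu_", "tau_"), b)))
  miss <- setdiff(need, names(hp))
  if (length(miss))
    stop_bbmiss(paste("hyperparams missing:", paste(miss, collapse = ", ")),
                "bbmiss_input_error")
  invisible(hp)
}

#' Prior specification for sampled hyperparameters
#'
#' Defaults follow common practice for these models: `Beta(1, 1)` priors on
#' each mean `mu` and `Gamma(shape = 2, rate = 0.5)` priors on each
#' concentration `tau`, with optional truncation of the support to keep
#' slice/Metropolis updates away from numerically hostile boundaries
#' (`mu` in (0.001, 0.999), `tau` in (0.001, Inf)).
#'
#' @param mu_shape1,mu_shape2 Beta prior shapes for every `mu`.
#' @param tau_shape,tau_rate Gamma prior shape and rate for every `tau`.
#' @param mu_bounds,tau_bounds truncation intervals.
#' @param truncate apply the truncation bounds (default `TRUE`).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mu_shape1 = 1, mu_shape2 = 1,
                       tau_shape = 2, tau_rate = 0.5,
                       mu_bounds = c(0.001, 0.999),
                       tau_bounds = c(0.001, Inf),
                       truncate = TRUE) {
  if (mu_bounds[1] <= 0 || mu_bounds[2] >= 1 || mu_bounds[1] >= mu_bounds[2])
    stop_bbmiss("mu_bounds must be strictly inside (0, 1)", "bbmiss_input_error")
  if (tau_bounds[1] <= 0 || tau_bounds[1] >= tau_bounds[2])
    stop_bbmiss("tau_bounds must be strictly inside (0, Inf)", "bbmiss_input_error")
  structure(list(mu_shape1 = mu_shape1, mu_shape2 = mu_shape2,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 mu_bounds = mu_bounds, tau_bounds = tau_bounds,
                 truncate = truncate),
            class = "prior_spec")
}

#' Beta-binomial log density, mean/concentration parameterization
#'
#' Density of `x` successes in `n` trials when the success probability is
#' integrated over `Beta(mu * tau, (1 - mu) * tau)`.
#'
#' @param x,n counts, `0 <= x <= n` (vectorized).
#' @param mu,tau mean in (0,1) and concentration > 0.
#' @param log return the log density (default `TRUE`).
#' @return Numeric vector of (log) densities.
#' @export
dbetabinom_mutau <- function(x, n, mu, tau, log = TRUE) {
  a <- mu * tau
  b <- (1 - mu) * tau
  out <- lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
  if (log) out else exp(out)
}
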