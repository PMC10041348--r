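#' Posterior-predictive study error proportion
#'
#' For each retained posterior draw, simulates the error counts of a new
#' study with the same assignment/response pattern and forms the study
#' error proportion `PE`:
#'
#' * naive: `E_obs[i] ~ Binomial(R[i], p[i])`, `PE = sum(E_obs) / R_total`
#'   over responding examiners (the study is taken to consist of the
#'   answered items only, as published analyses do);
#' * ignorable: `E_obs[i] ~ Binomial(R[i], p[i] * pi[i])` and
#'   `E_mis[i] ~ Binomial(J[i] - R[i], p[i] * (1 - pi[i]))`,
#'   `PE = sum(E_obs + E_mis) / J_total`;
#' * non-ignorable: the same with `pi2[i]` in both roles.
#'
#' One predictive replicate is drawn per posterior draw, so the returned
#' vector is a sample from the posterior predictive distribution of `PE`.
#'
#' @param draws a `posterior_draws` object from [fit_naive()],
#'   [fit_ignorable()] or [fit_nonignorable_eb()].
#' @param panel optional `study_panel`; if supplied it is checked for
#'   consistency with the panel stored in `draws`.
#' @param level credible level for the equal-tailed interval (default 0.95).
#' @param seed optional seed for the predictive simulation.
#' @return An object of class `pe_predictive`: list with `draws` (vector of
#'   PE draws in `[0, 1]`), `mean`, `lower`, `upper` (empirical
#'   `(1-level)/2` and `1-(1-level)/2` quantiles), `model`, `policy`,
#'   `level`, and the denominator used (`denom`).
#' @export
pe_predictive <- function(draws, panel = NULL, level = 0.95, seed = NULL) {
  if (!inherits(draws, "posterior_draws"))
    stop_bbmiss("draws must be a posterior_draws object", "bbmiss_input_error")
  ps <- draws$panel_stats
  if (!is.null(panel)) {
    m <- match(draws$examiner_id, panel$examiner_id)
    if (anyNA(m) ||
        !identical(as.integer(panel$J[m]), as.integer(ps$J)) ||
        !identical(as.integer(panel$R[m]), as.integer(ps$R)))
      stop_bbmiss("panel does not match the panel the draws were fit to",
                  "bbmiss_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  J <- ps$J; R <- ps$R; I <- nrow(ps)
  pe <- unlist(lapply(draws$chains, function(ch) {
    n <- nrow(ch$p)
    Rm <- matrix(R, n, I, byrow = TRUE)
    Jm <- matrix(J, n, I, byrow = TRUE)
    if (draws$model == "naive") {
      eobs <- matrix(rbinom(n * I, Rm, ch$p), n, I)
      rowSums(eobs) / draws$R_total
    } else {
      resp <- if (draws$model == "ignorable") ch$pi else ch$pi2
      eobs <- matrix(rbinom(n * I, Rm, ch$p * resp), n, I)
      emis <- matrix(rbinom(n * I, Jm - Rm, ch$p * (1 - resp)), n, I)
      rowSums(eobs + emis) / draws$J_total
    }
  }))
  a <- (1 - level) / 2
  qs <- unname(quantile(pe, c(a, 1 - a), type = 7))
  structure(list(draws = pe, mean = mean(pe), lower = qs[1], upper = qs[2],
                 model = draws$model, policy = draws$policy, level = level,
                 denom = if (draws$model == "naive") draws$R_total else draws$J_total),
            class = "pe_predictive")
}

#' @export
print.pe_predictive <- function(x, ...) {
  cat(sprintf("posterior-predictive error proportion (%s model, inconclusives %s)\n",
              x$model,
              if (identical(x$policy, "as_correct_observed")) "observed-correct"
              else "missing"))
  cat(sprintf("  E(PE | data) = %s%%,  %.0f%% interval (%s%%, %s%%)\n",
              fmt_pct(x$mean), 100 * x$level, fmt_pct(x$lower), fmt_pct(x$upper)))
  invisible(x)
}

#' Summarize several predictive error proportions as one table
#'
#' Mirrors the usual reporting layout: one row per model/policy combination
#' with the predictive mean and equal-tailed interval, in percent (full
#' precision retained in the fraction columns).
#'
#' @param ... `pe_predictive` objects (or one list of them).
#' @return A data frame with columns `model`, `policy`, `pe_mean_pct`,
#'   `lower_pct`, `upper_pct`, `pe_mean`, `lower`, `upper`.
#' @export
pe_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "pe_predictive")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(x)
    data.frame(model = x$model, policy = x$policy,
               pe_mean_pct = round(100 * x$mean, 1),
               lower_pct = round(100 * x$lower, 1),
               upper_pct = round(100 * x$upper, 1),
               pe_mean = x$mean, lower = x$lower, upper = x$upper)))
}

#' Posterior summary for one examiner's error probability
#'
#' Equal-tailed credible interval and posterior mean of the examiner's
#' `p` draws, pooled over chains.
#'
#' @param draws a `posterior_draws` object.
#' @param examiner an examiner id present in the draws.
#' @param level credible level (default 0.95).
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
examiner_posterior_interval <- function(draws, examiner, level = 0.95) {
  i <- match(examiner, draws$examiner_id)
  if (is.na(i)) stop_bbmiss("unknown examiner in draws", "bbmiss_input_error")
  x <- unlist(lapply(draws$chains, function(ch) ch$p[, i]))
  a <- (1 - level) / 2
  qs <- unname(quantile(x, c(a, 1 - a), type = 7))
  c(mean = mean(x), lower = qs[1], upper = qs[2])
}

#' Posterior summaries for every examiner's error probability
#'
#' One row per examiner: posterior mean and equal-tailed credible interval
#' of the `p` draws, keyed by `examiner_id` (the shape used for
#' per-examiner interval plots).
#'
#' @param draws a `posterior_draws` object.
#' @param level credible level (default 0.95).
#' @return A data frame with columns `examiner_id`, `mean`, `lower`,
#'   `upper`.
#' @export
examiner_intervals <- function(draws, level = 0.95) {
  out <- t(vapply(draws$examiner_id,
                  function(id) examiner_posterior_interval(draws, id, level),
                  numeric(3)))
  data.frame(examiner_id = draws$examiner_id,
             mean = out[, "mean"], lower = out[, "lower"],
             upper = out[, "upper"], row.names = NULL)
}

#' Exact Clopper-Pearson binomial interval
#'
#' The conventional frequentist baseline for black-box error rates: the
#' exact interval obtained by inverting binomial tail probabilities via Beta
#' quantiles.  `lower = qbeta(alpha/2; x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2; x + 1, n - x)` (1 when `x = n`).
#'
#' @param x error count, `0 <= x <= n`.
#' @param n trial count, `> 0`.
#' @param level confidence level (default 0.95).
#' @return An object of class `cp_result`: list with `x`, `n`, `point`
#'   (`x/n`), `lower`, `upper`, `level`.
#' @examples
#' clopper_pearson(12, 2560)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || n <= 0 || x < 0 || x > n)
    stop_bbmiss("need 0 <= x <= n with n > 0", "bbmiss_input_error")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(x = x, n = n, point = x / n, lower = lower, upper = upper,
                 level = level),
            class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("Clopper-Pearson: %d/%d = %s%%,  %.0f%% CI (%s%%, %s%%)\n",
              x$x, x$n, fmt_pct(x$point), 100 * x$level,
              fmt_pct(x$lower), fmt_pct(x$upper)))
  invisible(x)
}
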