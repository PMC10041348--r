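#' Chain settings for the Gibbs samplers
#'
#' Defaults follow the settings used for the naive and ignorable models in
#' the motivating palmar-print reanalysis: 2 chains of 15 000 iterations
#' with 5 000 burn-in.  The non-ignorable sampler is typically run longer
#' (40 000/10 000 with inconclusives observed, 60 000/10 000 with
#' inconclusives missing); see [default_chain_config()].
#'
#' @param n_chains number of independent chains (>= 1; >= 2 for the
#'   Gelman-Rubin diagnostic).
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations discarded per chain (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer; chain `c` uses seed `seed + c - 1`.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_chains = 2, n_iter = 15000, n_burn = 5000,
                         thin = 1, seed = 1) {
  if (n_burn >= n_iter) stop_bbmiss("n_burn must be < n_iter", "bbmiss_input_error")
  if (n_chains < 1 || thin < 1) stop_bbmiss("bad chain settings", "bbmiss_input_error")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' Replicating chain settings per model and policy
#'
#' @param model `"naive"`, `"ignorable"` or `"nonignorable"`.
#' @param policy inconclusive policy of the panel being fit.
#' @param seed base seed.
#' @return A [chain_config()].
#' @export
default_chain_config <- function(model = c("naive", "ignorable", "nonignorable"),
                                 policy = c("as_correct_observed", "as_missing"),
                                 seed = 1) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  if (model != "nonignorable")
    chain_config(2, 15000, 5000, seed = seed)
  else if (policy == "as_correct_observed")
    chain_config(2, 40000, 10000, seed = seed)
  else
    chain_config(2, 60000, 10000, seed = seed)
}

# --- internal: joint random-walk Metropolis update of one (mu, tau) block ---
# x: current probability vector governed by Beta(mu*tau, (1-mu)*tau)
# state: list(mu, tau, lsd = log proposal sds, acc, try)
mh_update_block <- function(x, state, priors) {
  th <- c(stats::qlogis(state$mu), log(state$tau))
  prop <- th + rnorm(2, 0, exp(state$lsd))
  mu_new <- stats::plogis(prop[1]); tau_new <- exp(prop[2])
  state$try <- state$try + 1
  state$c_try <- state$c_try + 1
  if (priors$truncate &&
      (mu_new < priors$mu_bounds[1] || mu_new > priors$mu_bounds[2] ||
       tau_new < priors$tau_bounds[1] || tau_new > priors$tau_bounds[2]))
    return(state)  # reject: outside truncated support
  lp <- function(mu, tau) {
    sum(dbeta(x, mu * tau, (1 - mu) * tau, log = TRUE)) +
      dbeta(mu, priors$mu_shape1, priors$mu_shape2, log = TRUE) +
      dgamma(tau, priors$tau_shape, rate = priors$tau_rate, log = TRUE) +
      log(mu) + log1p(-mu) + log(tau)  # Jacobian of (logit, log) transform
  }
  lr <- lp(mu_new, tau_new) - lp(state$mu, state$tau)
  if (is.finite(lr) && log(runif(1)) < lr) {
    state$mu <- mu_new; state$tau <- tau_new
    state$acc <- state$acc + 1
    state$c_acc <- state$c_acc + 1
  }
  state
}

# adapt proposal scale toward acceptance in [0.2, 0.45]; burn-in only
mh_adapt <- function(state) {
  if (state$try >= 50) {
    rate <- state$acc / state$try
    if (rate > 0.45) state$lsd <- state$lsd + 0.2
    if (rate < 0.20) state$lsd <- state$lsd - 0.2
    state$acc <- 0; state$try <- 0
  }
  state
}

new_mh_state <- function(mu, tau) list(mu = mu, tau = tau, lsd = log(0.25),
                                       acc = 0, try = 0, c_acc = 0, c_try = 0)

new_posterior_draws <- function(model, chains, panel, config, hyper = NULL,
                                acceptance = NULL) {
  structure(list(model = model,
                 chains = chains,
                 examiner_id = panel$examiner_id,
                 panel_stats = as.data.frame(panel)[c("examiner_id", "J", "R", "E_obs")],
                 policy = attr(panel, "policy"),
                 J_total = attr(panel, "J_total"),
                 R_total = attr(panel, "R_total"),
                 config = config, hyper_fixed = hyper,
                 acceptance = acceptance),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  nk <- nrow(x$chains[[1]]$p)
  cat(sprintf("posterior draws: %s model, %d chain(s) x %d kept draws, %d examiners\n",
              x$model, length(x$chains), nk, length(x$examiner_id)))
  if (!is.null(x$hyper_fixed))
    cat("  hyperparameters fixed (empirical Bayes)\n")
  invisible(x)
}

run_chains <- function(config, one_chain) {
  lapply(seq_len(config$n_chains), function(c) {
    set.seed(config$seed + c - 1L)
    one_chain()
  })
}

keep_index <- function(config) seq(config$n_burn + 1L, config$n_iter, config$thin)

#' Fit the naive (complete-data) hierarchical model
#'
#' Models observed errors only: `E_obs[i] ~ Binomial(R[i], p[i])` with
#' `p[i] ~ Beta(mu_p tau_p, (1-mu_p) tau_p)`; examiners without any observed
#' response are excluded.  The sampler alternates an exact conjugate draw of
#' every `p[i]` with a joint random-walk Metropolis update of
#' `(mu_p, tau_p)` on the (logit, log) scale (proposal scale adapted during
#' burn-in only, frozen afterwards to preserve detailed balance).
#'
#' @param panel a `study_panel`.
#' @param priors a [prior_spec()].
#' @param config a [chain_config()].
#' @param hyper_fixed optional [hyperparams()] with block `p`; if supplied
#'   the hyperparameters are held fixed and not sampled.
#' @param verbose log progress (with Metropolis acceptance rates where
#'   applicable) every 1000 iterations.
#' @return A `posterior_draws` object.  Each chain holds a matrix `p`
#'   (kept draws x examiners) and, when sampled, a matrix `hyper` with
#'   columns `mu_p`, `tau_p`.
#' @export
fit_naive <- function(panel, priors = prior_spec(), config = chain_config(),
                      hyper_fixed = NULL, verbose = FALSE) {
  panel <- panel_responders(panel)
  if (nrow(panel) == 0)
    stop_bbmiss("no examiner with an observed response", "bbmiss_input_error")
  R <- panel$R; E <- panel$E_obs; I <- nrow(panel)
  sample_hyper <- is.null(hyper_fixed)
  if (!sample_hyper) require_blocks(hyper_fixed, "p")
  keep <- keep_index(config)

  one_chain <- function() {
    hs <- new_mh_state(mu = 0.2, tau = 2)
    if (!sample_hyper) { hs$mu <- hyper_fixed$mu_p; hs$tau <- hyper_fixed$tau_p }
    p <- rep(0.1, I)
    P <- matrix(NA_real_, length(keep), I)
    H <- if (sample_hyper) matrix(NA_real_, length(keep), 2) else NULL
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      a <- hs$mu * hs$tau; b <- (1 - hs$mu) * hs$tau
      p <- clamp01(rbeta(I, a + E, b + R - E))
      if (sample_hyper) {
        hs <- mh_update_block(p, hs, priors)
        if (it <= config$n_burn) hs <- mh_adapt(hs)
      }
      if (it > config$n_burn && (it - config$n_burn - 1L) %% config$thin == 0L) {
        k <- k + 1L
        P[k, ] <- p
        if (sample_hyper) H[k, ] <- c(hs$mu, hs$tau)
      }
      if (verbose && it %% 1000L == 0L)
        log_msg("naive: iteration %d/%d%s", it, config$n_iter,
                if (sample_hyper)
                  sprintf(", (mu_p, tau_p) acceptance %.2f",
                          hs$c_acc / max(1, hs$c_try)) else "")
    }
    out <- list(p = P)
    if (sample_hyper) {
      colnames(H) <- c("mu_p", "tau_p")
      out$hyper <- H
    }
    out
  }
  chains <- run_chains(config, one_chain)
  new_posterior_draws("naive", chains, panel, config,
                      hyper = if (sample_hyper) NULL else hyper_fixed)
}

#' Fit the ignorable-missingness hierarchical model
#'
#' Adds a response process independent of errors:
#' `R[i] ~ Binomial(J[i], pi[i])` with its own beta population, while the
#' error probabilities are informed by observed errors only (unanswered
#' items carry no information about `p[i]` under ignorability).  Examiners
#' with `R[i] = 0` draw `p[i]` from the current population distribution.
#' Conjugate draws for all probabilities; Metropolis blocks for
#' `(mu_p, tau_p)` and `(mu_pi, tau_pi)` unless `hyper_fixed` is given.
#'
#' @inheritParams fit_naive
#' @param hyper_fixed optional [hyperparams()] with blocks `p` and `pi`.
#' @return A `posterior_draws` object; chains hold matrices `p`, `pi` and,
#'   when sampled, `hyper` with columns `mu_p`, `tau_p`, `mu_pi`, `tau_pi`.
#' @export
fit_ignorable <- function(panel, priors = prior_spec(), config = chain_config(),
                          hyper_fixed = NULL, verbose = FALSE) {
  if (nrow(panel) == 0) stop_bbmiss("empty panel", "bbmiss_input_error")
  J <- panel$J; R <- panel$R; E <- panel$E_obs; I <- nrow(panel)
  sample_hyper <- is.null(hyper_fixed)
  if (!sample_hyper) require_blocks(hyper_fixed, c("p", "pi"))
  keep <- keep_index(config)

  one_chain <- function() {
    hp <- new_mh_state(0.2, 2); hr <- new_mh_state(0.5, 2)
    if (!sample_hyper) {
      hp$mu <- hyper_fixed$mu_p; hp$tau <- hyper_fixed$tau_p
      hr$mu <- hyper_fixed$mu_pi; hr$tau <- hyper_fixed$tau_pi
    }
    P <- matrix(NA_real_, length(keep), I)
    PI <- matrix(NA_real_, length(keep), I)
    H <- if (sample_hyper) matrix(NA_real_, length(keep), 4) else NULL
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      ap <- hp$mu * hp$tau; bp <- (1 - hp$mu) * hp$tau
      ar <- hr$mu * hr$tau; br <- (1 - hr$mu) * hr$tau
      p <- clamp01(rbeta(I, ap + E, bp + R - E))
      pi <- clamp01(rbeta(I, ar + R, br + J - R))
      if (sample_hyper) {
        hp <- mh_update_block(p, hp, priors)
        hr <- mh_update_block(pi, hr, priors)
        if (it <= config$n_burn) { hp <- mh_adapt(hp); hr <- mh_adapt(hr) }
      }
      if (it > config$n_burn && (it - config$n_burn - 1L) %% config$thin == 0L) {
        k <- k + 1L
        P[k, ] <- p; PI[k, ] <- pi
        if (sample_hyper) H[k, ] <- c(hp$mu, hp$tau, hr$mu, hr$tau)
      }
      if (verbose && it %% 1000L == 0L)
        log_msg("ignorable: iteration %d/%d%s", it, config$n_iter,
                if (sample_hyper)
                  sprintf(", acceptance p-block %.2f, pi-block %.2f",
                          hp$c_acc / max(1, hp$c_try),
                          hr$c_acc / max(1, hr$c_try)) else "")
    }
    out <- list(p = P, pi = PI)
    if (sample_hyper) {
      colnames(H) <- c("mu_p", "tau_p", "mu_pi", "tau_pi")
      out$hyper <- H
    }
    out
  }
  chains <- run_chains(config, one_chain)
  new_posterior_draws("ignorable", chains, panel, config,
                      hyper = if (sample_hyper) NULL else hyper_fixed)
}

#' Fit the non-ignorable selection model (empirical Bayes)
#'
#' Hyperparameters are held fixed (normally at the marginal MLE from
#' [fit_eb_mle()]); the Gibbs sampler augments the data with the latent
#' number `z[i]` of errors among each examiner's unanswered items:
#'
#' 1. `z[i] ~ Binomial(J[i] - R[i], q[i])` with
#'    `q[i] = p[i](1 - pi2[i]) / [p[i](1 - pi2[i]) + (1 - p[i])(1 - pi1[i])]`;
#' 2. `p[i] | . ~ Beta(a_p + E[i] + z[i], b_p + J[i] - E[i] - z[i])`;
#' 3. `pi1[i] | . ~ Beta(a_1 + R[i] - E[i], b_1 + J[i] - R[i] - z[i])`;
#' 4. `pi2[i] | . ~ Beta(a_2 + E[i], b_2 + z[i])`.
#'
#' All conditionals are exact, so no Metropolis step is required.
#'
#' @inheritParams fit_naive
#' @param hyper a [hyperparams()] with blocks `p`, `pi1`, `pi2`, typically
#'   `fit_eb_mle(panel)$hyper`.
#' @param keep_z also store the latent missing-error counts.
#' @return A `posterior_draws` object; chains hold matrices `p`, `pi1`,
#'   `pi2` (and `z` if requested).
#' @export
fit_nonignorable_eb <- function(panel, hyper, config = chain_config(),
                                keep_z = FALSE, verbose = FALSE) {
  if (nrow(panel) == 0) stop_bbmiss("empty panel", "bbmiss_input_error")
  require_blocks(hyper, c("p", "pi1", "pi2"))
  J <- panel$J; R <- panel$R; E <- panel$E_obs; I <- nrow(panel)
  M <- J - R
  ap <- hyper$mu_p * hyper$tau_p;     bp <- (1 - hyper$mu_p) * hyper$tau_p
  a1 <- hyper$mu_pi1 * hyper$tau_pi1; b1 <- (1 - hyper$mu_pi1) * hyper$tau_pi1
  a2 <- hyper$mu_pi2 * hyper$tau_pi2; b2 <- (1 - hyper$mu_pi2) * hyper$tau_pi2
  keep <- keep_index(config)

  one_chain <- function() {
    p <- clamp01(rbeta(I, ap, bp))
    pi1 <- clamp01(rbeta(I, a1, b1))
    pi2 <- clamp01(rbeta(I, a2, b2))
    P <- matrix(NA_real_, length(keep), I)
    P1 <- matrix(NA_real_, length(keep), I)
    P2 <- matrix(NA_real_, length(keep), I)
    Z <- if (keep_z) matrix(NA_integer_, length(keep), I) else NULL
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      num <- p * (1 - pi2)
      q <- num / (num + (1 - p) * (1 - pi1))
      z <- rbinom(I, M, q)
      p <- clamp01(rbeta(I, ap + E + z, bp + J - E - z))
      pi1 <- clamp01(rbeta(I, a1 + R - E, b1 + M - z))
      pi2 <- clamp01(rbeta(I, a2 + E, b2 + z))
      if (it > config$n_burn && (it - config$n_burn - 1L) %% config$thin == 0L) {
        k <- k + 1L
        P[k, ] <- p; P1[k, ] <- pi1; P2[k, ] <- pi2
        if (keep_z) Z[k, ] <- z
      }
      if (verbose && it %% 1000L == 0L)
        log_msg("nonignorable: iteration %d/%d (all conditionals conjugate)",
                it, config$n_iter)
    }
    out <- list(p = P, pi1 = P1, pi2 = P2)
    if (keep_z) out$z <- Z
    out
  }
  chains <- run_chains(config, one_chain)
  new_posterior_draws("nonignorable", chains, panel, config, hyper = hyper)
}

#' Export posterior draws as a long-format table
#'
#' Columns `chain`, `iter` (index among kept draws), `parameter`, `value`;
#' parameters are named e.g. `p[ex3]`, `pi2[ex10]`, `mu_p`.
#'
#' @param draws a `posterior_draws` object.
#' @param path optional CSV path; if given, the table is also written there.
#' @return The long data frame, invisibly if `path` is given.
#' @export
draws_to_long <- function(draws, path = NULL) {
  out <- list()
  for (c in seq_along(draws$chains)) {
    ch <- draws$chains[[c]]
    for (par in names(ch)) {
      m <- ch[[par]]
      cols <- colnames(m) %||% paste0(par, "[", draws$examiner_id, "]")
      if (par == "hyper") cols <- colnames(m)
      out[[length(out) + 1L]] <- data.frame(
        chain = c,
        iter = rep(seq_len(nrow(m)), times = ncol(m)),
        parameter = rep(cols, each = nrow(m)),
        value = as.vector(m))
    }
  }
  long <- do.call(rbind, out)
  if (!is.null(path)) {
    write.csv(long, path, row.names = FALSE, quote = FALSE)
    return(invisible(long))
  }
  long
}
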