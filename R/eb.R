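#' Empirical-Bayes hyperparameter estimation for the non-ignorable model
#'
#' Maximizes the log marginal likelihood [log_marginal_nonignorable()] over
#' the six hyperparameters `(mu_p, tau_p, mu_pi1, tau_pi1, mu_pi2, tau_pi2)`.
#' Optimization runs on an unconstrained scale — logit for each mean
#' (rescaled to its truncation interval) and shifted log for each
#' concentration — with Nelder-Mead from multiple dispersed starts.  The
#' starts are stratified so that `mu_pi2` begins both near zero and near
#' `mu_pi1`: the surface can be multimodal when response and error rates are
#' correlated, and in sparse-error panels the maximum is often close to the
#' boundary.  Estimates within `boundary_tol` of a truncation bound are
#' flagged rather than hidden.
#'
#' @param panel a `study_panel` with at least one examiner with `R > 0`.
#' @param n_starts number of optimization starts (default 20).
#' @param starts optional list of [hyperparams()] objects used as starts
#'   (overrides `n_starts`).
#' @param mu_bounds,tau_bounds truncation intervals for every mean and
#'   concentration (defaults `(0.001, 0.999)` and `(0.001, 1e6)`).
#' @param boundary_tol estimates closer than this to a bound are flagged.
#' @param control passed to [stats::optim()] (Nelder-Mead); sensible
#'   defaults (`maxit = 3000`, `reltol = 1e-12`) are merged in.
#' @param seed integer seed for the jitter applied to the start grid.
#' @return An object of class `eb_fit`: list with elements `hyper` (the MLE
#'   as a [hyperparams()] object), `logML`, `n_starts`, `boundary_flags`
#'   (character vector of flagged parameters), `converged` (any start
#'   converged), and `starts` (data frame of per-start results).
#' @seealso [fit_nonignorable_eb()] which consumes the fitted values.
#' @export
fit_eb_mle <- function(panel, n_starts = 20, starts = NULL,
                       mu_bounds = c(0.001, 0.999),
                       tau_bounds = c(0.001, 1e6),
                       boundary_tol = 1e-3, control = list(), seed = 1) {
  if (sum(panel$R > 0) < 1)
    stop_bbmiss("need at least one examiner with an observed response",
                "bbmiss_input_error")
  st <- panel_suffstats(panel)

  mu_lo <- mu_bounds[1]; mu_hi <- mu_bounds[2]
  tau_lo <- tau_bounds[1]; tau_hi <- tau_bounds[2]
  to_mu  <- function(th) mu_lo + (mu_hi - mu_lo) * stats::plogis(th)
  fr_mu  <- function(mu) stats::qlogis((pmin(pmax(mu, mu_lo + 1e-12),
                                             mu_hi - 1e-12) - mu_lo) /
                                         (mu_hi - mu_lo))
  to_tau <- function(th) tau_lo + exp(th)
  fr_tau <- function(tau) log(pmax(tau - tau_lo, 1e-12))

  unpack <- function(th)
    hyperparams(mu_p = to_mu(th[1]), tau_p = to_tau(th[2]),
                mu_pi1 = to_mu(th[3]), tau_pi1 = to_tau(th[4]),
                mu_pi2 = to_mu(th[5]), tau_pi2 = to_tau(th[6]))
  pack <- function(hp)
    c(fr_mu(hp$mu_p), fr_tau(hp$tau_p), fr_mu(hp$mu_pi1), fr_tau(hp$tau_pi1),
      fr_mu(hp$mu_pi2), fr_tau(hp$tau_pi2))

  negll <- function(th) {
    if (any(!is.finite(th)) || to_tau(max(th[c(2, 4, 6)])) > tau_hi)
      return(1e10)
    val <- log_marginal_nonignorable(st_panel(st), unpack(th))
    if (!is.finite(val)) 1e10 else -val
  }

  if (is.null(starts)) starts <- default_starts(st, n_starts, seed)
  ctl <- modifyList(list(maxit = 3000, reltol = 1e-12), control)

  rows <- vector("list", length(starts))
  best <- NULL
  for (s in seq_along(starts)) {
    th0 <- pack(starts[[s]])
    fit <- tryCatch(optim(th0, negll, method = "Nelder-Mead", control = ctl),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[s]] <- data.frame(start = s, logML = NA_real_, converged = FALSE)
      next
    }
    rows[[s]] <- data.frame(start = s, logML = -fit$value,
                            converged = fit$convergence == 0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_bbmiss("all optimization starts failed", "bbmiss_fit_error")
  # polish the incumbent from its own optimum
  pol <- tryCatch(optim(best$par, negll, method = "Nelder-Mead", control = ctl),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol

  hp <- unpack(best$par)
  flags <- character(0)
  for (nm in c("mu_p", "mu_pi1", "mu_pi2")) {
    if (hp[[nm]] - mu_lo < boundary_tol) flags <- c(flags, paste0(nm, ":lower"))
    if (mu_hi - hp[[nm]] < boundary_tol) flags <- c(flags, paste0(nm, ":upper"))
  }
  for (nm in c("tau_p", "tau_pi1", "tau_pi2"))
    if (hp[[nm]] - tau_lo < boundary_tol) flags <- c(flags, paste0(nm, ":lower"))

  res <- list(hyper = hp, logML = -best$value,
              n_starts = length(starts),
              boundary_flags = flags,
              converged = any(vapply(rows, function(r) isTRUE(r$converged),
                                     logical(1))),
              starts = do.call(rbind, rows),
              mu_bounds = mu_bounds, tau_bounds = tau_bounds)
  class(res) <- "eb_fit"
  res
}

# wrap aggregated sufficient statistics as a panel-like frame whose weight
# column panel_suffstats() preserves (avoids re-tabulating inside optim)
st_panel <- function(st) {
  structure(data.frame(J = st$J, R = st$R, E_obs = st$E, .w = st$w),
            class = c("suffstat_panel", "data.frame"))
}

default_starts <- function(st, n_starts, seed) {
  # crude moment anchors from the observed panel
  obs_err <- sum(st$w * st$E) / max(1, sum(st$w * st$R))
  obs_resp <- sum(st$w * st$R) / max(1, sum(st$w * st$J))
  anchor_mu_p <- min(max(obs_err, 0.01), 0.9)
  anchor_pi <- min(max(obs_resp, 0.05), 0.95)
  grid <- expand.grid(mu_p = unique(c(anchor_mu_p, 0.05, 0.3)),
                      tau_p = c(1, 8),
                      mu_pi1 = unique(c(anchor_pi, 0.8)),
                      tau_pi1 = c(0.5, 4),
                      mu_pi2_mode = c("low", "high"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx <- rep_len(seq_len(nrow(grid)), n_starts)
  lapply(seq_len(n_starts), function(k) {
    g <- grid[idx[k], ]
    jit <- function(x, f = 0.25) x * exp(runif(1, -f, f))
    mu_pi2 <- if (g$mu_pi2_mode == "low") runif(1, 0.005, 0.05) else
      min(0.99, jit(g$mu_pi1))
    hyperparams(mu_p = min(0.99, max(0.002, jit(g$mu_p))),
                tau_p = jit(g$tau_p, 0.5),
                mu_pi1 = min(0.99, max(0.002, jit(g$mu_pi1))),
                tau_pi1 = jit(g$tau_pi1, 0.5),
                mu_pi2 = mu_pi2, tau_pi2 = jit(2, 0.5))
  })
}

#' @export
print.eb_fit <- function(x, ...) {
  cat(sprintf("empirical-Bayes MLE (non-ignorable model), log marginal = %.4f\n",
              x$logML))
  print(x$hyper)
  cat(sprintf("  starts: %d (converged: %s)\n", x$n_starts,
              if (x$converged) "yes" else "NO"))
  if (length(x$boundary_flags))
    cat("  at/near truncation boundary:", paste(x$boundary_flags, collapse = ", "),
        "\n")
  invisible(x)
}

#' Serialize an empirical-Bayes fit to a flat JSON file
#'
#' Writes fields `mu_p, tau_p, mu_pi1, tau_pi1, mu_pi2, tau_pi2, logML,
#' n_starts, boundary_flags`.
#'
#' @param fit an `eb_fit` from [fit_eb_mle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hyperparams <- function(fit, path) {
  out <- c(as.list(fit$hyper),
           list(logML = fit$logML, n_starts = fit$n_starts,
                boundary_flags = I(fit$boundary_flags)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read hyperparameters from a JSON file written by [write_hyperparams()]
#'
#' @param path input path.
#' @return A [hyperparams()] object.
#' @export
read_hyperparams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(x), c("mu_p", "tau_p", "mu_pi", "tau_pi",
                                "mu_pi1", "tau_pi1", "mu_pi2", "tau_pi2"))
  do.call(hyperparams, lapply(x[keep], as.numeric))
}
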