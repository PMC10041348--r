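#' Batch-means Monte Carlo standard error
#'
#' Nonoverlapping batch-means estimator of the Monte Carlo standard error of
#' a chain's sample mean: with `n` draws, batch size `b = floor(sqrt(n))`,
#' `a = floor(n / b)` batches, the MCSE is
#' `sqrt(b * var(batch means) / n)` computed on the first `a * b` draws.
#'
#' @param x numeric vector, one parameter's draws from one chain
#'   (length >= 4).
#' @return Nonnegative scalar.
#' @export
batch_means_mcse <- function(x) {
  n <- length(x)
  if (n < 4) stop_bbmiss("chain too short for batch means (need >= 4)",
                         "bbmiss_input_error")
  b <- floor(sqrt(n))
  a <- n %/% b
  bm <- colMeans(matrix(x[seq_len(a * b)], nrow = b))
  sqrt(b * var(bm) / (a * b))
}

#' Multivariate Gelman-Rubin diagnostic
#'
#' Brooks-Gelman multivariate potential scale reduction factor (MPSRF) over
#' the monitored parameters,
#' `(n - 1)/n + (m + 1)/m * lambda_1`, where `lambda_1` is the largest
#' eigenvalue of `W^{-1} B / n` (`W` pooled within-chain covariance, `B/n`
#' between-chain covariance of the means).  If the pooled covariance is
#' singular (more monitored parameters than effective draws) the function
#' falls back to the maximum univariate PSRF and flags it via the
#' `"fallback"` attribute.
#'
#' @param chains either a `posterior_draws` object (all probability
#'   parameters are monitored) or a list of draw matrices (iterations x
#'   parameters), one per chain, with equal dimensions.
#' @return Scalar >= 1 (up to numerical tolerance), with attribute
#'   `"fallback"` (logical).
#' @export
gelman_rubin_multivariate <- function(chains) {
  mats <- if (inherits(chains, "posterior_draws"))
    monitored_matrices(chains) else chains
  m <- length(mats)
  if (m < 2) stop_bbmiss("need at least two chains", "bbmiss_input_error")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_bbmiss("chains must have identical dimensions", "bbmiss_input_error")
  n <- dims[1, 1]; p <- dims[2, 1]

  means <- t(vapply(mats, colMeans, numeric(p)))
  W <- Reduce(`+`, lapply(mats, function(x) stats::cov(x))) / m
  Bn <- stats::cov(means)  # = B / n

  mpsrf_uni <- function() {
    psrf <- vapply(seq_len(p), function(j) {
      w <- mean(vapply(mats, function(x) var(x[, j]), numeric(1)))
      bn <- var(means[, j])
      if (w <= 0) return(1)
      sqrt((n - 1) / n + (m + 1) / m * bn / w)
    }, numeric(1))
    structure(max(psrf), fallback = TRUE)
  }

  if (p > (n - 1) * m) return(mpsrf_uni())
  lam <- tryCatch({
    ev <- eigen(solve(W, Bn), symmetric = FALSE, only.values = TRUE)$values
    max(Re(ev))
  }, error = function(e) NA_real_)
  if (!is.finite(lam) || lam < 0) return(mpsrf_uni())
  structure((n - 1) / n + (m + 1) / m * lam, fallback = FALSE)
}

# stack each chain's monitored probability parameters into one matrix
monitored_matrices <- function(draws) {
  pars <- intersect(c("p", "pi", "pi1", "pi2"), names(draws$chains[[1]]))
  lapply(draws$chains, function(ch) do.call(cbind, ch[pars]))
}

#' Convergence report for a set of chains
#'
#' Computes the per-parameter batch-means MCSE (maximum over chains) for
#' every monitored probability parameter and the multivariate Gelman-Rubin
#' statistic, and checks them against thresholds: MCSE below `mcse_threshold`
#' for all parameters and MPSRF below `gr_threshold`.
#'
#' @param draws a `posterior_draws` object with >= 2 chains.
#' @param mcse_threshold default 0.01.
#' @param gr_threshold default 1.1 for the naive/ignorable models and 1.2
#'   for the non-ignorable model.
#' @return A list of class `convergence_report` with elements `mcse`
#'   (named vector), `max_mcse`, `gelman_rubin`, `gr_fallback`, thresholds,
#'   and `pass` (logical).
#' @export
convergence_report <- function(draws, mcse_threshold = 0.01,
                               gr_threshold = NULL) {
  if (is.null(gr_threshold))
    gr_threshold <- if (draws$model == "nonignorable") 1.2 else 1.1
  mats <- monitored_matrices(draws)
  pars <- intersect(c("p", "pi", "pi1", "pi2"), names(draws$chains[[1]]))
  nms <- unlist(lapply(pars, function(par)
    paste0(par, "[", draws$examiner_id, "]")))
  mcse <- apply(vapply(mats, function(x)
    apply(x, 2, batch_means_mcse), numeric(ncol(mats[[1]]))), 1, max)
  names(mcse) <- nms
  gr <- if (length(mats) >= 2) gelman_rubin_multivariate(mats) else NA_real_
  out <- list(mcse = mcse, max_mcse = max(mcse),
              gelman_rubin = as.numeric(gr),
              gr_fallback = isTRUE(attr(gr, "fallback")),
              mcse_threshold = mcse_threshold, gr_threshold = gr_threshold,
              pass = max(mcse) < mcse_threshold &&
                (!is.na(gr) && as.numeric(gr) < gr_threshold))
  class(out) <- "convergence_report"
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence: max batch-means MCSE = %.4g (threshold %.3g)\n",
              x$max_mcse, x$mcse_threshold))
  cat(sprintf("  multivariate Gelman-Rubin = %.4f (threshold %.3g)%s\n",
              x$gelman_rubin, x$gr_threshold,
              if (x$gr_fallback) " [univariate fallback]" else ""))
  cat(sprintf("  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a convergence report as flat JSON
#'
#' @param report a `convergence_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_convergence <- function(report, path) {
  jsonlite::write_json(list(max_mcse = report$max_mcse,
                            gelman_rubin = report$gelman_rubin,
                            gr_fallback = report$gr_fallback,
                            mcse_threshold = report$mcse_threshold,
                            gr_threshold = report$gr_threshold,
                            pass = report$pass),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
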