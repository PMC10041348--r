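# build a posterior_draws object with prescribed constant draws, for
# predictive identities that need exact control of the posterior
constant_draws <- function(model, J, R, p, resp = NULL, n = 4000) {
  I <- length(J)
  pan <- panel_from_counts(J, R, pmin(R, 0L))
  ch <- list(p = matrix(p, n, I, byrow = TRUE))
  if (model == "ignorable") ch$pi <- matrix(resp, n, I, byrow = TRUE)
  if (model == "nonignorable") {
    ch$pi1 <- matrix(resp, n, I, byrow = TRUE)
    ch$pi2 <- matrix(resp, n, I, byrow = TRUE)
  }
  bbmiss:::new_posterior_draws(model, list(ch), pan,
                               chain_config(1, 2, 1, seed = 1))
}

test_that("degenerate zero-error posterior gives a degenerate predictive", {
  d <- constant_draws("nonignorable", J = c(10, 10), R = c(6, 8),
                      p = c(1e-300, 1e-300), resp = c(0.5, 0.5))
  pe <- pe_predictive(d, seed = 1)
  expect_true(all(pe$draws == 0))
  expect_equal(c(pe$mean, pe$lower, pe$upper), c(0, 0, 0))
})

test_that("predictive mean matches the analytic binomial-mixture mean for a fixed draw", {
  J <- c(22L, 22L, 22L); R <- c(20L, 10L, 2L)
  p <- c(0.3, 0.1, 0.25); pi2 <- c(0.6, 0.2, 0.4)
  d <- constant_draws("nonignorable", J, R, p, pi2, n = 20000)
  pe <- pe_predictive(d, seed = 2)
  analytic <- sum(R * p * pi2 + (J - R) * p * (1 - pi2)) / sum(J)
  expect_lt(abs(pe$mean - analytic), 3 * sd(pe$draws) / sqrt(length(pe$draws)) + 1e-4)
  # ignorable uses its single response block the same way
  di <- constant_draws("ignorable", J, R, p, pi2, n = 20000)
  pei <- pe_predictive(di, seed = 3)
  expect_lt(abs(pei$mean - analytic),
            3 * sd(pei$draws) / sqrt(length(pei$draws)) + 1e-4)
  # interval endpoints are the empirical 2.5%/97.5% quantiles of the draws
  expect_equal(pe$lower, quantile(pe$draws, 0.025, names = FALSE))
  expect_equal(pe$upper, quantile(pe$draws, 0.975, names = FALSE))
})

test_that("naive predictive uses responded items only as its denominator", {
  J <- c(22L, 22L); R <- c(20L, 5L); p <- c(0.5, 0.5)
  d <- constant_draws("naive", J, R, p)
  pe <- pe_predictive(d, seed = 4)
  expect_equal(pe$denom, sum(R))
  expect_lt(abs(pe$mean - 0.5), 0.01)
  expect_true(all(pe$draws >= 0 & pe$draws <= 1))
})

test_that("ignorable predictive concentrates relative to naive on an MCAR panel", {
  hp <- hyperparams(mu_p = 0.1, tau_p = 10, mu_pi1 = 0.6, tau_pi1 = 8,
                    mu_pi2 = 0.6, tau_pi2 = 8)
  st <- generate_study(generator_config(I = 220, J = 22, hyper = hp,
                                        mechanism = "mcar", seed = 31))
  pan <- build_panel(st$records, st$assignments, include_unit_nonrespondents = TRUE)
  cfg <- chain_config(2, 5000, 1500, seed = 6)
  pe_n <- pe_predictive(fit_naive(pan, config = cfg), seed = 7)
  pe_i <- pe_predictive(fit_ignorable(pan, config = cfg), seed = 7)
  expect_lt(pe_i$upper - pe_i$lower, pe_n$upper - pe_n$lower)
})

test_that("naive and ignorable predictive means agree under an ignorable mechanism", {
  # dispersed (U-shaped) response probabilities: the regime in which the
  # predictive identities leave no systematic gap between the two models
  hp <- hyperparams(mu_p = 0.1, tau_p = 10, mu_pi1 = 0.6, tau_pi1 = 0.4,
                    mu_pi2 = 0.6, tau_pi2 = 0.4)
  st <- generate_study(generator_config(I = 220, J = 22, hyper = hp,
                                        mechanism = "ignorable", seed = 31))
  pan <- build_panel(st$records, st$assignments, include_unit_nonrespondents = TRUE)
  cfg <- chain_config(2, 5000, 1500, seed = 6)
  pe_n <- pe_predictive(fit_naive(pan, config = cfg), seed = 7)
  pe_i <- pe_predictive(fit_ignorable(pan, config = cfg), seed = 7)
  expect_lt(abs(pe_i$mean - pe_n$mean), 2 * sd(pe_n$draws))
  expect_lt(pe_i$upper - pe_i$lower, pe_n$upper - pe_n$lower)
})

test_that("examiner posterior intervals: degenerate, conjugate, and ordering checks", {
  d <- constant_draws("naive", c(10L, 10L), c(10L, 10L), c(0.2, 0.3))
  ci <- examiner_posterior_interval(d, "ex1")
  expect_equal(unname(ci), c(0.2, 0.2, 0.2))
  expect_error(examiner_posterior_interval(d, "nobody"),
               class = "bbmiss_input_error")

  # single-examiner conjugate case: interval matches Beta quantiles
  pan <- panel_from_counts(22, 22, 1)
  dd <- fit_naive(pan, config = chain_config(2, 12000, 2000, seed = 12),
                  hyper_fixed = hyperparams(mu_p = 0.5, tau_p = 2))
  ci <- examiner_posterior_interval(dd, "ex1")
  expect_equal(ci[["lower"]], qbeta(0.025, 2, 22), tolerance = 0.02)
  expect_equal(ci[["upper"]], qbeta(0.975, 2, 22), tolerance = 0.02)

  # an examiner observed at 2/12 sits above one at 1/22 in the same fit
  pan2 <- panel_from_counts(c(22, 22), c(22, 12), c(1, 2),
                            examiner_id = c("A", "B"))
  d2 <- fit_naive(pan2, config = chain_config(2, 8000, 2000, seed = 13))
  expect_gt(examiner_posterior_interval(d2, "B")[["mean"]],
            examiner_posterior_interval(d2, "A")[["mean"]])
})

test_that("Clopper-Pearson reproduces closed forms, boundaries, and tail inversion", {
  cp <- clopper_pearson(12, 2560)
  expect_equal(cp$point, 12 / 2560)
  expect_equal(round(100 * cp$point, 1), 0.5)
  expect_equal(round(100 * c(cp$lower, cp$upper), 1), c(0.2, 0.8))
  cp2 <- clopper_pearson(12, 1785)
  expect_equal(round(100 * cp2$point, 1), 0.7)
  expect_equal(round(100 * c(cp2$lower, cp2$upper), 1), c(0.3, 1.2))

  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(5, 0), class = "bbmiss_input_error")
  expect_error(clopper_pearson(11, 10), class = "bbmiss_input_error")

  set.seed(5)
  for (k in 1:12) {
    n <- sample(1:400, 1)
    x <- sample(0:n, 1)
    cp <- clopper_pearson(x, n)
    want <- cp_tail_oracle(x, n)
    expect_equal(cp$lower, want[["lower"]], tolerance = 1e-8)
    expect_equal(cp$upper, want[["upper"]], tolerance = 1e-8)
    expect_true(cp$lower <= cp$point && cp$point <= cp$upper)
  }
})

test_that("pe_table mirrors the summary layout with full precision retained", {
  d <- constant_draws("naive", c(10L, 10L), c(10L, 10L), c(0.2, 0.2))
  pe <- pe_predictive(d, seed = 1)
  tab <- pe_table(pe, pe)
  expect_identical(names(tab),
                   c("model", "policy", "pe_mean_pct", "lower_pct", "upper_pct",
                     "pe_mean", "lower", "upper"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$pe_mean_pct[1], round(100 * pe$mean, 1))
  expect_equal(tab$pe_mean[1], pe$mean)
})

test_that("predictive checks its inputs against the stored panel", {
  d <- constant_draws("naive", c(10L, 10L), c(8L, 8L), c(0.2, 0.2))
  wrong <- panel_from_counts(c(10, 10), c(7, 8), c(0, 0))
  expect_error(pe_predictive(d, panel = wrong), class = "bbmiss_input_error")
})
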