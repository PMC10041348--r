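test_that("inconclusive policy changes R but not E_obs for a partial responder", {
  st <- examiner_ab_study()
  obs <- build_panel(st$records, st$assignments, policy = "as_correct_observed")
  mis <- build_panel(st$records, st$assignments, policy = "as_missing")

  b_obs <- obs[obs$examiner_id == "B", ]
  expect_equal(unname(unlist(b_obs[c("J", "R", "E_obs")])), c(22L, 12L, 2L))
  b_mis <- mis[mis$examiner_id == "B", ]
  expect_equal(unname(unlist(b_mis[c("J", "R", "E_obs")])), c(22L, 11L, 2L))

  a_obs <- obs[obs$examiner_id == "A", ]
  expect_equal(unname(unlist(a_obs[c("J", "R", "E_obs")])), c(22L, 22L, 1L))
  # A answered everything definitively, so the policy cannot matter
  a_mis <- mis[mis$examiner_id == "A", ]
  expect_equal(unname(unlist(a_mis[c("J", "R", "E_obs")])),
               unname(unlist(a_obs[c("J", "R", "E_obs")])))
})

test_that("unit non-respondents are dropped by default but representable", {
  st <- examiner_ab_study()
  asg <- rbind(st$assignments, data.frame(examiner_id = "C", n_assigned = 22L))
  dropped <- build_panel(st$records, asg, policy = "as_correct_observed")
  expect_false("C" %in% dropped$examiner_id)
  kept <- build_panel(st$records, asg, policy = "as_correct_observed",
                      include_unit_nonrespondents = TRUE)
  cc <- kept[kept$examiner_id == "C", ]
  expect_equal(unname(unlist(cc[c("J", "R", "E_obs")])), c(22L, 0L, 0L))
  expect_equal(attr(kept, "I"), 3L)
  expect_equal(attr(kept, "I_star"), 2L)  # C responded nowhere
})

test_that("hand-enumerated three-examiner toy tallies under both policies", {
  rec <- bind_records(
    make_examiner_records("e1", 4, n_ident = 1, n_excl = 2, n_inc = 1),
    make_examiner_records("e2", 4, n_excl = 1, n_nv = 2),
    make_examiner_records("e3", 4, n_ident = 2, n_excl = 2))
  asg <- data.frame(examiner_id = c("e1", "e2", "e3"), n_assigned = 4L)
  obs <- build_panel(rec, asg, policy = "as_correct_observed")
  # e1: inconclusive observed-correct -> R=4, E=1; e2: no_value always
  # missing -> R=1, E=0; e3: fully answered, 2 errors
  expect_equal(obs$R, c(4L, 1L, 4L))
  expect_equal(obs$E_obs, c(1L, 0L, 2L))
  mis <- build_panel(rec, asg, policy = "as_missing")
  expect_equal(mis$R, c(3L, 1L, 4L))
  expect_equal(mis$E_obs, c(1L, 0L, 2L))
  expect_equal(attr(obs, "J_total"), 12L)
})

test_that("same-source stratum uses the symmetric error definition", {
  rec <- decision_records(rep("s1", 3), paste0("it", 1:3), "same_source",
                          c("exclusion", "identification", "inconclusive"))
  asg <- data.frame(examiner_id = "s1", n_assigned = 5L)
  pan <- build_panel(rec, asg, policy = "as_correct_observed",
                     stratum = "same_source")
  # an exclusion on a same-source item is the error (false negative)
  expect_equal(pan$E_obs, 1L)
  expect_equal(pan$R, 3L)
})

test_that("pooled non-response rate is 1 - R_total/J_total", {
  pan <- counts_panel_from_totals(2560)
  expect_equal(attr(pan, "J_total"), 4972L)
  expect_equal(nonresponse_rate(pan), 1 - 2560 / 4972)
  pan2 <- counts_panel_from_totals(1785, policy = "as_missing")
  expect_equal(nonresponse_rate(pan2), 1 - 1785 / 4972)
  full <- panel_from_counts(c(5, 5), c(5, 5), c(0, 1))
  expect_equal(nonresponse_rate(full), 0)
  expect_error(nonresponse_rate(panel_from_counts(0L, 0L, 0L)),
               class = "bbmiss_input_error")
  # zero-examiner panels are representable and also rejected here
  expect_error(nonresponse_rate(panel_from_counts(integer(0), integer(0), integer(0))),
               class = "bbmiss_input_error")
})

test_that("per-examiner empirical rates and their failure modes", {
  pan <- panel_from_counts(J = c(22, 22, 10), R = c(22, 12, 0),
                           E_obs = c(1, 2, 0),
                           examiner_id = c("A", "B", "Z"))
  expect_equal(empirical_error_rate(pan, "A"), 1 / 22)
  expect_equal(empirical_error_rate(pan, "B"), 2 / 12)
  expect_equal(examiner_nonresponse_rate(pan, "B"), 10 / 22)
  expect_error(empirical_error_rate(pan, "Z"), class = "bbmiss_input_error")
  expect_error(empirical_error_rate(pan, "nope"), class = "bbmiss_input_error")
})

test_that("malformed inputs are rejected", {
  st <- examiner_ab_study()
  # record for an examiner not covered by assignments
  expect_error(build_panel(st$records,
                           data.frame(examiner_id = "A", n_assigned = 22L)),
               class = "bbmiss_input_error")
  # more records than assigned items
  expect_error(build_panel(st$records,
                           data.frame(examiner_id = c("A", "B"),
                                      n_assigned = c(5L, 22L))),
               class = "bbmiss_input_error")
  # unknown decision vocabulary
  bad <- as.data.frame(st$records)
  bad$decision[1] <- "maybe"
  expect_error(build_panel(bad, st$assignments), class = "bbmiss_input_error")
  # duplicate (examiner, item)
  dup <- rbind(as.data.frame(st$records), as.data.frame(st$records)[1, ])
  expect_error(bbmiss:::validate_decision_records(dup),
               class = "bbmiss_input_error")
})

test_that("panel construction is deterministic, order-invariant, and self-consistent", {
  for (seed in c(2, 9)) {
    study <- generate_study(generator_config(
      I = 40, J = 8,
      hyper = hyperparams(mu_p = 0.25, tau_p = 3, mu_pi1 = 0.7, tau_pi1 = 2,
                          mu_pi2 = 0.15, tau_pi2 = 2),
      mechanism = "nonignorable", inconclusive_rate = 0.2,
      no_value_rate = 0.1, seed = seed))
    rec <- study$records
    for (policy in c("as_correct_observed", "as_missing")) {
      pan <- build_panel(rec, study$assignments, policy = policy,
                         include_unit_nonrespondents = TRUE)
      expect_true(all(pan$E_obs <= pan$R))
      expect_true(all(pan$R <= pan$J))
      expect_equal(attr(pan, "I_star"), sum(pan$R > 0))
      expect_equal(attr(pan, "J_total"), sum(pan$J))
      expect_equal(attr(pan, "R_total"), sum(pan$R))
      # permutation invariance over record order
      shuf <- as.data.frame(rec)[sample(nrow(rec)), ]
      pan2 <- build_panel(shuf, study$assignments, policy = policy,
                          include_unit_nonrespondents = TRUE)
      expect_identical(as.data.frame(pan), as.data.frame(pan2))
    }
    obs <- build_panel(rec, study$assignments, policy = "as_correct_observed",
                       include_unit_nonrespondents = TRUE)
    mis <- build_panel(rec, study$assignments, policy = "as_missing",
                       include_unit_nonrespondents = TRUE)
    expect_true(all(mis$R <= obs$R))         # reclassifying never adds responses
    expect_identical(mis$E_obs, obs$E_obs)   # and never changes observed errors
  }
})

test_that("responders-only restriction recomputes totals", {
  pan <- panel_from_counts(c(22, 22, 22), c(22, 12, 0), c(1, 2, 0))
  rs <- panel_responders(pan)
  expect_equal(attr(rs, "I"), 2L)
  expect_equal(attr(rs, "I_star"), 2L)
  expect_equal(attr(rs, "J_total"), 44L)
  expect_equal(attr(rs, "R_total"), 34L)
  expect_identical(attr(rs, "policy"), attr(pan, "policy"))
})

test_that("panel CSV round-trips through the documented schema", {
  pan <- counts_panel_from_totals(300, I = 20, E_total = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_panel_csv(pan, path)
  got <- read.csv(path)
  expect_identical(names(got), c("examiner_id", "J", "R", "E_obs"))
  expect_equal(got$R, pan$R)
})
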