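# record-set builders used across tests

# an examiner who answered `n_excl` exclusions, `n_ident` identifications
# (errors on different-source items), `n_inc` inconclusives, `n_nv` no-value
# determinations, out of `assigned` different-source items
make_examiner_records <- function(id, assigned, n_ident = 0, n_excl = 0,
                                  n_inc = 0, n_nv = 0) {
  dec <- c(rep("identification", n_ident), rep("exclusion", n_excl),
           rep("inconclusive", n_inc), rep("no_value", n_nv))
  stopifnot(length(dec) <= assigned)
  if (length(dec) == 0) return(NULL)
  decision_records(examiner_id = rep(id, length(dec)),
                   item_id = paste0(id, "_it", seq_along(dec)),
                   ground_truth = "different_source",
                   decision = dec)
}

bind_records <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  bbmiss:::validate_decision_records(do.call(rbind, lapply(parts, as.data.frame)))
}

# "Examiner A": answered all 22 items, 1 error, no inconclusives.
# "Examiner B": answered 12 items of 22, 2 errors, 1 inconclusive.
examiner_ab_study <- function() {
  list(records = bind_records(
         make_examiner_records("A", 22, n_ident = 1, n_excl = 21),
         make_examiner_records("B", 22, n_ident = 2, n_excl = 9, n_inc = 1)),
       assignments = data.frame(examiner_id = c("A", "B"),
                                n_assigned = c(22L, 22L)))
}

# per-examiner counts matching the reanalysed study's summary table:
# 226 examiners x 22 assigned = 4972 trials, with total responses 2560
# (inconclusives observed) or 1785 (inconclusives missing)
counts_panel_from_totals <- function(R_total, I = 226, J_each = 22,
                                     E_total = 12,
                                     policy = "as_correct_observed") {
  base <- R_total %/% I
  extra <- R_total - base * I
  R <- c(rep(base + 1L, extra), rep(base, I - extra))
  E <- integer(I)
  E[seq_len(E_total)] <- 1L
  stopifnot(all(E <= R))
  panel_from_counts(rep(J_each, I), R, E, policy = policy)
}
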