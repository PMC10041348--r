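#' Decision records for a black-box study
#'
#' Construct and validate the long-format table of examiner decisions: one
#' row per (examiner, item) pair that received any response.  Items assigned
#' but never answered have no record; they are recovered from the assignment
#' table when a panel is built.
#'
#' @param examiner_id character or factor, examiner identifiers.
#' @param item_id character or factor, item identifiers.
#' @param ground_truth `"same_source"` or `"different_source"` per item.
#' @param decision one of `"identification"`, `"exclusion"`,
#'   `"inconclusive"`, `"no_value"`.
#' @return A `data.frame` of class `decision_records` with the four columns
#'   above, validated: the decision vocabulary is closed and each
#'   (examiner, item) pair appears at most once.
#' @seealso [build_panel()], [read_decision_records()]
#' @export
decision_records <- function(examiner_id, item_id, ground_truth, decision) {
  df <- data.frame(examiner_id = as.character(examiner_id),
                   item_id = as.character(item_id),
                   ground_truth = as.character(ground_truth),
                   decision = as.character(decision),
                   stringsAsFactors = FALSE)
  validate_decision_records(df)
}

validate_decision_records <- function(df) {
  needed <- c("examiner_id", "item_id", "ground_truth", "decision")
  if (!all(needed %in% names(df)))
    stop_bbmiss(paste("decision records need columns:",
                      paste(needed, collapse = ", ")), "bbmiss_input_error")
  bad_gt <- setdiff(unique(df$ground_truth), c("same_source", "different_source"))
  if (length(bad_gt))
    stop_bbmiss(paste("unknown ground_truth label(s):",
                      paste(bad_gt, collapse = ", ")), "bbmiss_input_error")
  bad_dec <- setdiff(unique(df$decision),
                     c("identification", "exclusion", "inconclusive", "no_value"))
  if (length(bad_dec))
    stop_bbmiss(paste("unknown decision label(s):",
                      paste(bad_dec, collapse = ", ")), "bbmiss_input_error")
  if (anyDuplicated(df[c("examiner_id", "item_id")]))
    stop_bbmiss("duplicated (examiner_id, item_id) pair in decision records",
                "bbmiss_input_error")
  class(df) <- c("decision_records", "data.frame")
  df
}

#' Read decision records / assignment counts from CSV
#'
#' `read_decision_records()` expects header
#' `examiner_id,item_id,ground_truth,decision`; `read_assignments()` expects
#' `examiner_id,n_assigned`.  Both are plain UTF-8 comma-separated files with
#' no index column.
#'
#' @param path file path.
#' @return A validated `decision_records` data frame, or an assignment
#'   data frame with columns `examiner_id`, `n_assigned`.
#' @export
read_decision_records <- function(path) {
  validate_decision_records(read.csv(path, colClasses = "character"))
}

#' @rdname read_decision_records
#' @export
read_assignments <- function(path) {
  df <- read.csv(path, colClasses = c("character", "integer"))
  if (!all(c("examiner_id", "n_assigned") %in% names(df)))
    stop_bbmiss("assignment table needs columns examiner_id, n_assigned",
                "bbmiss_input_error")
  if (any(df$n_assigned < 0)) stop_bbmiss("negative assignment count",
                                          "bbmiss_input_error")
  if (anyDuplicated(df$examiner_id))
    stop_bbmiss("duplicated examiner in assignment table", "bbmiss_input_error")
  df
}

#' Build a study panel from decision records
#'
#' Reduces decision records for one ground-truth stratum to the per-examiner
#' sufficient statistics consumed by all models: items assigned `J`, items
#' with an observed binary decision `R`, and observed errors `E_obs`.  An
#' error is a decision that contradicts ground truth (an identification on a
#' different-source item, or an exclusion on a same-source item).
#'
#' Inconclusive decisions are handled by `policy`:
#' `"as_correct_observed"` counts them as observed, correct decisions (the
#' prevailing practice in published studies); `"as_missing"` treats them as
#' non-responses.  `"no_value"` determinations are treated as missing under
#' both policies.
#'
#' @param records a `decision_records` data frame (see [decision_records()]).
#' @param assignments data frame with columns `examiner_id`, `n_assigned`:
#'   the number of items in this stratum assigned to each examiner.
#' @param policy inconclusive-handling policy, see above.
#' @param stratum which ground-truth stratum to analyse; records from the
#'   other stratum are dropped first.
#' @param include_unit_nonrespondents if `FALSE` (default), examiners that
#'   appear in `assignments` but have no record at all in `records` (unit
#'   non-respondents) are dropped, matching the usual restriction of
#'   published analyses to participants who returned at least one response.
#'   If `TRUE` they are kept with `R = 0`.
#' @return An object of class `study_panel`: a data frame with one row per
#'   examiner (`examiner_id`, `J`, `R`, `E_obs`) and attributes `policy`,
#'   `stratum`, `I` (examiners), `I_star` (examiners with `R > 0`),
#'   `J_total`, `R_total`.
#' @examples
#' rec <- decision_records(
#'   examiner_id = rep("ex1", 3), item_id = paste0("it", 1:3),
#'   ground_truth = "different_source",
#'   decision = c("identification", "exclusion", "inconclusive"))
#' asg <- data.frame(examiner_id = "ex1", n_assigned = 5)
#' build_panel(rec, asg, policy = "as_correct_observed")
#' @export
build_panel <- function(records, assignments,
                        policy = c("as_correct_observed", "as_missing"),
                        stratum = c("different_source", "same_source"),
                        include_unit_nonrespondents = FALSE) {
  policy <- match.arg(policy)
  stratum <- match.arg(stratum)
  records <- validate_decision_records(as.data.frame(records))
  if (!all(c("examiner_id", "n_assigned") %in% names(assignments)))
    stop_bbmiss("assignment table needs columns examiner_id, n_assigned",
                "bbmiss_input_error")

  responded <- unique(records$examiner_id)  # responded in any stratum
  rec <- records[records$ground_truth == stratum, , drop = FALSE]
  unknown <- setdiff(rec$examiner_id, assignments$examiner_id)
  if (length(unknown))
    stop_bbmiss(paste("records for examiner(s) missing from assignments:",
                      paste(unknown, collapse = ", ")), "bbmiss_input_error")

  keep <- if (include_unit_nonrespondents) assignments$examiner_id else
    intersect(assignments$examiner_id, responded)
  ids <- sort(unique(keep))

  # per-record status under the policy
  error_decision <- if (stratum == "different_source") "identification" else "exclusion"
  correct_decision <- if (stratum == "different_source") "exclusion" else "identification"
  observed <- rec$decision %in% c(error_decision, correct_decision) |
    (policy == "as_correct_observed" & rec$decision == "inconclusive")
  is_error <- rec$decision == error_decision

  R <- E <- integer(length(ids))
  names(R) <- names(E) <- ids
  tab_R <- table(factor(rec$examiner_id[observed], levels = ids))
  tab_E <- table(factor(rec$examiner_id[observed & is_error], levels = ids))
  R[] <- as.integer(tab_R)
  E[] <- as.integer(tab_E)
  J <- assignments$n_assigned[match(ids, assignments$examiner_id)]

  over <- ids[R > J]
  if (length(over))
    stop_bbmiss(paste("more observed responses than assigned items for:",
                      paste(over, collapse = ", ")), "bbmiss_input_error")

  panel <- data.frame(examiner_id = ids, J = as.integer(J),
                      R = as.integer(R), E_obs = as.integer(E),
                      stringsAsFactors = FALSE)
  new_study_panel(panel, policy = policy, stratum = stratum)
}

new_study_panel <- function(panel, policy, stratum) {
  rownames(panel) <- NULL
  structure(panel,
            policy = policy, stratum = stratum,
            I = nrow(panel), I_star = sum(panel$R > 0L),
            J_total = sum(panel$J), R_total = sum(panel$R),
            class = c("study_panel", "data.frame"))
}

#' Assemble a study panel directly from per-examiner counts
#'
#' The hierarchical models depend on the data only through the per-examiner
#' sufficient statistics (assigned `J`, responded `R`, observed errors
#' `E_obs`), so a panel can be built from published count tables without the
#' underlying item-level records.
#'
#' @param J,R,E_obs integer vectors, one entry per examiner, with
#'   `0 <= E_obs <= R <= J`.
#' @param examiner_id optional identifiers (default `ex1, ex2, ...`).
#' @param policy,stratum labels recorded on the panel.
#' @return A `study_panel` object, as from [build_panel()].
#' @export
panel_from_counts <- function(J, R, E_obs, examiner_id = NULL,
                              policy = "as_correct_observed",
                              stratum = "different_source") {
  n <- length(J)
  if (length(R) != n || length(E_obs) != n)
    stop_bbmiss("J, R, E_obs must have equal length", "bbmiss_input_error")
  if (any(E_obs < 0 | R < E_obs | J < R))
    stop_bbmiss("need 0 <= E_obs <= R <= J for every examiner",
                "bbmiss_input_error")
  if (is.null(examiner_id))
    examiner_id <- if (n) paste0("ex", seq_len(n)) else character(0)
  panel <- data.frame(examiner_id = as.character(examiner_id),
                      J = as.integer(J), R = as.integer(R),
                      E_obs = as.integer(E_obs), stringsAsFactors = FALSE)
  new_study_panel(panel, policy = policy, stratum = stratum)
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf("study panel (%s, inconclusives %s)\n", attr(x, "stratum"),
              if (attr(x, "policy") == "as_correct_observed")
                "observed-correct" else "missing"))
  cat(sprintf("  examiners I = %d (I* = %d with >= 1 response)\n",
              attr(x, "I"), attr(x, "I_star")))
  cat(sprintf("  items assigned J = %d, responded R = %d, observed errors = %d\n",
              attr(x, "J_total"), attr(x, "R_total"), sum(x$E_obs)))
  cat(sprintf("  pooled non-response rate = %s%%\n",
              fmt_pct(nonresponse_rate(x))))
  invisible(x)
}

#' Pooled non-response rate of a panel
#'
#' The fraction of assigned items without an observed binary decision,
#' `1 - R_total / J_total`, pooling unit and item non-response.
#'
#' @param panel a `study_panel`.
#' @return A fraction in `[0, 1]`.
#' @export
nonresponse_rate <- function(panel) {
  J <- attr(panel, "J_total")
  if (is.null(J) || J <= 0)
    stop_bbmiss("panel has no assigned items (J_total = 0)", "bbmiss_input_error")
  1 - attr(panel, "R_total") / J
}

#' Per-examiner empirical rates
#'
#' `empirical_error_rate()` returns observed errors over observed responses,
#' `E_obs / R`; it is undefined (an error) for an examiner with no observed
#' response.  `examiner_nonresponse_rate()` returns `1 - R / J`.
#'
#' @param panel a `study_panel`.
#' @param examiner an `examiner_id` present in the panel.
#' @return A fraction in `[0, 1]`.
#' @export
empirical_error_rate <- function(panel, examiner) {
  i <- match(examiner, panel$examiner_id)
  if (is.na(i)) stop_bbmiss("unknown examiner", "bbmiss_input_error")
  if (panel$R[i] == 0)
    stop_bbmiss("empirical error rate undefined: examiner has no observed response",
                "bbmiss_input_error")
  panel$E_obs[i] / panel$R[i]
}

#' @rdname empirical_error_rate
#' @export
examiner_nonresponse_rate <- function(panel, examiner) {
  i <- match(examiner, panel$examiner_id)
  if (is.na(i)) stop_bbmiss("unknown examiner", "bbmiss_input_error")
  if (panel$J[i] == 0)
    stop_bbmiss("examiner has no assigned items", "bbmiss_input_error")
  1 - panel$R[i] / panel$J[i]
}

#' Write a panel's per-examiner counts to CSV
#'
#' Columns `examiner_id,J,R,E_obs`.
#'
#' @param panel a `study_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(as.data.frame(panel)[c("examiner_id", "J", "R", "E_obs")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a panel to examiners with at least one observed response
#'
#' Returns the sub-panel of examiners with `R > 0` (the `I*` examiners),
#' with all panel totals recomputed.  The naive model applies this
#' restriction automatically; it is exported so that other fits (e.g. the
#' empirical-Bayes marginal MLE) can be run on either the full panel or
#' the responders-only panel.
#'
#' @param panel a `study_panel`.
#' @return A `study_panel` containing only responding examiners.
#' @export
panel_responders <- function(panel) {
  sub <- as.data.frame(panel)[panel$R > 0L, , drop = FALSE]
  new_study_panel(sub, policy = attr(panel, "policy"),
                  stratum = attr(panel, "stratum"))
}
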