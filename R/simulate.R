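#' Configuration for the synthetic black-box-study generator
#'
#' @param I number of examiners.
#' @param J items assigned per examiner (scalar or length-`I` vector); all
#'   items belong to one ground-truth stratum.
#' @param hyper a [hyperparams()] object giving the population truth.  For
#'   `mechanism = "nonignorable"` blocks `p`, `pi1`, `pi2` are required;
#'   for `"ignorable"` and `"mcar"` blocks `p` and `pi1` suffice (the two
#'   response blocks are forced equal).
#' @param mechanism missingness mechanism: `"nonignorable"` (response
#'   probability differs between error and non-error items), `"ignorable"`
#'   (one examiner-varying response probability), or `"mcar"` (one common
#'   response probability `mu_pi1` shared by all examiners).
#' @param inconclusive_rate,no_value_rate fraction of responded items
#'   relabelled as inconclusive / no-value decisions.
#' @param inconclusive_error_ratio multiplies the inconclusive rate on items
#'   whose latent decision would have been an error (1 = relabelling
#'   independent of the latent error, the default).
#' @param stratum ground-truth stratum for the emitted records.
#' @param seed integer master seed.  Each examiner uses an independent
#'   substream derived from it, so increasing `I` extends a study without
#'   perturbing earlier examiners.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(I, J = 22, hyper, mechanism = c("nonignorable",
                                                             "ignorable", "mcar"),
                             inconclusive_rate = 0, no_value_rate = 0,
                             inconclusive_error_ratio = 1,
                             stratum = "different_source", seed = 1) {
  mechanism <- match.arg(mechanism)
  if (I < 1) stop_bbmiss("need I >= 1 examiners", "bbmiss_input_error")
  J <- rep_len(as.integer(J), I)
  if (all(J == 0)) stop_bbmiss("no items assigned", "bbmiss_input_error")
  rates <- c(inconclusive_rate, no_value_rate)
  if (any(rates < 0 | rates > 1) ||
      inconclusive_rate * max(1, inconclusive_error_ratio) > 1)
    stop_bbmiss("relabelling rates must lie in [0, 1]", "bbmiss_input_error")
  require_blocks(hyper, if (mechanism == "nonignorable") c("p", "pi1", "pi2")
                 else c("p", "pi1"))
  structure(list(I = as.integer(I), J = J, hyper = hyper, mechanism = mechanism,
                 inconclusive_rate = inconclusive_rate,
                 no_value_rate = no_value_rate,
                 inconclusive_error_ratio = inconclusive_error_ratio,
                 stratum = stratum, seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic per-examiner substream seed (31-bit)
examiner_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
}

#' Generate a complete synthetic black-box study
#'
#' Simulates the generative process of the hierarchical selection model:
#' per examiner, an error probability `p_i` and response probabilities
#' `pi1_i` (no error) / `pi2_i` (error) are drawn from their Beta
#' populations; each assigned item gets a latent error indicator
#' `y ~ Bernoulli(p_i)` and a response indicator `r ~ Bernoulli(pi1_i)` if
#' `y = 0`, `Bernoulli(pi2_i)` if `y = 1`.  Responded items are emitted as
#' decision records (`identification` for an error on a different-source
#' item, `exclusion` otherwise), optionally relabelled as inconclusive or
#' no-value at the configured rates.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_study`: list with `records`
#'   (a `decision_records` data frame of responded items), `assignments`
#'   (`examiner_id`, `n_assigned`), `truth` (per-examiner `p`, `pi1`, `pi2`)
#'   and `latent` (item-level `y`, `r`, `decision` for every assigned item),
#'   plus the `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_bbmiss("config must be a generator_config", "bbmiss_input_error")
  hp <- config$hyper
  err_dec <- if (config$stratum == "different_source") "identification" else "exclusion"
  ok_dec <- if (config$stratum == "different_source") "exclusion" else "identification"

  truth <- vector("list", config$I)
  latent <- vector("list", config$I)
  for (i in seq_len(config$I)) {
    set.seed(examiner_seed(config$seed, i))
    J <- config$J[i]
    p <- rbeta(1, hp$mu_p * hp$tau_p, (1 - hp$mu_p) * hp$tau_p)
    if (config$mechanism == "mcar") {
      pi1 <- pi2 <- hp$mu_pi1
    } else {
      pi1 <- rbeta(1, hp$mu_pi1 * hp$tau_pi1, (1 - hp$mu_pi1) * hp$tau_pi1)
      pi2 <- if (config$mechanism == "ignorable") pi1 else
        rbeta(1, hp$mu_pi2 * hp$tau_pi2, (1 - hp$mu_pi2) * hp$tau_pi2)
    }
    y <- as.integer(runif(J) < p)
    r <- as.integer(runif(J) < ifelse(y == 1, pi2, pi1))
    dec <- ifelse(y == 1, err_dec, ok_dec)
    dec[r == 0] <- NA_character_
    # relabelling layer, applied to responded items only
    if (config$inconclusive_rate > 0 || config$no_value_rate > 0) {
      u <- runif(J)
      nv <- r == 1 & u < config$no_value_rate
      inc_rate <- config$inconclusive_rate *
        ifelse(y == 1, config$inconclusive_error_ratio, 1)
      v <- runif(J)
      inc <- r == 1 & !nv & v < inc_rate
      dec[nv] <- "no_value"
      dec[inc] <- "inconclusive"
    }
    truth[[i]] <- data.frame(examiner_id = sprintf("ex%04d", i),
                             p = p, pi1 = pi1, pi2 = pi2)
    latent[[i]] <- data.frame(examiner_id = sprintf("ex%04d", i),
                              item_id = sprintf("ex%04d_it%03d", i, seq_len(J)),
                              y = y, r = r, decision = dec,
                              stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  latent <- do.call(rbind, latent)
  rownames(truth) <- rownames(latent) <- NULL

  resp <- latent[latent$r == 1, , drop = FALSE]
  records <- decision_records(resp$examiner_id, resp$item_id,
                              config$stratum, resp$decision)
  assignments <- data.frame(examiner_id = sprintf("ex%04d", seq_len(config$I)),
                            n_assigned = config$J, stringsAsFactors = FALSE)
  structure(list(records = records, assignments = assignments,
                 truth = truth, latent = latent, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic black-box study: %d examiners, %d assigned items, %d records\n",
              x$config$I, sum(x$config$J), nrow(x$records)))
  cat(sprintf("  mechanism: %s, seed %d\n", x$config$mechanism, x$config$seed))
  invisible(x)
}

#' Synthetic stand-in for the palmar-print study's different-source stratum
#'
#' Generates a study with the dimensions of the motivating latent palmar
#' print black-box study (226 responding examiners, 22 different-source
#' items each, 4972 assigned trials) under non-ignorable missingness, with
#' population truth near the hyperparameter estimates reported for that
#' study (`mu_p = 0.2, tau_p = 7.1, mu_pi1 = 0.6, tau_pi1 = 0.4,
#' mu_pi2 = 0.01, tau_pi2 = 3.5`), emulating its missingness regime.  The
#' real data are not redistributable; this fixture is synthetic.
#'
#' @param seed integer seed.
#' @return A `synthetic_study`.
#' @export
palmar_print_fixture <- function(seed = 1) {
  generate_study(generator_config(
    I = 226, J = 22,
    hyper = hyperparams(mu_p = 0.2, tau_p = 7.1, mu_pi1 = 0.6, tau_pi1 = 0.4,
                        mu_pi2 = 0.01, tau_pi2 = 3.5),
    mechanism = "nonignorable", seed = seed))
}

#' Write a synthetic study to CSV files
#'
#' Writes `records.csv` (`examiner_id,item_id,ground_truth,decision`),
#' `assignments.csv` (`examiner_id,n_assigned`) and a latent-truth sidecar
#' `truth.csv` intended for test harnesses only.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(study$records), file.path(dir, "records.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(study$assignments, file.path(dir, "assignments.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
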