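# internal numerical helpers

# log(sum(exp(x))) without overflow; -Inf for empty/-Inf-only input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# keep sampled probabilities strictly inside (0,1) so log densities stay finite
clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bbmiss <- function(msg, class) {
  stop(structure(class = c(class, "bbmiss_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# round-half-to-even percentage used in printed reports
fmt_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round(100 * x, digits))
}
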