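# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash used wherever the pipeline needs independent
#' random streams (replicates, imputed sets) that are fully determined by a
#' single master seed.  Kept strictly below `.Machine$integer.max`.
#'
#' @param seed master seed (integer).
#' @param i stream index (integer >= 0).
#' @return a positive integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  s <- (abs(as.double(seed)) %% 1e6) * 2099 + as.double(i) * 7919 + 1
  as.integer(s %% (.Machine$integer.max - 1L) + 1)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Score ranges used for validation and for clipping imputed draws.
score_ranges <- list(
  das  = c(0, 5),
  pga  = c(0, 10),
  cmas = c(0, 52),
  gc_dose = c(0, Inf)
)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
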