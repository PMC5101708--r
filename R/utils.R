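# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed error
#'
#' All package errors carry class `twinpk_error` plus a specific subclass so
#' callers can branch on failure modes (e.g. `twinpk_insufficient_data`).
#'
#' @param msg message.
#' @param class specific condition subclass.
#' @param ... fields attached to the condition.
#' @noRd
tpk_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "twinpk_error", "error")))
}

#' @noRd
assert_that <- function(ok, msg, class = "twinpk_invalid_input") {
  if (!isTRUE(ok)) tpk_stop(msg, class)
  invisible(TRUE)
}

# Deterministic sub-seed for a named stream, derived from the run seed.
# Keeps draws for one output table invariant to changes in the others
# (e.g. adding genotype loci never perturbs phenotype draws).
stream_seed <- function(seed, stream) {
  offsets <- c(phenotypes = 1L, genotypes = 2L, covariates = 3L,
               concentrations = 4L, rgc = 5L, bootstrap = 6L)
  off <- offsets[[stream]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

# Evaluate expr under a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so library code never disturbs the session RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sample variance that returns NA (not an error) below 2 observations.
safe_var <- function(x) if (length(x) < 2L) NA_real_ else stats::var(x)
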