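#' @keywords internal
"_PACKAGE"

## Canonical timepoint ordering used throughout: exposure happens after
## baseline, chronic tinnitus is assessed at week4.
TIMEPOINTS <- c("baseline", "week1", "week4", "week8")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded to `seed`, then
#' restores the previous stream so callers never observe a side effect on
#' \code{.Random.seed}.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

## Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Population standard deviation (divide by n).  The artifact-exclusion
## rule is a relative comparison so the convention cancels; it is fixed
## here for reproducibility.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x) && x >= 0
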