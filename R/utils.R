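# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded calls never perturb
#' the global random stream. A `NULL` seed evaluates the expression with the
#' current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("seed must be a single finite number or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Classed conditions so callers can distinguish bad parameters from
# infeasible-but-valid requests and degenerate analysis inputs.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("beatattn_invalid_parameter", "error")))
}

stop_infeasible <- function(..., data = NULL) {
  stop(errorCondition(paste0(...), class = c("beatattn_infeasible", "error"),
                      data = data))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("beatattn_degenerate", "error")))
}

#' Wrap angles to the half-open interval (-pi, pi]
#' @noRd
wrap_pi <- function(x) pi - ((pi - x) %% (2 * pi))

#' Derive a vector of child seeds from one base seed
#'
#' Deterministic and independent of the caller's RNG state; children stay
#' within the 32-bit integer range `set.seed()` accepts.
#' @noRd
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}
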